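#' Load the van der Waals radii table
#'
#' Chothia-style united-atom radii by element (C 1.87, N 1.65, O 1.40,
#' S 1.85, P 1.90; `DEFAULT` covers anything else), in angstroms.
#'
#' @param path optional custom TSV (columns `element`, `radius`).
#' @return named numeric vector of radii.
#' @export
load_radii <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("vdw_radii.tsv")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  r <- setNames(tab$radius, tab$element)
  if (any(r <= 0.5 | r >= 3.0)) stop("radii must lie in (0.5, 3.0) angstroms")
  r
}

.atom_radii <- function(x, radii) {
  r <- unname(radii[x$atoms$element])
  r[is.na(r)] <- unname(radii["DEFAULT"])
  r
}

#' Per-atom solvent accessible surface area (Lee-Richards)
#'
#' Numerically integrates the solvent accessible surface of each atom,
#' inflated by the probe radius, over z-slices: in each slice the exposed
#' arc of the atom's circle — the part not covered by the circles of
#' intersecting inflated neighbors — contributes `R * dz * arc_angle`
#' of area. Each atom uses its own slice grid of approximately
#' `slice_dz` spacing, rescaled so the slab count is integral (an
#' isolated sphere then integrates to its exact analytic area).
#'
#' @param x a `prot_structure` with at least one atom.
#' @param probe probe radius in angstroms (1.4 = water).
#' @param radii radii table from [load_radii()].
#' @param slice_dz target slice thickness in angstroms, in (0.01, 0.5).
#' @return numeric vector of areas (square angstroms), one per atom row.
#' @export
sasa_atoms <- function(x, probe = 1.4, radii = load_radii(),
                       slice_dz = 0.05) {
  stopifnot(inherits(x, "prot_structure"))
  if (nrow(x$atoms) == 0) stop("empty structure")
  stopifnot(probe > 0, slice_dz > 0.01, slice_dz < 0.5)
  co <- as.matrix(x$atoms[, c("x", "y", "z")])
  R <- .atom_radii(x, radii) + probe
  n <- nrow(co)
  areas <- numeric(n)
  # pairwise inflated-contact neighbor lists
  for (i in seq_len(n)) {
    dxy2_all <- (co[, 1] - co[i, 1])^2 + (co[, 2] - co[i, 2])^2
    d3 <- sqrt(dxy2_all + (co[, 3] - co[i, 3])^2)
    nb <- which(d3 < R[i] + R & seq_len(n) != i)
    nk <- max(1L, as.integer(ceiling(2 * R[i] / slice_dz)))
    dz <- 2 * R[i] / nk
    zs <- co[i, 3] - R[i] + (seq_len(nk) - 0.5) * dz
    for (z in zs) {
      ri2 <- R[i]^2 - (z - co[i, 3])^2
      if (ri2 <= 0) next
      ri <- sqrt(ri2)
      exposed <- 2 * pi
      if (length(nb) > 0) {
        zn <- nb[abs(z - co[nb, 3]) < R[nb]]
        if (length(zn) > 0) {
          rj <- sqrt(R[zn]^2 - (z - co[zn, 3])^2)
          dxy <- sqrt(dxy2_all[zn])
          full <- dxy + ri <= rj            # slice circle fully covered
          if (any(full)) {
            exposed <- 0
          } else {
            act <- dxy < ri + rj & dxy + rj > ri & dxy > 0
            if (any(act)) {
              alpha <- acos(pmin(1, pmax(-1,
                (dxy[act]^2 + ri2 - rj[act]^2) / (2 * dxy[act] * ri))))
              theta <- atan2(co[zn[act], 2] - co[i, 2],
                             co[zn[act], 1] - co[i, 1])
              exposed <- .exposed_angle(theta - alpha, theta + alpha)
            }
          }
        }
      }
      areas[i] <- areas[i] + R[i] * dz * exposed
    }
  }
  areas
}

# total angle of [0, 2*pi) not covered by the union of arcs [lo, hi]
.exposed_angle <- function(lo, hi) {
  lo <- lo %% (2 * pi)
  hi <- hi %% (2 * pi)
  wrap <- hi < lo
  a0 <- c(lo[!wrap], lo[wrap], rep(0, sum(wrap)))
  a1 <- c(hi[!wrap], rep(2 * pi, sum(wrap)), hi[wrap])
  ord <- order(a0)
  a0 <- a0[ord]
  a1 <- a1[ord]
  covered <- 0
  cur_lo <- a0[1]
  cur_hi <- a1[1]
  for (k in seq_along(a0)[-1]) {
    if (a0[k] <= cur_hi) {
      cur_hi <- max(cur_hi, a1[k])
    } else {
      covered <- covered + (cur_hi - cur_lo)
      cur_lo <- a0[k]
      cur_hi <- a1[k]
    }
  }
  covered <- covered + (cur_hi - cur_lo)
  max(0, 2 * pi - covered)
}

.SASA_CATEGORIES <- c("all_atoms", "total_side", "main_chain",
                      "non_polar", "all_polar")

#' Per-residue accessibility profile (absolute part)
#'
#' Sums per-atom areas into the five Naccess-style categories per
#' residue: all atoms; side chain (everything outside the backbone set
#' \{N, CA, C, O, OXT\} — for Gly the CA counts as main chain only);
#' main chain; non-polar (carbon atoms); all polar (N, O, S atoms).
#'
#' @param atom_areas vector from [sasa_atoms()] (same atom order).
#' @param x the `prot_structure` the areas were computed on.
#' @return data frame with `res_index`, `res_seq`, `res_name`,
#'   `one_letter`, and the five `*_abs` columns (square angstroms).
#' @export
residue_accessibility <- function(atom_areas, x) {
  stopifnot(inherits(x, "prot_structure"),
            length(atom_areas) == nrow(x$atoms))
  main <- x$atoms$name %in% .BACKBONE_ATOMS
  polar <- x$atoms$element %in% c("N", "O", "S")
  by_res <- function(mask) {
    v <- tapply(atom_areas * mask, x$atoms$res_index, sum)
    as.numeric(v[as.character(x$residues$res_index)])
  }
  out <- data.frame(
    res_index = x$residues$res_index,
    res_seq = x$residues$res_seq,
    res_name = x$residues$res_name,
    one_letter = x$residues$one_letter,
    all_atoms_abs = by_res(rep(TRUE, nrow(x$atoms))),
    total_side_abs = by_res(!main),
    main_chain_abs = by_res(main),
    non_polar_abs = by_res(!polar),
    all_polar_abs = by_res(polar),
    stringsAsFactors = FALSE)
  out
}

#' Relative accessibility (% of Ala-X-Ala reference)
#'
#' Adds the five `*_rel` columns: 100 x absolute / reference for the
#' residue letter, per category. Residues without a reference (letter
#' `X`) or with a zero reference area (e.g. the glycine side chain)
#' report `NA`.
#'
#' @param abs_profile output of [residue_accessibility()].
#' @param reference reference table from [load_reference_table()] or
#'   [build_reference_table()].
#' @return `abs_profile` with `*_rel` columns appended.
#' @export
relative_accessibility <- function(abs_profile,
                                   reference = load_reference_table()) {
  for (cat in .SASA_CATEGORIES) {
    ref <- reference[[paste0(cat, "_abs")]][
      match(abs_profile$one_letter, reference$one_letter)]
    ref[!is.na(ref) & ref <= 0] <- NA
    abs_profile[[paste0(cat, "_rel")]] <-
      100 * abs_profile[[paste0(cat, "_abs")]] / ref
  }
  abs_profile
}

#' Build the Ala-X-Ala reference table
#'
#' For each of the twenty residue types X, builds an extended Ala-X-Ala
#' tripeptide (phi = -120, psi = +120 degrees) with the packaged ideal
#' geometry and records the absolute accessibility of the central
#' residue in each category. The packaged default table was generated by
#' this function with default parameters; regeneration reproduces it.
#'
#' @param probe probe radius (angstroms).
#' @param radii radii table.
#' @param slice_dz slice thickness (angstroms).
#' @return data frame with `one_letter` and the five `*_abs` columns.
#' @export
build_reference_table <- function(probe = 1.4, radii = load_radii(),
                                  slice_dz = 0.05) {
  rows <- lapply(sort(unname(.AA321)), function(letter) {
    res <- .AA123[letter]
    tri <- tryCatch(build_peptide(c("ALA", res, "ALA")),
                    error = function(e)
                      stop("reference builder failed for X=", letter, ": ",
                           conditionMessage(e)))
    ar <- sasa_atoms(tri, probe = probe, radii = radii, slice_dz = slice_dz)
    prof <- residue_accessibility(ar, tri)
    cbind(data.frame(one_letter = letter, stringsAsFactors = FALSE),
          prof[2, paste0(.SASA_CATEGORIES, "_abs"), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load the packaged Ala-X-Ala reference table
#' @param path optional custom table (TSV as written by
#'   [write_reference_table()]).
#' @return reference data frame.
#' @export
load_reference_table <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("rsa_reference.tsv")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a reference table to TSV
#' @param reference data frame from [build_reference_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(reference, path) {
  out <- reference
  for (cat in paste0(.SASA_CATEGORIES, "_abs"))
    out[[cat]] <- sprintf("%.6f", out[[cat]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Full accessibility profile of a structure
#'
#' Convenience wrapper: per-atom Lee-Richards areas, category sums, and
#' relative values against the reference table.
#'
#' @param x a `prot_structure`.
#' @param probe,radii,slice_dz see [sasa_atoms()].
#' @param reference see [relative_accessibility()].
#' @return data frame with absolute and relative categories per residue.
#' @export
accessibility_profile <- function(x, probe = 1.4, radii = load_radii(),
                                  slice_dz = 0.05,
                                  reference = load_reference_table()) {
  ar <- sasa_atoms(x, probe = probe, radii = radii, slice_dz = slice_dz)
  relative_accessibility(residue_accessibility(ar, x), reference)
}

#' Export an accessibility profile as TSV (.rsa-style columns)
#'
#' @param profile output of [accessibility_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_accessibility_tsv <- function(profile, path) {
  cols <- c("res_name", "res_seq",
            as.vector(rbind(paste0(.SASA_CATEGORIES, "_abs"),
                            paste0(.SASA_CATEGORIES, "_rel"))))
  out <- profile[, cols]
  for (cc in cols[-(1:2)]) out[[cc]] <- round(out[[cc]], 3)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
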