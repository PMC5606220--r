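#' Build a synthetic structure from a declarative spec
#'
#' Test-data generator: constructs a single-chain structure with atoms at
#' exact coordinates. The spec is a list of residues, each a list with
#' `res_name`, optional `res_seq`, and `atoms` — a named list mapping atom
#' names to 3-vectors (in angstroms). Atom names are validated against the
#' packaged residue geometry templates, so fixtures can only plant
#' chemically meaningful atoms. Deterministic for a fixed spec; `path`
#' optionally writes the PDB serialization.
#'
#' @param spec list of residue specs (see details above).
#' @param path optional output PDB path.
#' @param chain chain identifier (default `"A"`).
#' @param id structure label.
#' @return a `prot_structure` (with the file written when `path` is given).
#' @export
make_fixture <- function(spec, path = NULL, chain = "A", id = "fixture.A") {
  tmpl <- residue_templates()
  rows <- list()
  serial <- 0L
  for (ri in seq_along(spec)) {
    rs <- spec[[ri]]
    res_name <- rs$res_name
    res_seq <- if (!is.null(rs$res_seq)) as.integer(rs$res_seq) else ri
    known <- tmpl$atom_name[tmpl$res_name == res_name]
    if (length(known) == 0 && res_name %in% names(.AA321))
      stop("unknown residue template: ", res_name)
    for (an in names(rs$atoms)) {
      if (length(known) > 0 && !an %in% known)
        stop("unknown atom name '", an, "' for residue ", res_name)
      serial <- serial + 1L
      cc <- rs$atoms[[an]]
      el <- if (length(known) > 0)
        tmpl$element[tmpl$res_name == res_name & tmpl$atom_name == an][1]
      else toupper(substr(gsub("[0-9']", "", an), 1, 1))
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = an, element = el, res_name = res_name,
        res_seq = res_seq, icode = " ", chain_id = chain,
        x = cc[1], y = cc[2], z = cc[3],
        occupancy = 1, altloc = " ", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    rows <- list(data.frame(
      serial = integer(0), name = character(0), element = character(0),
      res_name = character(0), res_seq = integer(0), icode = character(0),
      chain_id = character(0), x = numeric(0), y = numeric(0),
      z = numeric(0), occupancy = numeric(0), altloc = character(0),
      stringsAsFactors = FALSE))
  }
  x <- .new_structure(do.call(rbind, rows), id)
  if (!is.null(path)) write_structure(x, path)
  x
}

#' Packaged ideal residue geometry templates
#'
#' Heavy-atom coordinates of the twenty standard amino acids in an ideal
#' local geometry, used by the peptide builder and to validate fixture
#' atom names.
#'
#' @return data frame with `res_name`, `atom_name`, `element`, `x`, `y`, `z`.
#' @export
residue_templates <- function() {
  read.delim(.extdata("residue_templates.tsv"), stringsAsFactors = FALSE)
}

# place atom D given positions A,B,C and internal coordinates
# |CD| = bond, angle(BCD) = ang (deg), dihedral(ABCD) = dih (deg)
.nerf_place <- function(A, B, C, bond, ang, dih) {
  ang <- ang * pi / 180
  dih <- dih * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an idealized polypeptide chain
#'
#' Constructs a chain with ideal backbone geometry (N-CA 1.458, CA-C
#' 1.525, C-N 1.329 angstroms; trans peptide bonds) at the given backbone
#' dihedrals, then grafts ideal side-chain geometry from the packaged
#' residue templates by superposing each template's N/CA/C triad onto the
#' built backbone. The default dihedrals (phi = -120, psi = +120 degrees)
#' give the extended conformation used for Ala-X-Ala reference tripeptides.
#'
#' @param res_names character vector of three-letter residue codes, or a
#'   one-letter sequence string.
#' @param phi,psi backbone dihedrals in degrees (recycled along the chain).
#' @param chain chain identifier.
#' @param id structure label.
#' @return a `prot_structure`.
#' @export
build_peptide <- function(res_names, phi = -120, psi = 120,
                          chain = "A", id = "peptide.A") {
  if (length(res_names) == 1 && !res_names %in% names(.AA321)) {
    letters1 <- strsplit(res_names, "")[[1]]
    if (!all(letters1 %in% names(.AA123)))
      stop("unknown residue letter in sequence")
    res_names <- unname(.AA123[letters1])
  }
  n <- length(res_names)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  tmpl <- residue_templates()

  bN <- matrix(0, n, 3)  # backbone N, CA, C per residue
  bCA <- matrix(0, n, 3)
  bC <- matrix(0, n, 3)
  bN[1, ] <- c(0, 0, 0)
  bCA[1, ] <- c(1.458, 0, 0)
  ang_NCAC <- 111.2
  bC[1, ] <- .nerf_place(c(-1, 1, 0), bN[1, ], bCA[1, ], 1.525, ang_NCAC,
                         phi[1])
  for (i in seq_len(n)[-1]) {
    bN[i, ] <- .nerf_place(bN[i - 1, ], bCA[i - 1, ], bC[i - 1, ],
                           1.329, 116.2, psi[i - 1])
    bCA[i, ] <- .nerf_place(bCA[i - 1, ], bC[i - 1, ], bN[i, ],
                            1.458, 121.7, 180)          # omega (trans)
    bC[i, ] <- .nerf_place(bC[i - 1, ], bN[i, ], bCA[i, ],
                           1.525, ang_NCAC, phi[i])
  }

  spec <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- tmpl[tmpl$res_name == res_names[i], , drop = FALSE]
    if (nrow(tt) == 0) stop("no template for residue ", res_names[i])
    tco <- as.matrix(tt[, c("x", "y", "z")])
    rownames(tco) <- tt$atom_name
    fit <- kabsch_superpose(tco[c("N", "CA", "C"), , drop = FALSE],
                            rbind(bN[i, ], bCA[i, ], bC[i, ]))
    placed <- sweep(tco %*% t(fit$rotation), 2, fit$translation, "+")
    # carbonyl O points opposite the next N (psi + 180)
    Oi <- .nerf_place(bN[i, ], bCA[i, ], bC[i, ], 1.231, 120.5,
                      psi[i] + 180)
    atoms <- lapply(seq_len(nrow(placed)), function(k) placed[k, ])
    names(atoms) <- tt$atom_name
    atoms[["N"]] <- bN[i, ]
    atoms[["CA"]] <- bCA[i, ]
    atoms[["C"]] <- bC[i, ]
    atoms[["O"]] <- Oi
    spec[[i]] <- list(res_name = res_names[i], res_seq = i, atoms = atoms)
  }
  make_fixture(spec, chain = chain, id = id)
}

#' Apply a rigid transform to a structure
#'
#' @param x a `prot_structure`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 vector (angstroms).
#' @param id label of the returned copy.
#' @return transformed `prot_structure` with coordinates `R x + t`.
#' @export
transform_structure <- function(x, rotation = diag(3),
                                translation = c(0, 0, 0), id = x$id) {
  stopifnot(inherits(x, "prot_structure"))
  co <- as.matrix(x$atoms[, c("x", "y", "z")])
  co <- sweep(co %*% t(rotation), 2, translation, "+")
  x$atoms$x <- co[, 1]
  x$atoms$y <- co[, 2]
  x$atoms$z <- co[, 3]
  x$id <- id
  x
}

#' Add isotropic Gaussian coordinate noise
#'
#' @param x a `prot_structure`.
#' @param sigma standard deviation per coordinate (angstroms).
#' @param seed integer seed (local RNG; the global seed is untouched).
#' @param id label of the returned copy.
#' @return perturbed `prot_structure`.
#' @export
perturb_structure <- function(x, sigma = 0.3, seed = 1L, id = x$id) {
  stopifnot(inherits(x, "prot_structure"))
  n <- nrow(x$atoms)
  old <- .Random.seed_exists()
  set.seed(seed)
  eps <- matrix(rnorm(3 * n, sd = sigma), n, 3)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  x$atoms$x <- x$atoms$x + eps[, 1]
  x$atoms$y <- x$atoms$y + eps[, 2]
  x$atoms$z <- x$atoms$z + eps[, 3]
  x$id <- id
  x
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

# key atoms used by the planted-interaction fixtures, one per criterion
.PAIR_FIXTURE_ATOMS <- list(
  aromatic_stacking = list(a = list(res = "PHE", atom = "CZ"),
                           b = list(res = "PHE", atom = "CZ")),
  disulfide_bridge  = list(a = list(res = "CYS", atom = "SG"),
                           b = list(res = "CYS", atom = "SG")),
  hydrogen_bond     = list(a = list(res = "SER", atom = "OG"),
                           b = list(res = "THR", atom = "OG1")),
  hydrophobic       = list(a = list(res = "LEU", atom = "CD1"),
                           b = list(res = "LEU", atom = "CD1")),
  repulsive         = list(a = list(res = "LYS", atom = "NZ"),
                           b = list(res = "LYS", atom = "NZ")),
  salt_bridge       = list(a = list(res = "LYS", atom = "NZ"),
                           b = list(res = "ASP", atom = "OD1"))
)

#' Planted two-residue interaction fixture
#'
#' Builds a minimal two-residue structure whose designated key atoms (one
#' per interaction kind, e.g. Lys NZ / Asp OD1 for a salt bridge) sit
#' exactly `distance` angstroms apart along x. Each residue carries only
#' its key atom plus CA and CB placed well behind it, pointing away from
#' the gap, so the key pair is the only atom pair whose types and
#' distance can satisfy the planted criterion.
#'
#' @param kind one of the six interaction kinds.
#' @param distance key-atom separation in angstroms.
#' @return a `prot_structure` with two residues.
#' @export
fixture_pair <- function(kind, distance) {
  kind <- match.arg(kind, .INTERACTION_KINDS)
  fx <- .PAIR_FIXTURE_ATOMS[[kind]]
  mk <- function(res, atom, flip, shift) {
    # local geometry: key atom at the origin, backbone stub pointing -x
    co <- rbind(c(0, 0, 0), c(-3.0, 0.8, 0.4), c(-2.2, -0.7, 0.9))
    rownames(co) <- c(atom, "CA", "CB")
    if (flip) {
      co[, 1] <- -co[, 1]          # proper rotation: pi about z
      co[, 2] <- -co[, 2]
    }
    co <- sweep(co, 2, shift, "+")
    atoms <- lapply(seq_len(nrow(co)), function(k) co[k, ])
    names(atoms) <- rownames(co)
    atoms
  }
  spec <- list(
    list(res_name = fx$a$res, res_seq = 1,
         atoms = mk(fx$a$res, fx$a$atom, FALSE, c(0, 0, 0))),
    list(res_name = fx$b$res, res_seq = 2,
         atoms = mk(fx$b$res, fx$b$atom, TRUE, c(distance, 0, 0)))
  )
  make_fixture(spec, id = paste0("pair_", kind, ".A"))
}

# proper rotation taking unit vector a to unit vector b (Rodrigues)
.rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c0 <- sum(a * b)
  if (sum(v^2) < 1e-16) {
    if (c0 > 0) return(diag(3))
    # pick any perpendicular axis for a half-turn
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2] * p[3] - a[3] * p[2],
           a[3] * p[1] - a[1] * p[3],
           a[1] * p[2] - a[2] * p[1])
    v <- v / sqrt(sum(v^2))
    K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c0) / sum(v^2))
}

#' Blocked-pair fixture (occluded contact)
#'
#' A donor/acceptor pair planted at an in-window hydrogen-bond distance
#' with a third atom placed exactly on the segment between them. Every
#' sphere through the pair then contains the blocker, so the pair cannot
#' be Delaunay neighbors and no contact is reported; with
#' `blocked = FALSE` the blocker is omitted and the contact appears.
#'
#' @param blocked whether to include the intervening atom.
#' @param distance donor-acceptor separation (angstroms).
#' @return a `prot_structure` with two or three residues.
#' @export
fixture_blocked_pair <- function(blocked = TRUE, distance = 2.8) {
  base <- fixture_pair("hydrogen_bond", distance)
  if (!blocked) return(base)
  spec <- lapply(seq_len(nrow(base$residues)), function(i) {
    a <- base$atoms[base$atoms$res_index == i, , drop = FALSE]
    atoms <- lapply(seq_len(nrow(a)), function(k) c(a$x[k], a$y[k], a$z[k]))
    names(atoms) <- a$name
    list(res_name = base$residues$res_name[i], res_seq = i, atoms = atoms)
  })
  # Cys SG exactly midway on the donor-acceptor segment; the cysteine
  # type cannot pair with anything in this fixture, so the blocker adds
  # no interaction of its own
  spec[[length(spec) + 1]] <- list(
    res_name = "CYS", res_seq = length(spec) + 1,
    atoms = list(SG = c(distance / 2, 0, 0)))
  make_fixture(spec, id = "blocked_pair.A")
}

#' Single-atom fixture
#' @param radius_atom atom name to plant (default an alanine CB).
#' @return a `prot_structure` with one residue and one atom.
#' @export
fixture_single_atom <- function(radius_atom = "CB") {
  make_fixture(list(list(res_name = "ALA", res_seq = 1,
                         atoms = setNames(list(c(0, 0, 0)), radius_atom))),
               id = "single_atom.A")
}

#' Five-residue extended mini-chain fixture
#' @param sequence one-letter sequence (default `"AGSLK"`).
#' @return a `prot_structure`.
#' @export
fixture_mini_chain <- function(sequence = "AGSLK") {
  build_peptide(sequence, id = "mini_chain.A")
}
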