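#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of two paired coordinate sets, returning a
#' proper rotation (determinant +1) and translation mapping `P` onto `Q`,
#' with the post-fit RMSD.
#'
#' @param P,Q numeric matrices (n x 3) of paired coordinates, n >= 3.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P)
  Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("paired coordinate sets differ in size")
  if (nrow(P) < 3) stop("need at least 3 paired points")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  s <- svd(t(Pc) %*% Qc)
  if (s$d[2] < 1e-10)
    stop("degenerate (collinear) input: superposition is not unique")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cq - as.vector(R %*% cp)
  fitted <- sweep(Pc %*% t(R), 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Global pairwise sequence alignment (affine gaps)
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap
#' scoring, used to seed the structural alignment and to place a mutant
#' sequence whose length differs from the wild type.
#'
#' @param a,b amino-acid sequences (strings).
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @return list with gapped strings `a_aligned`, `b_aligned` and `score`.
#' @export
global_seq_align <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  stopifnot(nzchar(a), nzchar(b))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  list(a_aligned = as.character(Biostrings::alignedPattern(al)),
       b_aligned = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

.ca_coords <- function(x) {
  ca <- x$atoms[x$atoms$name == "CA", , drop = FALSE]
  co <- as.matrix(ca[, c("x", "y", "z")])
  rownames(co) <- ca$res_index
  list(coords = co, res_index = ca$res_index)
}

# aligned-string pair -> matrix of (index in a, index in b) matched columns
.aligned_pairs <- function(a_aligned, b_aligned) {
  ca <- strsplit(a_aligned, "")[[1]]
  cb <- strsplit(b_aligned, "")[[1]]
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-"
  cbind(a = ia[keep], b = ib[keep])
}

# longest increasing subsequence (in the second column, rows sorted by first)
.lis_rows <- function(pairs) {
  n <- nrow(pairs)
  if (n <= 1) return(pairs)
  ord <- order(pairs[, 1], pairs[, 2])
  p <- pairs[ord, , drop = FALSE]
  best <- integer(n)   # length of LIS ending at k
  prev <- integer(n)
  for (k in seq_len(n)) {
    best[k] <- 1L
    prev[k] <- 0L
    for (m in seq_len(k - 1)) {
      if (p[m, 1] < p[k, 1] && p[m, 2] < p[k, 2] && best[m] + 1L > best[k]) {
        best[k] <- best[m] + 1L
        prev[k] <- m
      }
    }
  }
  k <- which.max(best)
  idx <- integer(0)
  while (k > 0) {
    idx <- c(k, idx)
    k <- prev[k]
  }
  p[idx, , drop = FALSE]
}

#' Structure-based pairwise alignment against the wild-type chain
#'
#' Iterative refinement: residue pairs are seeded from a global sequence
#' alignment, superposed by Kabsch on paired CA atoms, then re-paired as
#' mutually nearest CA pairs within `cutoff`, kept monotonic (no
#' crossings) by longest-increasing-subsequence filtering; iteration
#' stops when the pair set is stable or after `max_iter` rounds.
#'
#' @param wild,member `prot_structure` objects with CA atoms in at least
#'   4 residues each.
#' @param cutoff re-pairing distance cutoff in angstroms.
#' @param max_iter maximum refinement iterations.
#' @return a `correspondence`: list with `pairs` (matrix of wild/member
#'   residue indices, monotonic in both), `rmsd`, `iterations`.
#' @export
structural_align_pair <- function(wild, member, cutoff = 5.0,
                                  max_iter = 20L) {
  wca <- .ca_coords(wild)
  mca <- .ca_coords(member)
  if (nrow(wca$coords) < 4 || nrow(mca$coords) < 4)
    stop("both structures need CA atoms in at least 4 residues")
  seed <- global_seq_align(sequence_of(wild), sequence_of(member))
  pairs <- .aligned_pairs(seed$a_aligned, seed$b_aligned)
  # map chain positions to CA-bearing residues
  pairs <- pairs[pairs[, 1] %in% seq_len(nrow(wild$residues)) &
                 pairs[, 2] %in% seq_len(nrow(member$residues)), ,
                 drop = FALSE]
  wi <- match(pairs[, 1], wca$res_index)
  mi <- match(pairs[, 2], mca$res_index)
  ok <- !is.na(wi) & !is.na(mi)
  pairs <- cbind(wca$res_index[wi[ok]], mca$res_index[mi[ok]])
  if (nrow(pairs) < 3) stop("fewer than 3 seed pairs")
  rmsd <- NA_real_
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    fit <- kabsch_superpose(
      mca$coords[match(pairs[, 2], mca$res_index), , drop = FALSE],
      wca$coords[match(pairs[, 1], wca$res_index), , drop = FALSE])
    rmsd <- fit$rmsd
    moved <- sweep(mca$coords %*% t(fit$rotation), 2, fit$translation, "+")
    # mutually nearest CA pairs within the cutoff
    d2 <- outer(rowSums(wca$coords^2), rowSums(moved^2), "+") -
      2 * wca$coords %*% t(moved)
    d2[d2 < 0] <- 0
    nn_w <- apply(d2, 1, which.min)
    nn_m <- apply(d2, 2, which.min)
    mutual <- which(nn_m[nn_w] == seq_along(nn_w))
    dist_ok <- sqrt(d2[cbind(mutual, nn_w[mutual])]) <= cutoff
    cand <- cbind(wca$res_index[mutual[dist_ok]],
                  mca$res_index[nn_w[mutual[dist_ok]]])
    if (nrow(cand) < 3) break
    cand <- .lis_rows(cand)
    stopifnot(all(diff(cand[, 1]) > 0), all(diff(cand[, 2]) > 0))
    if (nrow(cand) == nrow(pairs) && all(cand == pairs)) break
    pairs <- cand
  }
  fit <- kabsch_superpose(
    mca$coords[match(pairs[, 2], mca$res_index), , drop = FALSE],
    wca$coords[match(pairs[, 1], wca$res_index), , drop = FALSE])
  structure(list(pairs = unname(pairs), rmsd = fit$rmsd,
                 iterations = iterations),
            class = "correspondence")
}

#' @export
print.correspondence <- function(x, ...) {
  cat(sprintf("<correspondence: %d pairs, rmsd %.3f A, %d iterations>\n",
              nrow(x$pairs), x$rmsd, x$iterations))
  invisible(x)
}

#' Assemble the family alignment in wild-type column coordinates
#'
#' Columns are exactly the wild-type residue positions 1..L; each family
#' member's residues are placed at the columns their structural
#' correspondence maps to (gaps elsewhere; member residues pairing
#' outside wild positions are dropped). The mutant row is placed by
#' identity when its length equals L, otherwise by global sequence
#' alignment (insertions relative to the wild type are dropped with a
#' warning). Members whose alignment fails are skipped with a warning.
#'
#' @param wild wild-type `prot_structure`.
#' @param members named list of `prot_structure` objects.
#' @param mutant_seq mutant amino-acid sequence (string), or `NULL`.
#' @param cutoff,max_iter passed to [structural_align_pair()].
#' @return a `family_alignment`: list with `columns` (wild residue
#'   table), `rows` (character matrix rows x L; first rows `mutant` (if
#'   given) and `wild`), `row_ids`, `correspondences` (per member), and
#'   `failed` (character vector of skipped member ids).
#' @export
assemble_family_alignment <- function(wild, members = list(),
                                      mutant_seq = NULL, cutoff = 5.0,
                                      max_iter = 20L) {
  L <- nrow(wild$residues)
  wild_row <- wild$residues$one_letter
  rows <- list()
  ids <- character(0)
  if (!is.null(mutant_seq)) {
    mut <- toupper(gsub("\\s", "", mutant_seq))
    if (nchar(mut) == L) {
      mrow <- strsplit(mut, "")[[1]]
    } else {
      al <- global_seq_align(paste(wild_row, collapse = ""), mut)
      wa <- strsplit(al$a_aligned, "")[[1]]
      ba <- strsplit(al$b_aligned, "")[[1]]
      mrow <- ba[wa != "-"]             # drop insertions relative to wild
      if (any(ba[wa == "-"] != "-"))
        warning("mutant insertions relative to the wild type were dropped")
    }
    rows[["mutant"]] <- mrow
    ids <- c(ids, "mutant")
  }
  rows[["wild"]] <- wild_row
  ids <- c(ids, wild$id)
  corr <- list()
  failed <- character(0)
  for (nm in names(members)) {
    res <- tryCatch(
      structural_align_pair(wild, members[[nm]], cutoff, max_iter),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("family member ", nm, " skipped: ", conditionMessage(res))
      failed <- c(failed, nm)
      next
    }
    corr[[nm]] <- res
    row <- rep("-", L)
    keep <- res$pairs[, 1] >= 1 & res$pairs[, 1] <= L
    row[res$pairs[keep, 1]] <-
      members[[nm]]$residues$one_letter[res$pairs[keep, 2]]
    rows[[nm]] <- row
    ids <- c(ids, members[[nm]]$id)
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- NULL
  structure(list(columns = wild$residues, rows = mat, row_ids = ids,
                 correspondences = corr, failed = failed),
            class = "family_alignment")
}

#' @export
print.family_alignment <- function(x, ...) {
  cat(sprintf("<family_alignment: %d rows x %d columns (%d members%s)>\n",
              nrow(x$rows), ncol(x$rows), length(x$correspondences),
              if (length(x$failed)) paste0(", ", length(x$failed), " failed")
              else ""))
  invisible(x)
}

#' Detect point mutations between the wild and mutant rows
#'
#' One record per alignment column where both letters are present and
#' differ. The real (author) position comes from the wild-type
#' structure; a dG-change value is attached when the optional table has a
#' matching (wild_res, real_position, mut_res) row, otherwise the bin is
#' `"not calculated"`.
#'
#' @param wild_row,mutant_row character vectors of length L (letters or
#'   `"-"`).
#' @param x the wild-type `prot_structure` (defines real positions).
#' @param ddg_table optional data frame with columns `wild_res`,
#'   `real_position`, `mut_res`, `ddg` (kcal/mol, positive
#'   destabilizing).
#' @param bin_edges passed to [ddg_bin()].
#' @return data frame with `column`, `wild_res`, `mut_res`,
#'   `real_position`, `ddg`, `ddg_bin`.
#' @export
detect_mutations <- function(wild_row, mutant_row, x, ddg_table = NULL,
                             bin_edges = c(-1.5, -0.5, 0.5, 1.5)) {
  stopifnot(length(wild_row) == length(mutant_row))
  if (all(mutant_row == "-")) stop("mutant row is all gaps")
  diffs <- which(wild_row != "-" & mutant_row != "-" &
                 wild_row != mutant_row)
  out <- data.frame(
    column = diffs,
    wild_res = wild_row[diffs],
    mut_res = mutant_row[diffs],
    real_position = x$residues$res_seq[diffs],
    ddg = rep(NA_real_, length(diffs)),
    stringsAsFactors = FALSE)
  if (!is.null(ddg_table) && nrow(out) > 0) {
    key <- paste(out$wild_res, out$real_position, out$mut_res)
    tk <- paste(ddg_table$wild_res, ddg_table$real_position,
                ddg_table$mut_res)
    out$ddg <- ddg_table$ddg[match(key, tk)]
  }
  out$ddg_bin <- vapply(out$ddg, ddg_bin, "", bin_edges = bin_edges)
  out
}

#' Export a family alignment as gapped FASTA plus a column map
#'
#' @param fa a `family_alignment`.
#' @param fasta_path output FASTA path.
#' @param map_path optional TSV path for the (column, member, member real
#'   position) mapping.
#' @param members the named member list used to assemble `fa` (needed for
#'   real positions in the map; optional).
#' @return `fasta_path`, invisibly.
#' @export
write_alignment_fasta <- function(fa, fasta_path, map_path = NULL,
                                  members = NULL) {
  stopifnot(inherits(fa, "family_alignment"))
  lines <- character(0)
  for (r in seq_len(nrow(fa$rows))) {
    lines <- c(lines, paste0(">", fa$row_ids[r]),
               paste(fa$rows[r, ], collapse = ""))
  }
  writeLines(lines, fasta_path)
  if (!is.null(map_path)) {
    maps <- list()
    for (nm in names(fa$correspondences)) {
      p <- fa$correspondences[[nm]]$pairs
      real <- if (!is.null(members) && nm %in% names(members))
        members[[nm]]$residues$res_seq[p[, 2]] else p[, 2]
      maps[[nm]] <- data.frame(column = p[, 1], member = nm,
                               member_position = real,
                               stringsAsFactors = FALSE)
    }
    map <- if (length(maps)) do.call(rbind, maps) else
      data.frame(column = integer(0), member = character(0),
                 member_position = integer(0))
    rownames(map) <- NULL
    write.table(map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Read a dG-change table
#' @param path TSV with columns `wild_res`, `real_position`, `mut_res`,
#'   `ddg`.
#' @return data frame.
#' @export
read_ddg_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("wild_res", "real_position", "mut_res", "ddg")
  if (!all(need %in% names(tab)))
    stop("ddg table needs columns: ", paste(need, collapse = ", "))
  tab
}
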