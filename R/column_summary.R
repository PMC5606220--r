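#' Residue color schemes
#'
#' The three physicochemical grouping schemes used for conservativeness
#' and row clustering:
#' * **CINEMA** — 6 groups: polar positive \{H,K,R\}, polar negative
#'   \{D,E\}, polar neutral \{N,Q,S,T\}, nonpolar aliphatic
#'   \{A,G,I,L,M,V\}, nonpolar rings \{F,P,W,Y\}, cysteine \{C\}.
#' * **CLUSTAL** — 4 groups: \{G,P,S,T\}, \{H,K,R\}, \{F,W,Y\},
#'   \{I,L,M,V\}; the remaining letters are ungrouped.
#' * **LESK** — 5 groups: small nonpolar \{G,A,S,T\}, hydrophobic
#'   \{C,V,I,L,P,F,Y,M,W\}, polar \{N,Q,H\}, negatively charged \{D,E\},
#'   positively charged \{K,R\}.
#'
#' @param name scheme name.
#' @return named list of character vectors (group -> letters).
#' @export
color_scheme <- function(name = c("CINEMA", "CLUSTAL", "LESK")) {
  name <- match.arg(name)
  switch(name,
    CINEMA = list(
      polar_positive = c("H", "K", "R"),
      polar_negative = c("D", "E"),
      polar_neutral = c("N", "Q", "S", "T"),
      nonpolar_aliphatic = c("A", "G", "I", "L", "M", "V"),
      nonpolar_rings = c("F", "P", "W", "Y"),
      cysteine = "C"),
    CLUSTAL = list(
      small = c("G", "P", "S", "T"),
      basic = c("H", "K", "R"),
      aromatic = c("F", "W", "Y"),
      aliphatic = c("I", "L", "M", "V")),
    LESK = list(
      small_nonpolar = c("G", "A", "S", "T"),
      hydrophobic = c("C", "V", "I", "L", "P", "F", "Y", "M", "W"),
      polar = c("N", "Q", "H"),
      negative = c("D", "E"),
      positive = c("K", "R")))
}

.scheme_group_of <- function(letter, scheme) {
  for (g in names(scheme)) if (letter %in% scheme[[g]]) return(g)
  NA_character_
}

#' Column conservation
#'
#' Residue frequencies over the non-gap cells of one alignment column,
#' the maximum conservation percentage, and the gap fraction.
#'
#' @param cells character vector of letters / `"-"`.
#' @return list with `frequencies` (named fractions over non-gap cells),
#'   `max_pct`, `gap_fraction`; all-gap columns return `NA` statistics
#'   with `all_gap = TRUE`.
#' @export
conservation <- function(cells) {
  ng <- cells[cells != "-"]
  if (length(ng) == 0) {
    return(list(frequencies = numeric(0), max_pct = NA_real_,
                gap_fraction = 1, all_gap = TRUE))
  }
  tab <- table(ng)
  freq <- as.numeric(tab) / length(ng)
  names(freq) <- names(tab)
  list(frequencies = sort(freq, decreasing = TRUE),
       max_pct = 100 * max(freq),
       gap_fraction = 1 - length(ng) / length(cells),
       all_gap = FALSE)
}

#' Sequence-logo information content of a column
#'
#' Schneider-Stephens information content over the 20-letter alphabet
#' without small-sample correction: `bits = log2(20) - H`, where `H` is
#' the Shannon entropy (bits) of the non-gap letter frequencies. Letter
#' heights are `frequency * bits`.
#'
#' @param cells character vector of letters / `"-"`.
#' @return list with `bits` and `heights` (named numeric).
#' @export
logo_information <- function(cells) {
  cons <- conservation(cells)
  if (isTRUE(cons$all_gap)) return(list(bits = NA_real_, heights = numeric(0)))
  f <- cons$frequencies
  H <- -sum(f * log2(f))
  bits <- max(0, log2(20) - H)
  list(bits = bits, heights = f * bits)
}

#' Column mean and standard deviation of a property
#'
#' Arithmetic mean and population standard deviation (divide by n) over
#' the rows with a value; rows that are gaps at this column are excluded
#' by passing only non-gap values.
#'
#' @param values numeric vector of per-row property values (`NA` ignored).
#' @return list with `mu` and `sigma`; both `NA` when no values.
#' @export
summarize_property <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0) return(list(mu = NA_real_, sigma = NA_real_))
  mu <- mean(v)
  list(mu = mu, sigma = sqrt(mean((v - mu)^2)))
}

#' Conservativeness of a substitution under a color scheme
#'
#' Conservative iff both residues share a group; `"unclassified"` when
#' either letter is ungrouped in the scheme (possible under CLUSTAL).
#'
#' @param wild_res,mut_res single residue letters.
#' @param scheme scheme name or list from [color_scheme()].
#' @return `"conservative"`, `"non-conservative"` or `"unclassified"`.
#' @export
classify_conservativeness <- function(wild_res, mut_res,
                                      scheme = "CINEMA") {
  if (is.character(scheme) && length(scheme) == 1)
    scheme <- color_scheme(scheme)
  valid <- unname(unlist(.AA321))
  if (!wild_res %in% valid || !mut_res %in% valid)
    stop("invalid residue letter: ", wild_res, "/", mut_res)
  ga <- .scheme_group_of(wild_res, scheme)
  gb <- .scheme_group_of(mut_res, scheme)
  if (is.na(ga) || is.na(gb)) return("unclassified")
  if (ga == gb) "conservative" else "non-conservative"
}

#' Bin a folding free-energy change
#'
#' Interval lookup on the four default edges (kcal/mol, positive
#' destabilizing): `<= -1.5` highly stabilizing, `(-1.5, -0.5]`
#' stabilizing, `(-0.5, 0.5)` neutral, `[0.5, 1.5)` destabilizing,
#' `>= 1.5` highly destabilizing; a missing value is `"not calculated"`.
#'
#' @param ddg numeric or `NA`.
#' @param bin_edges four strictly increasing edges.
#' @return bin label.
#' @export
ddg_bin <- function(ddg, bin_edges = c(-1.5, -0.5, 0.5, 1.5)) {
  stopifnot(length(bin_edges) == 4, all(diff(bin_edges) > 0))
  if (is.na(ddg)) return("not calculated")
  if (ddg <= bin_edges[1]) "highly stabilizing"
  else if (ddg <= bin_edges[2]) "stabilizing"
  else if (ddg < bin_edges[3]) "neutral"
  else if (ddg < bin_edges[4]) "destabilizing"
  else "highly destabilizing"
}

#' Per-column summary table over a family alignment
#'
#' For every wild-type column: residue frequencies and maximum
#' conservation, gap fraction, logo information, mean/population-sigma of
#' each numeric property supplied, and per-kind interaction conservation
#' (the percentage of non-gap rows whose residue establishes that kind
#' in its own structure).
#'
#' Properties and graphs are supplied per row id: `properties` maps
#' row id -> data frame with `res_index` plus numeric columns;
#' `graphs` maps row id -> `residue_graph`. The wild-type row uses the
#' column index directly; member rows are mapped through their stored
#' correspondences.
#'
#' @param fa a `family_alignment`.
#' @param properties named list (by row id) of per-residue property data
#'   frames (must contain `res_index`).
#' @param graphs named list (by row id) of `residue_graph` objects.
#' @param include_mutant_row logical: count the mutant row in
#'   conservation statistics (default `FALSE`; the mutant is a sequence,
#'   not a structure).
#' @return data frame with one row per column.
#' @export
summarize_columns <- function(fa, properties = list(), graphs = list(),
                              include_mutant_row = FALSE) {
  stopifnot(inherits(fa, "family_alignment"))
  L <- ncol(fa$rows)
  row_names <- rownames(fa$rows)
  use_rows <- row_names[row_names != "mutant" | include_mutant_row]
  # column index of each row's residues: wild = identity, members via pairs
  col_of <- list()
  for (nm in use_rows) {
    if (nm == "wild") {
      col_of[[nm]] <- cbind(seq_len(L), seq_len(L))
    } else if (nm %in% names(fa$correspondences)) {
      col_of[[nm]] <- fa$correspondences[[nm]]$pairs[, c(1, 2), drop = FALSE]
    }
  }
  prop_names <- character(0)
  for (nm in names(properties)) {
    pn <- setdiff(names(properties[[nm]]),
                  c("res_index", "res_seq", "res_name", "one_letter",
                    "icode"))
    prop_names <- union(prop_names, pn[vapply(properties[[nm]][pn],
                                              is.numeric, TRUE)])
  }
  rows_out <- vector("list", L)
  for (col in seq_len(L)) {
    cells <- fa$rows[use_rows, col]
    cons <- conservation(cells)
    logo <- logo_information(cells)
    rec <- list(column = col,
                wild_res = fa$columns$one_letter[col],
                real_position = fa$columns$res_seq[col],
                max_conservation = cons$max_pct,
                gap_fraction = cons$gap_fraction,
                logo_bits = logo$bits)
    # property mu/sigma across rows with a structural residue here
    for (pn in prop_names) {
      vals <- c()
      for (nm in use_rows) {
        if (!nm %in% names(col_of) || !nm %in% names(properties)) next
        m <- col_of[[nm]]
        hit <- m[m[, 1] == col, 2]
        if (length(hit) == 1) {
          pr <- properties[[nm]]
          v <- pr[[pn]][match(hit, pr$res_index)]
          vals <- c(vals, v)
        }
      }
      st <- summarize_property(vals)
      rec[[paste0(pn, "_mu")]] <- st$mu
      rec[[paste0(pn, "_sigma")]] <- st$sigma
    }
    # interaction conservation per kind
    ic <- .interaction_conservation_at(col, col_of, graphs)
    for (kind in .INTERACTION_KINDS)
      rec[[paste0(.KIND_ALIASES[[kind]], "_pct")]] <- ic[[kind]]
    rows_out[[col]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows_out)
  rownames(out) <- NULL
  out
}

.interaction_conservation_at <- function(col, col_of, graphs) {
  out <- setNames(rep(NA_real_, length(.INTERACTION_KINDS)),
                  .INTERACTION_KINDS)
  for (kind in .INTERACTION_KINDS) {
    n_has <- 0L
    n_tot <- 0L
    for (nm in names(col_of)) {
      if (!nm %in% names(graphs)) next   # member lacking a graph: excluded
      m <- col_of[[nm]]
      hit <- m[m[, 1] == col, 2]
      if (length(hit) != 1) next         # gap row at this column
      n_tot <- n_tot + 1L
      rg <- graphs[[nm]]
      inc <- rg$edges[rg$edges$i == hit | rg$edges$j == hit, , drop = FALSE]
      kinds <- unlist(strsplit(inc$kinds, ",", fixed = TRUE))
      if (kind %in% kinds) n_has <- n_has + 1L
    }
    out[kind] <- if (n_tot > 0) 100 * n_has / n_tot else NA_real_
  }
  out
}

#' Interaction conservation of one alignment column
#'
#' For each interaction kind, the percentage of non-gap rows whose
#' linked structural residue establishes at least one incident edge of
#' that kind in its own residue graph. Rows without a residue graph are
#' excluded from the denominator.
#'
#' @param fa a `family_alignment`.
#' @param column alignment column (wild-type position).
#' @param graphs named list (by row id, `"wild"` for the wild type) of
#'   `residue_graph` objects.
#' @return named numeric vector of percentages over the six kinds.
#' @export
interaction_conservation <- function(fa, column, graphs) {
  stopifnot(inherits(fa, "family_alignment"),
            column >= 1, column <= ncol(fa$rows))
  col_of <- list(wild = cbind(seq_len(ncol(fa$rows)),
                              seq_len(ncol(fa$rows))))
  for (nm in names(fa$correspondences))
    col_of[[nm]] <- fa$correspondences[[nm]]$pairs[, c(1, 2), drop = FALSE]
  .interaction_conservation_at(column, col_of, graphs)
}

#' Columns at or above a conservation threshold
#' @param summaries output of [summarize_columns()].
#' @param threshold percentage in (0, 100].
#' @return integer vector of column indices, ascending.
#' @export
frequent_columns <- function(summaries, threshold) {
  stopifnot(threshold > 0, threshold <= 100)
  sort(summaries$column[!is.na(summaries$max_conservation) &
                        summaries$max_conservation >= threshold])
}

#' Top N columns by average property value
#'
#' Stable sort on the column's property mean; ties break toward the
#' lower column index. `direction = "top-down"` ranks descending,
#' `"bottom-up"` ascending.
#'
#' @param summaries output of [summarize_columns()].
#' @param property property name (a `<property>_mu` column must exist).
#' @param n number of columns to return.
#' @param direction `"top-down"` or `"bottom-up"`.
#' @return integer vector of column indices, best first.
#' @export
top_n_columns_by_average <- function(summaries, property, n,
                                     direction = c("top-down", "bottom-up")) {
  direction <- match.arg(direction)
  stopifnot(n >= 1)
  mu_col <- paste0(property, "_mu")
  if (!mu_col %in% names(summaries)) stop("unknown property: ", property)
  mu <- summaries[[mu_col]]
  ok <- !is.na(mu)
  key <- if (direction == "top-down") -mu[ok] else mu[ok]
  ord <- order(key, summaries$column[ok])
  head(summaries$column[ok][ord], n)
}

#' Order alignment rows by EM clustering
#'
#' Rows are encoded as per-column group-membership indicator vectors
#' under the chosen color scheme, reduced by principal components when
#' the dimension exceeds the number of rows, and fitted with a
#' diagonal-covariance Gaussian mixture for k = 1..min(8, rows/3 + 1)
#' components, selecting k by BIC. The returned ordering groups rows by
#' mixture component, within a component by descending posterior
#' probability, so similar rows sit next to each other.
#'
#' @param fa a `family_alignment`.
#' @param scheme scheme name or group list.
#' @param seed integer seed (EM initialization is deterministic given
#'   the seed).
#' @return integer permutation of `seq_len(nrow(fa$rows))`.
#' @export
cluster_rows_em <- function(fa, scheme = "CINEMA", seed = 1L) {
  stopifnot(inherits(fa, "family_alignment"))
  n <- nrow(fa$rows)
  if (n < 2) {
    warning("fewer than 2 rows: identity ordering")
    return(seq_len(n))
  }
  if (is.character(scheme)) scheme <- color_scheme(scheme)
  groups <- names(scheme)
  # one-hot group membership per column
  feat <- matrix(0, n, ncol(fa$rows) * length(groups))
  for (r in seq_len(n)) {
    for (col in seq_len(ncol(fa$rows))) {
      g <- .scheme_group_of(fa$rows[r, col], scheme)
      if (!is.na(g)) {
        feat[r, (col - 1) * length(groups) + match(g, groups)] <- 1
      }
    }
  }
  keep <- apply(feat, 2, function(v) length(unique(v)) > 1)
  if (!any(keep)) return(seq_len(n))        # all rows identical
  feat <- feat[, keep, drop = FALSE]
  if (ncol(feat) > max(2, n - 2)) {
    pc <- prcomp(feat, center = TRUE, scale. = FALSE)
    k <- which(pc$sdev > 1e-8)              # drop rank-deficient directions
    k <- k[k <= min(max(2, n - 2), 10)]
    feat <- pc$x[, k, drop = FALSE]
  }
  gmax <- min(8, floor(n / 3) + 1)
  models <- if (ncol(feat) == 1) c("E", "V") else c("EII", "VII")
  old <- .Random.seed_exists()
  set.seed(seed)
  # tiny deterministic regularization keeps duplicated rows from
  # producing singular within-component covariances
  feat <- feat + matrix(rnorm(length(feat), sd = 1e-6), nrow(feat))
  fit <- tryCatch(
    suppressWarnings(Mclust(feat, G = seq_len(gmax),
                            modelNames = models,
                            verbose = FALSE)),
    error = function(e) NULL)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  if (is.null(fit)) return(seq_len(n))
  cls <- fit$classification
  post <- if (is.matrix(fit$z)) fit$z[cbind(seq_len(n), cls)] else rep(1, n)
  order(cls, -post, seq_len(n))
}

#' Flag candidate critical positions
#'
#' A column is flagged when its all-atoms relative accessibility is both
#' low and conserved (mean `<= t_acc`, sigma `<= t_sd`) and its
#' hydrophobic-interaction conservation is high (`>= t_hyd`): buried,
#' invariant positions anchored by conserved hydrophobic packing, where
#' substitutions tend to be structurally damaging. The flags are
#' screening hints, not verdicts.
#'
#' @param summaries output of [summarize_columns()] (needs
#'   `all_atoms_rel_mu`, `all_atoms_rel_sigma`, `hydrophobic_pct`).
#' @param t_acc,t_sd accessibility mean/sigma thresholds (percent).
#' @param t_hyd hydrophobic conservation threshold (percent).
#' @return data frame with `column`, `real_position`, the three values
#'   and a `rationale` string, one row per flagged column.
#' @export
flag_critical_positions <- function(summaries, t_acc = 10.0, t_sd = 10.0,
                                    t_hyd = 80.0) {
  need <- c("all_atoms_rel_mu", "all_atoms_rel_sigma", "hydrophobic_pct")
  if (!all(need %in% names(summaries)))
    stop("summaries lack accessibility/hydrophobic columns; run the ",
         "pipeline with accessibility and contacts enabled")
  mu <- summaries$all_atoms_rel_mu
  sd_ <- summaries$all_atoms_rel_sigma
  hyd <- summaries$hydrophobic_pct
  flag <- !is.na(mu) & !is.na(sd_) & !is.na(hyd) &
    mu <= t_acc & sd_ <= t_sd & hyd >= t_hyd
  idx <- which(flag)
  data.frame(
    column = summaries$column[idx],
    real_position = summaries$real_position[idx],
    accessibility_mu = mu[idx],
    accessibility_sigma = sd_[idx],
    hydrophobic_pct = hyd[idx],
    rationale = sprintf(
      "accessibility mu %.2f <= %.1f, sigma %.2f <= %.1f, hydrophobic %.1f%% >= %.1f%%",
      mu[idx], t_acc, sd_[idx], t_sd, hyd[idx], t_hyd),
    stringsAsFactors = FALSE)
}

#' Assess detected mutations against the column summaries
#'
#' Joins each mutation record with its column summary excerpt, the
#' conservativeness under the chosen scheme, and the critical-position
#' flag.
#'
#' @param mutations output of [detect_mutations()].
#' @param summaries output of [summarize_columns()].
#' @param scheme scheme name.
#' @param critical output of [flag_critical_positions()] (optional).
#' @return data frame of mutation assessments.
#' @export
assess_mutations <- function(mutations, summaries, scheme = "CINEMA",
                             critical = NULL) {
  if (nrow(mutations) == 0) {
    mutations$conservativeness <- character(0)
    mutations$critical <- logical(0)
    return(mutations)
  }
  mutations$conservativeness <- mapply(
    classify_conservativeness, mutations$wild_res, mutations$mut_res,
    MoreArgs = list(scheme = scheme))
  m <- match(mutations$column, summaries$column)
  for (cc in c("max_conservation", "logo_bits", "all_atoms_rel_mu",
               "all_atoms_rel_sigma", "hydrophobic_pct")) {
    if (cc %in% names(summaries)) mutations[[cc]] <- summaries[[cc]][m]
  }
  mutations$critical <- if (!is.null(critical))
    mutations$column %in% critical$column else NA
  mutations
}
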