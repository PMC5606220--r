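test_that("conservation reports frequencies over non-gap cells", {
  c1 <- conservation(c("R", "R", "R", "H"))
  expect_equal(unname(c1$frequencies["R"]), 0.75)
  expect_equal(unname(c1$frequencies["H"]), 0.25)
  expect_equal(c1$max_pct, 75)
  expect_equal(conservation(rep("I", 5))$max_pct, 100)
  c2 <- conservation(c("R", "-", "R", "R"))
  expect_equal(unname(c2$frequencies["R"]), 1)
  expect_equal(c2$gap_fraction, 0.25)
  c3 <- conservation(rep("-", 3))
  expect_true(c3$all_gap)
  expect_true(is.na(c3$max_pct))
  expect_equal(sum(c1$frequencies), 1, tolerance = 1e-12)
})

test_that("logo information implements Schneider-Stephens content", {
  aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  expect_equal(logo_information(aa20)$bits, 0, tolerance = 1e-12)
  single <- logo_information(rep("W", 7))
  expect_equal(single$bits, log2(20), tolerance = 1e-12)
  half <- logo_information(c("A", "A", "G", "G"))
  expect_equal(half$bits, log2(20) - 1, tolerance = 1e-12)  # H = 1 bit
  expect_equal(unname(half$heights["A"]), 0.5 * (log2(20) - 1))
  expect_true(all(logo_information(c("A", "C", "C"))$bits >= 0))
})

test_that("summarize_property uses population sigma and ignores NA", {
  s <- summarize_property(c(2, 4))
  expect_equal(s$mu, 3)
  expect_equal(s$sigma, 1)
  expect_equal(summarize_property(rep(7, 5))$sigma, 0)
  set.seed(21)
  v <- rnorm(50)
  s2 <- summarize_property(v)
  # independent two-pass computation
  mu <- sum(v) / length(v)
  expect_equal(s2$mu, mu, tolerance = 1e-12)
  expect_equal(s2$sigma, sqrt(sum((v - mu)^2) / length(v)), tolerance = 1e-12)
  expect_true(is.na(summarize_property(c(NA, NA))$mu))
})

test_that("conservativeness follows the color-scheme groups", {
  expect_equal(classify_conservativeness("R", "H", "CINEMA"), "conservative")
  expect_equal(classify_conservativeness("I", "T", "CINEMA"),
               "non-conservative")
  expect_equal(classify_conservativeness("A", "D", "CLUSTAL"), "unclassified")
  expect_equal(classify_conservativeness("G", "T", "CLUSTAL"), "conservative")
  expect_equal(classify_conservativeness("C", "W", "LESK"), "conservative")
  expect_error(classify_conservativeness("B", "A"), "invalid residue")
  # symmetry over all letter pairs and schemes
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (scheme in c("CINEMA", "CLUSTAL", "LESK")) {
    for (k in 1:30) {
      p <- sample(aa, 2)
      expect_equal(classify_conservativeness(p[1], p[2], scheme),
                   classify_conservativeness(p[2], p[1], scheme))
    }
  }
})

test_that("scheme definitions partition as documented", {
  cin <- color_scheme("CINEMA")
  expect_length(cin, 6)
  expect_setequal(unlist(cin), c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                                 "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                                 "W", "Y"))
  expect_setequal(cin$polar_positive, c("H", "K", "R"))
  clu <- color_scheme("CLUSTAL")
  expect_length(clu, 4)
  expect_equal(length(unlist(clu)), 14)    # six letters ungrouped
  lesk <- color_scheme("LESK")
  expect_length(lesk, 5)
  expect_setequal(unname(unlist(lesk)), unname(unlist(cin)))
})

test_that("ddg binning covers the default edges and missing values", {
  expect_equal(ddg_bin(NA), "not calculated")
  expect_equal(ddg_bin(0), "neutral")
  expect_equal(ddg_bin(5), "highly destabilizing")
  expect_equal(ddg_bin(1.0), "destabilizing")
  expect_equal(ddg_bin(-1.0), "stabilizing")
  expect_equal(ddg_bin(-5), "highly stabilizing")
  expect_error(ddg_bin(1, bin_edges = c(1, 0, 2, 3)))
})

test_that("frequent_columns and top_n ranking follow thresholds and ties", {
  summaries <- data.frame(column = 1:3,
                          max_conservation = c(100, 75, 90),
                          x_mu = c(5, 9, 1))
  expect_equal(frequent_columns(summaries, 100), 1)
  expect_equal(frequent_columns(summaries, 50), 1:3)
  expect_error(frequent_columns(summaries, 101))
  expect_equal(top_n_columns_by_average(summaries, "x", 1, "top-down"), 2)
  expect_equal(top_n_columns_by_average(summaries, "x", 1, "bottom-up"), 3)
  tie <- data.frame(column = 1:2, x_mu = c(7, 7))
  expect_equal(top_n_columns_by_average(tie, "x", 1, "top-down"), 1)
  expect_error(top_n_columns_by_average(summaries, "zz", 1), "unknown")
})

make_abstract_alignment <- function(rows_chr, wild) {
  rows <- do.call(rbind, lapply(rows_chr, function(s) strsplit(s, "")[[1]]))
  rownames(rows) <- names(rows_chr)
  structure(list(columns = wild$residues, rows = rows,
                 row_ids = names(rows_chr), correspondences = list(),
                 failed = character(0)),
            class = "family_alignment")
}

test_that("EM row clustering groups planted blocks contiguously", {
  w <- fixture_mini_chain("AGSLKT")
  rows <- rep(c("AGSLKT", "DEDEDE"), 5)
  names(rows) <- paste0("r", 1:10)
  fa <- make_abstract_alignment(as.list(rows), w)
  ord <- cluster_rows_em(fa, "CINEMA", seed = 3)
  expect_setequal(ord, 1:10)               # a permutation, nothing lost
  lab <- rep(c(1, 2), 5)[ord]
  expect_true(all(diff(which(lab == 1)) == 1))
  expect_true(all(diff(which(lab == 2)) == 1))
  expect_equal(cluster_rows_em(fa, "CINEMA", seed = 3), ord)  # deterministic
})

test_that("EM clustering recovers a planted 3-cluster partition exactly", {
  w <- fixture_mini_chain("AGSLKT")
  pats <- c("KRHKRH", "DEDEDE", "AGSLKT")
  rows <- as.list(rep(pats, 4))             # interleaved cluster labels
  names(rows) <- paste0("r", seq_along(rows))
  truth <- rep(1:3, 4)
  fa <- make_abstract_alignment(rows, w)
  ord <- cluster_rows_em(fa, "CINEMA", seed = 5)
  expect_setequal(ord, seq_along(rows))
  # adjusted Rand index of the induced contiguous grouping vs planted labels
  grouped <- truth[ord]
  blocks <- cumsum(c(1, diff(match(grouped, unique(grouped))) != 0))
  ari <- mclust::adjustedRandIndex(grouped, blocks)
  expect_equal(ari, 1.0)
})

test_that("identical rows keep input order and tiny families warn", {
  w <- fixture_mini_chain("AGSLKT")
  rows <- as.list(rep("AGSLKT", 4))
  names(rows) <- paste0("r", 1:4)
  fa <- make_abstract_alignment(rows, w)
  expect_equal(cluster_rows_em(fa, "CINEMA", seed = 1), 1:4)
  one <- make_abstract_alignment(list(r1 = "AGSLKT"), w)
  expect_warning(ord <- cluster_rows_em(one), "fewer than 2")
  expect_equal(ord, 1L)
})

test_that("interaction conservation counts rows establishing each kind", {
  w <- fixture_helical()
  set.seed(23)
  m1 <- transform_structure(w, random_rotation(), c(3, 1, 0), id = "m1.A")
  m2 <- transform_structure(w, random_rotation(), c(0, 5, 2), id = "m2.A")
  fa <- assemble_family_alignment(w, list(m1 = m1, m2 = m2))
  rg <- project_residue_graph(build_atom_graph(w))
  graphs <- list(wild = rg, m1 = rg, m2 = rg)  # rigid copies: same graph
  sums <- summarize_columns(fa, graphs = graphs)
  expect_gt(nrow(rg$edges), 0)
  for (col in seq_len(nrow(w$residues))) {
    ic <- interaction_conservation(fa, col, graphs)
    manual_kinds <- unlist(strsplit(
      rg$edges$kinds[rg$edges$i == col | rg$edges$j == col], ","))
    for (kind in names(ic)) {
      expect_equal(unname(ic[kind]),
                   if (kind %in% manual_kinds) 100 else 0)
    }
  }
  # member lacking a graph is excluded from the denominator
  ic2 <- interaction_conservation(fa, 1, graphs[c("wild", "m1")])
  expect_false(any(is.na(ic2)))
})

test_that("gap rows are excluded from interaction conservation", {
  w <- fixture_helical()
  rg <- project_residue_graph(build_atom_graph(w))
  atoms <- w$atoms[w$atoms$res_index != 1, ]
  mdel <- rinmut:::.new_structure(atoms, "mdel.A")
  fa <- assemble_family_alignment(w, list(mdel = mdel))
  rg_del <- project_residue_graph(build_atom_graph(mdel))
  ic <- interaction_conservation(fa, 1, list(wild = rg, mdel = rg_del))
  # only the wild row is non-gap at column 1
  kinds1 <- unlist(strsplit(rg$edges$kinds[rg$edges$i == 1 |
                                           rg$edges$j == 1], ","))
  for (kind in names(ic))
    expect_equal(unname(ic[kind]), if (kind %in% kinds1) 100 else 0)
})

test_that("critical-position flags follow thresholds and are monotone", {
  summaries <- data.frame(
    column = 1:3, real_position = 11:13,
    all_atoms_rel_mu = c(0.3, 30, 5),
    all_atoms_rel_sigma = c(0.6, 6, 2),
    hydrophobic_pct = c(98, 8, 85))
  fl <- flag_critical_positions(summaries)
  expect_setequal(fl$column, c(1, 3))    # buried + conserved hydrophobic
  expect_false(2 %in% fl$column)         # exposed, few hydrophobic contacts
  expect_match(fl$rationale[1], "hydrophobic 98")
  none <- flag_critical_positions(summaries, t_acc = 0, t_sd = 0,
                                  t_hyd = 101)
  expect_equal(nrow(none), 0)
  # monotonicity: relaxing thresholds never removes a flagged column
  relaxed <- flag_critical_positions(summaries, t_acc = 50, t_sd = 50,
                                     t_hyd = 50)
  expect_true(all(fl$column %in% relaxed$column))
})
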