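test_that("shipped typing table follows the seven-label convention", {
  typing <- load_typing_table()
  x <- build_peptide("CSGK")
  types <- assign_atom_types(x, typing)
  at <- function(res_seq, name)
    types[[which(x$atoms$res_seq == res_seq & x$atoms$name == name)]]
  expect_equal(at(1, "SG"), "cysteine")
  expect_setequal(at(2, "OG"), c("donor", "acceptor"))
  expect_setequal(at(4, "NZ"), c("positive", "donor"))
  expect_equal(at(2, "CA"), character(0))      # intentionally untyped
  expect_equal(at(1, "N"), "donor")            # backbone
  expect_equal(at(1, "O"), "acceptor")
})

test_that("atoms missing from the typing table get empty sets with warning", {
  typing <- load_typing_table()
  typing <- typing[!(typing$res_name == "ANY" & typing$atom_name == "CA"), ]
  x <- build_peptide("G")
  expect_warning(types <- assign_atom_types(x, typing), "no typing entry")
  ca <- which(x$atoms$name == "CA")
  expect_equal(types[[ca]], character(0))
})

test_that("malformed typing tables are rejected with the offending row", {
  bad <- tempfile()
  writeLines(c("res_name\tatom_name\tlabels", "ALA\tCB\tnot_a_label"), bad)
  expect_error(load_typing_table(bad), "row 1")
})

test_that("delaunay_neighbors matches geometry on canonical configurations", {
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  e <- delaunay_neighbors(tetra)
  expect_equal(nrow(e), 6)       # a tetrahedron is its own triangulation
  expect_error(delaunay_neighbors(tetra[1:3, ]), "at least 4")

  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  pts <- rbind(cube, c(0.5, 0.5, 0.5))
  e <- delaunay_neighbors(pts)
  keypairs <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  # the center is a Delaunay neighbor of all 8 cube vertices (confirmed by
  # the empty-circumsphere oracle on the same points)
  oe <- oracle_delaunay_edges(pts)
  oc <- oe[oe[, 1] == 9 | oe[, 2] == 9, , drop = FALSE]
  expect_equal(sort(unique(c(oc))), 1:9)
  for (v in 1:8) expect_true(paste(v, 9) %in% keypairs)
})

test_that("delaunay_neighbors equals the empty-circumsphere oracle on random clouds", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(10:25, 1)
    P <- matrix(runif(3 * n, 0, 10), n, 3)
    imp <- delaunay_neighbors(P)
    imp <- imp[order(imp[, 1], imp[, 2]), , drop = FALSE]
    expect_equal(unname(imp), unname(oracle_delaunay_edges(P)),
                 info = paste("seed", seed))
  }
})

test_that("classify_pair implements the distance windows and is symmetric", {
  expect_equal(classify_pair("hydrophobic", "hydrophobic", 3.0), "hydrophobic")
  expect_equal(classify_pair("hydrophobic", "hydrophobic", 3.9), character(0))
  expect_setequal(
    classify_pair(c("positive", "donor"), c("negative", "acceptor"), 2.8),
    c("salt_bridge", "hydrogen_bond"))
  expect_equal(classify_pair("positive", "positive", 5.5), "repulsive")
  expect_equal(classify_pair("cysteine", "cysteine", 2.05), "disulfide_bridge")
  # symmetry over random type sets and distances
  vocab <- c("positive", "negative", "donor", "acceptor", "aromatic",
             "hydrophobic", "cysteine")
  set.seed(99)
  for (k in 1:50) {
    a <- sample(vocab, sample(0:3, 1))
    b <- sample(vocab, sample(0:3, 1))
    d <- runif(1, 0.5, 7)
    expect_setequal(classify_pair(a, b, d), classify_pair(b, a, d))
  }
})

test_that("peptide-bond C-N distances can never satisfy any criterion", {
  cr <- load_criteria()
  expect_true(all(cr$d_min >= 1.4))
  expect_equal(classify_pair("donor", "acceptor", 1.33), character(0))
})

test_that("planted in-window pairs produce exactly the planted interaction", {
  for (kind in names(mid_window)) {
    fx <- fixture_pair(kind, mid_window[[kind]])
    rg <- project_residue_graph(build_atom_graph(fx))
    expect_equal(nrow(rg$edges), 1, info = kind)
    expect_true(kind %in% strsplit(rg$edges$kinds, ",")[[1]], info = kind)
  }
})

test_that("occluded pairs are removed and unblocked pairs restored", {
  blocked <- fixture_blocked_pair(TRUE)
  # the blocker sits exactly on the donor-acceptor segment: every sphere
  # through the pair contains it, confirmed by the circumsphere oracle
  co <- structure_coords(blocked)
  oe <- oracle_delaunay_edges(co)
  key <- which(blocked$atoms$name %in% c("OG", "OG1"))
  expect_false(any(oe[, 1] == key[1] & oe[, 2] == key[2]))
  expect_equal(nrow(build_atom_graph(blocked)$edges), 0)
  open <- fixture_blocked_pair(FALSE)
  expect_equal(build_atom_graph(open)$edges$kinds, "hydrogen_bond")
})

test_that("atom-graph edges are Delaunay neighbors with satisfied windows", {
  fx <- fixture_helical()
  ag <- build_atom_graph(fx)
  expect_gt(nrow(ag$edges), 0)
  de <- delaunay_neighbors(structure_coords(fx))
  dkey <- paste(de[, 1], de[, 2])
  cr <- load_criteria()
  for (k in seq_len(nrow(ag$edges))) {
    e <- ag$edges[k, ]
    expect_true(paste(min(e$i, e$j), max(e$i, e$j)) %in% dkey)
    for (kind in strsplit(e$kinds, ",")[[1]]) {
      w <- cr[cr$kind == kind, ]
      expect_true(any(w$d_min <= e$distance & e$distance <= w$d_max))
    }
    expect_false(fx$atoms$res_index[e$i] == fx$atoms$res_index[e$j])
  }
})

test_that("sequence-adjacent backbone contacts are filtered by default", {
  p <- build_peptide("AAAA")
  ag_def <- build_atom_graph(p)
  bb <- p$atoms$name %in% c("N", "CA", "C", "O", "OXT")
  adj_bb <- function(ag) {
    ri <- p$atoms$res_index
    e <- ag$edges
    sum(abs(ri[e$i] - ri[e$j]) == 1 & bb[e$i] & bb[e$j])
  }
  expect_equal(adj_bb(ag_def), 0)
  ag_keep <- build_atom_graph(p, keep_adjacent_backbone = TRUE)
  expect_gt(adj_bb(ag_keep), 0)   # peptide-unit O(i)-N(i+1) hydrogen bonds
})

test_that("residue projection unions kinds and counts atomic edges", {
  # two atomic edges between residues 1 and 3 with different kinds
  spec <- list(
    list(res_name = "SER", res_seq = 1,
         atoms = list(OG = c(0, 0, 0), CB = c(0.8, -1.2, 0.4))),
    list(res_name = "ALA", res_seq = 2,
         atoms = list(CB = c(12, 12, 12))),
    list(res_name = "ASP", res_seq = 3,
         atoms = list(OD1 = c(2.5, 0, 0), CB = c(2.2, -1.5, 0.6))))
  fx <- make_fixture(spec)
  rg <- project_residue_graph(build_atom_graph(fx))
  e13 <- rg$edges[rg$edges$i == 1 & rg$edges$j == 3, ]
  expect_equal(nrow(e13), 1)
  kinds <- strsplit(e13$kinds, ",")[[1]]
  expect_true("hydrogen_bond" %in% kinds)   # OG-OD1 at 2.5
  expect_equal(e13$atomic_count,
               sum(fx$atoms$res_index[build_atom_graph(fx)$edges$i] %in% c(1, 3) &
                   fx$atoms$res_index[build_atom_graph(fx)$edges$j] %in% c(1, 3)))
})

test_that("empty atom graphs project to node-only residue graphs", {
  spec <- list(
    list(res_name = "ALA", res_seq = 1, atoms = list(CB = c(0, 0, 0))),
    list(res_name = "ALA", res_seq = 2, atoms = list(CB = c(50, 0, 0))),
    list(res_name = "ALA", res_seq = 3, atoms = list(CB = c(0, 50, 0))),
    list(res_name = "ALA", res_seq = 4, atoms = list(CB = c(0, 0, 50))))
  rg <- project_residue_graph(build_atom_graph(make_fixture(spec)))
  expect_equal(nrow(rg$edges), 0)
  expect_equal(nrow(rg$nodes), 4)
})

test_that("residue_interaction_summary counts partner residues per kind", {
  adj <- matrix(0, 3, 3)
  rg <- graph_from_adjacency(adj)
  rg$edges <- data.frame(
    i = c(1, 1), j = c(2, 3),
    kinds = c("hydrogen_bond", "hydrogen_bond,hydrophobic"),
    atomic_count = c(1L, 2L), min_distance = c(2.8, 3.0),
    stringsAsFactors = FALSE)
  s <- residue_interaction_summary(rg, 1)
  expect_equal(unname(s["hydrogen_bond"]), 2L)
  expect_equal(unname(s["hydrophobic"]), 1L)
  expect_equal(sum(s), 3L)
  expect_equal(sum(residue_interaction_summary(rg, 2)), 1L)
  expect_error(residue_interaction_summary(rg, 99), "unknown residue")
  # compact-chain fixture: counts equal a brute-force recount over edges
  fx <- fixture_helical()
  rg2 <- project_residue_graph(build_atom_graph(fx))
  expect_gt(nrow(rg2$edges), 0)
  for (ri in rg2$nodes$res_index) {
    s2 <- residue_interaction_summary(rg2, ri)
    for (kind in names(s2)) {
      manual <- 0L
      for (k in seq_len(nrow(rg2$edges))) {
        e <- rg2$edges[k, ]
        if ((e$i == ri || e$j == ri) &&
            kind %in% strsplit(e$kinds, ",")[[1]]) manual <- manual + 1L
      }
      expect_equal(unname(s2[kind]), manual)
    }
  }
})

test_that("graph exports are deterministic and carry report aliases", {
  fx <- fixture_pair("salt_bridge", 4.0)
  rg <- project_residue_graph(build_atom_graph(fx))
  f1 <- tempfile(); f2 <- tempfile()
  write_edge_tsv(rg, f1)
  write_edge_tsv(rg, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(any(grepl("charged_attractive", readLines(f1))))
  gml <- tempfile(fileext = ".graphml")
  write_graphml(rg, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(rg$edges))
})
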