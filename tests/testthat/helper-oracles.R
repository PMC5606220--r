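# Independent brute-force oracles used to validate the fast implementations.

# --- empty-circumsphere Delaunay oracle -------------------------------------
# Edge set = union of edges of all 4-subsets whose circumsphere contains no
# other point strictly inside.
oracle_circumsphere <- function(P, idx) {
  a <- P[idx[1], ]
  A <- 2 * (P[idx[2:4], , drop = FALSE] - rep(a, each = 3))
  rhs <- rowSums(P[idx[2:4], , drop = FALSE]^2) - sum(a^2)
  if (abs(det(A)) < 1e-10) return(NULL)
  cen <- solve(A, rhs)
  list(center = cen, r2 = sum((cen - a)^2))
}

oracle_delaunay_edges <- function(P) {
  n <- nrow(P)
  combos <- combn(n, 4)
  edges <- matrix(integer(0), 0, 2)
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    cs <- oracle_circumsphere(P, idx)
    if (is.null(cs)) next
    others <- setdiff(seq_len(n), idx)
    if (length(others) > 0) {
      d2 <- rowSums(sweep(P[others, , drop = FALSE], 2, cs$center)^2)
      if (any(d2 < cs$r2 - 1e-9 * (1 + cs$r2))) next
    }
    edges <- rbind(edges, t(combn(idx, 2)))
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# --- graph centrality oracles ------------------------------------------------
# Adjacency-matrix based: BFS distances by layered expansion; shortest-path
# counts as minimal-length walk counts (A^d entries).
oracle_graph_metrics <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  Npaths <- diag(n)
  reach <- diag(n) == 1
  walk <- diag(n)
  for (d in seq_len(n)) {
    walk <- walk %*% adj
    newly <- walk > 0 & !reach
    D[newly] <- d
    Npaths[newly] <- walk[newly]
    reach <- reach | newly
    if (all(reach) || sum(newly) == 0) {
      if (all(reach)) break
    }
  }
  degree <- rowSums(adj)
  closeness <- vapply(seq_len(n), function(v) {
    dv <- D[v, -v]
    dv <- dv[is.finite(dv)]
    if (length(dv) == 0 || degree[v] == 0) 0 else 1 / sum(dv)
  }, 0)
  betweenness <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        betweenness[v] <- betweenness[v] +
          Npaths[s, v] * Npaths[v, t] / Npaths[s, t]
      }
    }
  }
  list(degree = degree, closeness = closeness, betweenness = betweenness)
}

# build a residue_graph purely from an adjacency matrix (abstract graph tests)
graph_from_adjacency <- function(adj) {
  n <- nrow(adj)
  nodes <- data.frame(res_index = seq_len(n), res_name = "ALA",
                      res_seq = seq_len(n), icode = " ", one_letter = "A",
                      stringsAsFactors = FALSE)
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      kinds = rep("hydrophobic", nrow(idx)),
                      atomic_count = rep(1L, nrow(idx)),
                      min_distance = rep(3, nrow(idx)),
                      stringsAsFactors = FALSE)
  x <- structure(list(id = "abstract.A",
                      atoms = data.frame(), residues = nodes),
                 class = "prot_structure")
  structure(list(structure = x, nodes = nodes, edges = edges),
            class = "residue_graph")
}

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.numeric(runif(length(up)) < p)
  adj + t(adj)
}

# --- SASA oracles ------------------------------------------------------------
# exposed area of sphere 1 (radius R1) partially covered by sphere 2 (R2) at
# center distance d: full sphere minus the spherical cap inside sphere 2
oracle_two_sphere_areas <- function(R1, R2, d) {
  cap <- function(Ra, Rb) {
    if (d >= Ra + Rb) return(0)            # disjoint
    if (d + Ra <= Rb) return(4 * pi * Ra^2) # fully inside
    xplane <- (d^2 + Ra^2 - Rb^2) / (2 * d)
    h <- Ra - xplane
    2 * pi * Ra * h
  }
  c(4 * pi * R1^2 - cap(R1, R2), 4 * pi * R2^2 - cap(R2, R1))
}

# high-density point-sampling SASA oracle (Fibonacci sphere sampling)
oracle_sasa_sampling <- function(x, probe = 1.4, npts = 10000,
                                 radii = load_radii()) {
  co <- as.matrix(x$atoms[, c("x", "y", "z")])
  R <- unname(radii[x$atoms$element])
  R[is.na(R)] <- unname(radii["DEFAULT"])
  R <- R + probe
  ga <- pi * (3 - sqrt(5))
  k <- seq_len(npts)
  zu <- 1 - 2 * (k - 0.5) / npts
  ru <- sqrt(1 - zu^2)
  unit <- cbind(ru * cos(ga * k), ru * sin(ga * k), zu)
  n <- nrow(co)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(unit * R[i], 2, co[i, ], "+")
    free <- rep(TRUE, npts)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- rowSums(sweep(pts, 2, co[j, ])^2)
      free <- free & d2 > R[j]^2
    }
    areas[i] <- 4 * pi * R[i]^2 * mean(free)
  }
  areas
}

# --- exhaustive global alignment oracle (short strings, affine gaps) --------
# enumerates all alignments recursively with state = last operation
oracle_best_alignment_score <- function(a, b, mat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env()
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(av)) {
      pen <- if (prev == "A") gap_extend else gap_open + gap_extend
      best <- max(best, -pen + rec(i + 1, j, "A"))
    }
    if (j <= length(bv)) {
      pen <- if (prev == "B") gap_extend else gap_open + gap_extend
      best <- max(best, -pen + rec(i, j + 1, "B"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "M")
}

# gap structure of an aligned pair ("M", "A" = gap in b, "B" = gap in a)
alignment_ops <- function(a_aligned, b_aligned) {
  ca <- strsplit(a_aligned, "")[[1]]
  cb <- strsplit(b_aligned, "")[[1]]
  ifelse(ca == "-", "B", ifelse(cb == "-", "A", "M"))
}
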