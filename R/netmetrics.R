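#' Per-residue network centralities
#'
#' Computes the three complex-network centralities on the residue
#' interaction graph, with all interaction kinds collapsed to unweighted
#' undirected edges:
#'
#' * **degree** — number of incident edges;
#' * **betweenness** — unnormalized shortest-path betweenness (endpoints
#'   excluded, pair contributions split across equal-length shortest
#'   paths);
#' * **closeness** — reciprocal of the summed shortest-path distances to
#'   all reachable nodes (so values on an n-node connected graph lie in
#'   (0, 1/(n-1)]); isolated nodes report 0 by convention.
#'
#' Disconnected graphs are handled per component: closeness sums over
#' reachable nodes only and betweenness counts paths within components.
#'
#' @param rg a `residue_graph`.
#' @return data frame with `res_index`, `res_seq`, `icode`, `res_name`,
#'   `degree`, `betweenness`, `closeness`.
#' @export
centrality_profile <- function(rg) {
  stopifnot(inherits(rg, "residue_graph"))
  g <- as_igraph(rg)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  clo <- suppressWarnings(
    igraph::closeness(g, mode = "all", normalized = FALSE))
  clo[!is.finite(clo)] <- 0          # isolated nodes
  data.frame(
    res_index = rg$nodes$res_index,
    res_seq = rg$nodes$res_seq,
    icode = rg$nodes$icode,
    res_name = rg$nodes$res_name,
    degree = as.integer(unname(deg)),
    betweenness = unname(btw),
    closeness = unname(clo),
    stringsAsFactors = FALSE)
}

#' Degree centrality per residue
#' @param rg a `residue_graph`.
#' @return named integer vector (names = residue indices).
#' @export
degree_centrality <- function(rg) {
  p <- centrality_profile(rg)
  setNames(p$degree, p$res_index)
}

#' Betweenness centrality per residue
#' @param rg a `residue_graph`.
#' @return named numeric vector (names = residue indices).
#' @export
betweenness_centrality <- function(rg) {
  p <- centrality_profile(rg)
  setNames(p$betweenness, p$res_index)
}

#' Closeness centrality per residue
#' @param rg a `residue_graph`.
#' @return named numeric vector (names = residue indices).
#' @export
closeness_centrality <- function(rg) {
  p <- centrality_profile(rg)
  setNames(p$closeness, p$res_index)
}

#' Export centralities as TSV
#' @param rg a `residue_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centrality_tsv <- function(rg, path) {
  p <- centrality_profile(rg)
  out <- data.frame(
    res_seq = p$res_seq, res_name = p$res_name, degree = p$degree,
    betweenness = signif(p$betweenness, 10),
    closeness = signif(p$closeness, 10), stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
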