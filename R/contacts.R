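#' Load the physicochemical atom-typing table
#'
#' The packaged default maps (residue name, atom name) to a subset of the
#' seven-label vocabulary \{positive, negative, donor, acceptor, aromatic,
#' hydrophobic, cysteine\} following standard pharmacophore conventions:
#' Arg/Lys/His side-chain nitrogens are positive donors, Asp/Glu
#' carboxylate oxygens negative acceptors, backbone N donor (except Pro)
#' and backbone O acceptor, hydroxyl oxygens donor+acceptor, ring atoms of
#' Phe/Tyr/Trp/His aromatic, aliphatic side-chain carbons (not bonded to
#' N/O/S) hydrophobic, and Cys SG the cysteine type. The row `ANY` matches
#' any residue unless a residue-specific row exists.
#'
#' @param path optional path to a custom table (TSV with columns
#'   `res_name`, `atom_name`, `labels`; labels semicolon-separated, empty
#'   for intentionally untyped atoms).
#' @return data frame with columns `res_name`, `atom_name`, `labels`.
#' @export
load_typing_table <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("atom_typing.tsv")
  tab <- read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                    na.strings = character(0))
  need <- c("res_name", "atom_name")
  if (!all(need %in% names(tab)))
    stop("malformed typing table: need columns res_name, atom_name, labels")
  if (!"labels" %in% names(tab)) tab$labels <- ""
  tab$labels[is.na(tab$labels)] <- ""
  vocab <- c("positive", "negative", "donor", "acceptor", "aromatic",
             "hydrophobic", "cysteine")
  for (i in seq_len(nrow(tab))) {
    labs <- .split_labels(tab$labels[i])
    if (length(labs) > 0 && !all(labs %in% vocab))
      stop("malformed typing table row ", i, ": ", tab$labels[i])
  }
  tab
}

.split_labels <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  strsplit(s, ";", fixed = TRUE)[[1]]
}

#' Load the interaction distance criteria
#'
#' Defaults are the six distance windows used throughout: aromatic
#' stacking 1.5-3.5 (two aromatic atoms), disulfide bridge 1.4-2.3 (two
#' cysteines), hydrogen bond 2.0-3.0 (acceptor + donor), hydrophobic
#' 2.0-3.8 (two hydrophobic atoms), repulsive 2.0-6.0 (same charge), salt
#' bridge 2.0-6.0 (opposite charge). All distances in angstroms.
#'
#' @param path optional custom criteria TSV (columns `kind`, `type_a`,
#'   `type_b`, `d_min`, `d_max`).
#' @return data frame of criteria.
#' @export
load_criteria <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("interaction_criteria.tsv")
  cr <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("kind", "type_a", "type_b", "d_min", "d_max")
  if (!all(need %in% names(cr))) stop("malformed criteria table")
  bad <- which(!(cr$d_min > 0 & cr$d_min < cr$d_max))
  if (length(bad))
    stop("malformed criteria row ", bad[1], ": need 0 < d_min < d_max")
  cr
}

#' Assign physicochemical types to every atom of a structure
#'
#' @param x a `prot_structure`.
#' @param typing typing table from [load_typing_table()].
#' @return a list (one element per atom, in `x$atoms` order) of character
#'   vectors of labels; atoms with no table entry get an empty set with a
#'   warning, and atoms of nonstandard residues are left untyped.
#' @export
assign_atom_types <- function(x, typing = load_typing_table()) {
  stopifnot(inherits(x, "prot_structure"))
  key_specific <- paste(typing$res_name, typing$atom_name, sep = "|")
  untypable <- character(0)
  types <- vector("list", nrow(x$atoms))
  for (i in seq_len(nrow(x$atoms))) {
    rn <- x$atoms$res_name[i]
    an <- x$atoms$name[i]
    if (!rn %in% names(.AA321)) {  # nonstandard residue: skip typing
      types[[i]] <- character(0)
      next
    }
    hit <- match(paste(rn, an, sep = "|"), key_specific)
    if (is.na(hit)) hit <- match(paste("ANY", an, sep = "|"), key_specific)
    if (is.na(hit)) {
      types[[i]] <- character(0)
      untypable <- c(untypable, paste0(rn, ":", an))
    } else {
      types[[i]] <- .split_labels(typing$labels[hit])
    }
  }
  if (length(untypable) > 0)
    warning("atoms with no typing entry (left untyped): ",
            paste(unique(untypable), collapse = ", "))
  types
}

#' Delaunay neighbor pairs of a 3-D point set
#'
#' Edges of the 3-D Delaunay triangulation, the cutoff-free "natural
#' neighbor" contact definition. Degenerate configurations (cospherical
#' or coplanar point subsets that defeat the incremental triangulation)
#' are retried once after a deterministic jitter of 1e-3 angstroms drawn
#' from a fixed-seed generator.
#'
#' @param coords numeric matrix (n x 3), n >= 4.
#' @return two-column integer matrix of index pairs (i < j).
#' @export
delaunay_neighbors <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4)
    stop("Delaunay triangulation requires at least 4 points")
  res <- tryCatch(.delaunay_edges_cpp(coords), error = function(e) e)
  if (inherits(res, "error")) {
    if (!grepl("degenerate", conditionMessage(res)))
      stop(res)
    old <- .Random.seed_exists()
    set.seed(20260919L)
    jit <- matrix(runif(length(coords), -1e-3, 1e-3), nrow(coords), 3)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    res <- .delaunay_edges_cpp(coords + jit)
  }
  res
}

#' Classify an atom pair into interaction kinds
#'
#' A kind applies iff the unordered pair of type sets matches the
#' criterion's atom-type pattern and the distance lies inside its window
#' (inclusive). Multiple kinds may apply; symmetric in its two arguments.
#'
#' @param types_a,types_b character vectors of atom-type labels.
#' @param distance interatomic distance in angstroms.
#' @param criteria criteria table from [load_criteria()].
#' @return character vector of interaction kinds (possibly empty).
#' @export
classify_pair <- function(types_a, types_b, distance,
                          criteria = load_criteria()) {
  stopifnot(distance > 0)
  hit <- (criteria$d_min <= distance & distance <= criteria$d_max) &
    ((criteria$type_a %in% types_a & criteria$type_b %in% types_b) |
     (criteria$type_a %in% types_b & criteria$type_b %in% types_a))
  unique(criteria$kind[hit])
}

#' Build the atomic interaction graph
#'
#' Nodes are heavy atoms with their physicochemical type sets; edges are
#' Delaunay neighbor pairs of atoms from different residues whose
#' distance and types satisfy at least one interaction criterion. Pairs
#' that are within an interaction window but not Delaunay neighbors are
#' occluded contacts and never appear. By default, pairs where both atoms
#' are backbone atoms of sequence-adjacent residues are excluded, since
#' the peptide-unit O(i)-N(i+1) geometry would otherwise register a
#' hydrogen bond at every position; set `keep_adjacent_backbone = TRUE`
#' to retain them.
#'
#' @param x a `prot_structure` with at least 4 atoms.
#' @param typing typing table.
#' @param criteria criteria table.
#' @param keep_adjacent_backbone keep backbone-backbone contacts of
#'   sequence-adjacent residues (default `FALSE`).
#' @return an `atom_graph`: list with `structure`, `types`, and `edges`
#'   (data frame `i`, `j` atom row indices, `distance`, `kinds`
#'   comma-separated).
#' @export
build_atom_graph <- function(x, typing = load_typing_table(),
                             criteria = load_criteria(),
                             keep_adjacent_backbone = FALSE) {
  stopifnot(inherits(x, "prot_structure"))
  if (nrow(x$atoms) < 4)
    stop("structure too small: need at least 4 atoms")
  types <- suppressWarnings(assign_atom_types(x, typing))
  co <- as.matrix(x$atoms[, c("x", "y", "z")])
  pairs <- delaunay_neighbors(co)
  ri <- x$atoms$res_index
  keep <- ri[pairs[, 1]] != ri[pairs[, 2]]
  pairs <- pairs[keep, , drop = FALSE]
  if (!keep_adjacent_backbone && nrow(pairs) > 0) {
    bb <- x$atoms$name %in% .BACKBONE_ATOMS
    adj <- abs(ri[pairs[, 1]] - ri[pairs[, 2]]) == 1
    drop <- adj & bb[pairs[, 1]] & bb[pairs[, 2]]
    pairs <- pairs[!drop, , drop = FALSE]
  }
  out <- list()
  if (nrow(pairs) > 0) {
    d <- sqrt(rowSums((co[pairs[, 1], , drop = FALSE] -
                       co[pairs[, 2], , drop = FALSE])^2))
    for (k in seq_len(nrow(pairs))) {
      kinds <- classify_pair(types[[pairs[k, 1]]], types[[pairs[k, 2]]],
                             d[k], criteria)
      if (length(kinds) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          i = pairs[k, 1], j = pairs[k, 2], distance = d[k],
          kinds = paste(sort(kinds), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(out)) do.call(rbind, out) else
    data.frame(i = integer(0), j = integer(0), distance = numeric(0),
               kinds = character(0), stringsAsFactors = FALSE)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(structure = x, types = types, edges = edges),
            class = "atom_graph")
}

#' @export
print.atom_graph <- function(x, ...) {
  cat(sprintf("<atom_graph %s: %d atoms, %d interaction edges>\n",
              x$structure$id, nrow(x$structure$atoms), nrow(x$edges)))
  invisible(x)
}

#' Project an atomic interaction graph to residue level
#'
#' A residue pair is connected iff at least one atomic interaction edge
#' joins their atoms; the edge carries the union of atomic interaction
#' kinds, the count of atomic edges, and the minimum atomic distance.
#'
#' @param ag an `atom_graph`.
#' @return a `residue_graph`: list with `structure`, `nodes` (the residue
#'   table) and `edges` (data frame `i`, `j` residue indices, `kinds`,
#'   `atomic_count`, `min_distance`).
#' @export
project_residue_graph <- function(ag) {
  stopifnot(inherits(ag, "atom_graph"))
  x <- ag$structure
  ri <- x$atoms$res_index
  e <- ag$edges
  if (nrow(e) > 0) {
    a <- pmin(ri[e$i], ri[e$j])
    b <- pmax(ri[e$i], ri[e$j])
    key <- paste(a, b, sep = "|")
    agg <- lapply(split(seq_len(nrow(e)), key), function(idx) {
      kinds <- sort(unique(unlist(strsplit(e$kinds[idx], ",", fixed = TRUE))))
      data.frame(i = a[idx[1]], j = b[idx[1]],
                 kinds = paste(kinds, collapse = ","),
                 atomic_count = length(idx),
                 min_distance = min(e$distance[idx]),
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, agg)
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(i = integer(0), j = integer(0), kinds = character(0),
                        atomic_count = integer(0), min_distance = numeric(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(structure = x, nodes = x$residues, edges = edges),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph %s: %d residues, %d edges>\n",
              x$structure$id, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Per-kind interaction counts for one residue
#'
#' For each of the six interaction kinds, the number of partner residues
#' connected to `res_index` by an edge carrying that kind.
#'
#' @param rg a `residue_graph`.
#' @param res_index residue index (row in `rg$nodes`).
#' @return named integer vector over the six kinds.
#' @export
residue_interaction_summary <- function(rg, res_index) {
  stopifnot(inherits(rg, "residue_graph"))
  if (!res_index %in% rg$nodes$res_index)
    stop("unknown residue index: ", res_index)
  counts <- setNames(integer(length(.INTERACTION_KINDS)), .INTERACTION_KINDS)
  e <- rg$edges
  inc <- e[e$i == res_index | e$j == res_index, , drop = FALSE]
  if (nrow(inc) > 0) {
    for (k in seq_len(nrow(inc))) {
      for (kind in strsplit(inc$kinds[k], ",", fixed = TRUE)[[1]])
        counts[kind] <- counts[kind] + 1L
    }
  }
  counts
}

#' Residue kinds established by each residue
#'
#' Helper for exports: the set of kinds each residue establishes, with
#' residues establishing more than one kind tagged `"multiple"`.
#'
#' @param rg a `residue_graph`.
#' @return data frame with `res_index`, `kinds`, `tag`.
#' @export
residue_kind_tags <- function(rg) {
  stopifnot(inherits(rg, "residue_graph"))
  kinds_per <- lapply(rg$nodes$res_index, function(ri) {
    inc <- rg$edges[rg$edges$i == ri | rg$edges$j == ri, , drop = FALSE]
    sort(unique(unlist(strsplit(inc$kinds, ",", fixed = TRUE))))
  })
  data.frame(
    res_index = rg$nodes$res_index,
    kinds = vapply(kinds_per, paste, "", collapse = ","),
    tag = vapply(kinds_per, function(k) {
      if (length(k) == 0) "none" else if (length(k) > 1) "multiple" else k
    }, ""),
    stringsAsFactors = FALSE)
}

#' Convert a residue graph to an igraph object
#' @param rg a `residue_graph`.
#' @return an undirected `igraph` graph whose vertices are residues (named
#'   by author residue number + insertion code) with the interaction-kind
#'   labels on edges.
#' @export
as_igraph <- function(rg) {
  stopifnot(inherits(rg, "residue_graph"))
  vn <- paste0(trimws(paste0(rg$nodes$res_seq,
                             ifelse(rg$nodes$icode == " ", "",
                                    rg$nodes$icode))))
  g <- igraph::make_empty_graph(n = nrow(rg$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vn)
  g <- igraph::set_vertex_attr(g, "res_name", value = rg$nodes$res_name)
  if (nrow(rg$edges) > 0) {
    g <- igraph::add_edges(g, rbind(rg$edges$i, rg$edges$j))
    g <- igraph::set_edge_attr(g, "kinds", value = rg$edges$kinds)
    g <- igraph::set_edge_attr(g, "atomic_count",
                               value = rg$edges$atomic_count)
    g <- igraph::set_edge_attr(g, "min_distance",
                               value = rg$edges$min_distance)
  }
  g
}

#' Export a residue graph as a TSV edge list
#'
#' Columns: `res_i`, `res_j` (author numbering), `kinds` (report aliases:
#' salt bridge as `charged_attractive`, repulsive as `charged_repulsive`),
#' `atomic_count`, `min_distance`.
#'
#' @param rg a `residue_graph`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(rg, path) {
  stopifnot(inherits(rg, "residue_graph"))
  e <- rg$edges
  alias <- function(s) {
    vapply(strsplit(s, ",", fixed = TRUE), function(k)
      paste(unname(.KIND_ALIASES[k]), collapse = ","), "")
  }
  out <- data.frame(
    res_i = rg$nodes$res_seq[match(e$i, rg$nodes$res_index)],
    res_j = rg$nodes$res_seq[match(e$j, rg$nodes$res_index)],
    kinds = if (nrow(e)) alias(e$kinds) else character(0),
    atomic_count = e$atomic_count,
    min_distance = round(e$min_distance, 3),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a residue graph as GraphML
#' @param rg a `residue_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(rg, path) {
  igraph::write_graph(as_igraph(rg), path, format = "graphml")
  invisible(path)
}
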