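#' Run the full mutational-analysis pipeline
#'
#' End-to-end batch analysis: reads the wild-type chain, the mutant
#' sequence and the family structures; builds atom and residue
#' interaction graphs, centralities and accessibility for the wild type
#' and every family member; assembles the structure-based family
#' alignment; summarizes every column; detects and assesses the
#' mutations; flags candidate critical positions; and writes all
#' artifacts plus a manifest into `out_dir`.
#'
#' Failure policy: a wild-type processing failure aborts; an individual
#' family-member failure skips that member with a warning and is listed
#' in the manifest.
#'
#' @param wild_path,wild_chain wild-type PDB path and chain.
#' @param mutant_fasta path to the mutant FASTA (optional).
#' @param family named list of `c(path, chain)` pairs, or a directory
#'   scanned for `*.pdb` files (chain defaults to `wild_chain`).
#' @param ddg_path optional dG-change TSV (see [read_ddg_table()]).
#' @param out_dir output directory (created).
#' @param seed integer seed recorded in the manifest and used for row
#'   clustering.
#' @param probe,slice_dz accessibility parameters.
#' @param cutoff,max_iter structural-alignment parameters.
#' @param scheme color scheme name.
#' @param keep_adjacent_backbone see [build_atom_graph()].
#' @param typing_path,criteria_path optional config overrides.
#' @param t_acc,t_sd,t_hyd critical-position thresholds.
#' @return (invisibly) list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(wild_path, wild_chain, mutant_fasta = NULL,
                         family = list(), ddg_path = NULL, out_dir,
                         seed = 1L, probe = 1.4, slice_dz = 0.05,
                         cutoff = 5.0, max_iter = 20L, scheme = "CINEMA",
                         keep_adjacent_backbone = FALSE,
                         typing_path = NULL, criteria_path = NULL,
                         t_acc = 10.0, t_sd = 10.0, t_hyd = 80.0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  typing <- load_typing_table(typing_path)
  criteria <- load_criteria(criteria_path)
  radii <- load_radii()
  reference <- load_reference_table()

  if (is.character(family) && length(family) == 1 && dir.exists(family)) {
    paths <- sort(list.files(family, pattern = "\\.pdb$", full.names = TRUE))
    family <- lapply(paths, function(p) list(path = p, chain = wild_chain))
    names(family) <- sub("\\.pdb$", "", basename(paths))
  }
  if (length(family) == 0) warning("family set empty")

  wild <- read_structure(wild_path, wild_chain)

  process_one <- function(x) {
    ag <- build_atom_graph(x, typing, criteria,
                           keep_adjacent_backbone = keep_adjacent_backbone)
    rg <- project_residue_graph(ag)
    cent <- centrality_profile(rg)
    acc <- accessibility_profile(x, probe = probe, radii = radii,
                                 slice_dz = slice_dz,
                                 reference = reference)
    prop <- merge(cent[, c("res_index", "degree", "betweenness",
                           "closeness")],
                  acc[, c("res_index", "all_atoms_rel", "all_atoms_abs")],
                  by = "res_index")
    list(structure = x, atom_graph = ag, residue_graph = rg,
         centrality = cent, accessibility = acc, properties = prop)
  }

  wild_res <- process_one(wild)
  members <- list()
  member_results <- list()
  failed <- character(0)
  for (nm in names(family)) {
    fm <- family[[nm]]
    res <- tryCatch({
      xm <- read_structure(fm$path, fm$chain)
      xm$id <- paste0(nm, ".", fm$chain)
      process_one(xm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("family member ", nm, " skipped: ", conditionMessage(res))
      failed <- c(failed, nm)
      next
    }
    members[[nm]] <- res$structure
    member_results[[nm]] <- res
  }

  mutant_seq <- if (!is.null(mutant_fasta)) read_fasta(mutant_fasta)$sequence
  fa <- assemble_family_alignment(wild, members, mutant_seq,
                                  cutoff = cutoff, max_iter = max_iter)
  failed <- union(failed, fa$failed)

  properties <- c(list(wild = wild_res$properties),
                  lapply(member_results, `[[`, "properties"))
  graphs <- c(list(wild = wild_res$residue_graph),
              lapply(member_results, `[[`, "residue_graph"))
  summaries <- summarize_columns(fa, properties, graphs)
  critical <- flag_critical_positions(summaries, t_acc, t_sd, t_hyd)

  ddg_table <- if (!is.null(ddg_path)) read_ddg_table(ddg_path)
  mutations <- if (!is.null(mutant_seq)) {
    mut <- detect_mutations(fa$rows["wild", ], fa$rows["mutant", ], wild,
                            ddg_table)
    assess_mutations(mut, summaries, scheme, critical)
  } else {
    data.frame()
  }

  ordering <- cluster_rows_em(fa, scheme, seed = seed)

  # ---- artifacts -------------------------------------------------------
  write_alignment_fasta(fa, file.path(out_dir, "alignment.fasta"),
                        file.path(out_dir, "alignment_map.tsv"), members)
  sum_out <- summaries
  num <- vapply(sum_out, is.numeric, TRUE)
  sum_out[num] <- lapply(sum_out[num], function(v) round(v, 6))
  sum_out$critical <- sum_out$column %in% critical$column
  write.table(sum_out, file.path(out_dir, "columns.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(mutations, file.path(out_dir, "mutations.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  all_results <- c(list(wild = wild_res), member_results)
  for (nm in names(all_results)) {
    d <- file.path(out_dir, nm)
    dir.create(d, showWarnings = FALSE)
    write_edge_tsv(all_results[[nm]]$residue_graph,
                   file.path(d, "edges.tsv"))
    write_graphml(all_results[[nm]]$residue_graph,
                  file.path(d, "graph.graphml"))
    write_centrality_tsv(all_results[[nm]]$residue_graph,
                         file.path(d, "centrality.tsv"))
    write_accessibility_tsv(all_results[[nm]]$accessibility,
                            file.path(d, "accessibility.tsv"))
  }
  manifest <- list(
    inputs = list(wild = wild_path, chain = wild_chain,
                  mutant = mutant_fasta,
                  family = lapply(family, function(f) f$path),
                  ddg = ddg_path),
    parameters = list(seed = seed, probe = probe, slice_dz = slice_dz,
                      cutoff = cutoff, max_iter = max_iter,
                      scheme = scheme,
                      keep_adjacent_backbone = keep_adjacent_backbone,
                      t_acc = t_acc, t_sd = t_sd, t_hyd = t_hyd),
    n_family = length(family), n_processed = length(member_results),
    skipped_members = as.list(failed),
    n_mutations = nrow(mutations),
    n_critical_positions = nrow(critical),
    row_order = fa$row_ids[ordering],
    version = as.character(utils::packageVersion("rinmut")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(wild = wild_res, members = member_results,
                 alignment = fa, summaries = summaries,
                 mutations = mutations, critical = critical,
                 ordering = ordering, manifest = manifest))
}
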