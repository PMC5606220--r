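#' Sequence-only structure scaffold
#'
#' Builds a `prot_structure` carrying only author numbering and residue
#' identity, with synthetic CA placeholder coordinates (3.8-angstrom
#' spacing along x). Useful for sequence-level operations that need
#' author numbering — e.g. numbering mutation records against a chain
#' whose structure is not loaded — and not valid for any geometric
#' analysis.
#'
#' @param sequence one-letter amino-acid sequence (X allowed).
#' @param start author number of the first residue.
#' @param id structure label.
#' @return a `prot_structure` with one placeholder CA atom per residue.
#' @export
sequence_structure <- function(sequence, start = 1L, id = "sequence.A") {
  letters1 <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  stopifnot(length(letters1) > 0)
  res_names <- ifelse(letters1 %in% names(.AA123),
                      unname(.AA123[letters1]), "UNK")
  atoms <- data.frame(
    serial = seq_along(letters1),
    name = "CA",
    element = "C",
    res_name = res_names,
    res_seq = start + seq_along(letters1) - 1L,
    icode = " ",
    chain_id = "A",
    x = 3.8 * seq_along(letters1), y = 0, z = 0,
    occupancy = 1, altloc = " ",
    stringsAsFactors = FALSE)
  .new_structure(atoms, id)
}

#' Apply point substitutions to a sequence
#'
#' @param sequence one-letter sequence.
#' @param mutations data frame with `wild_res`, `real_position`,
#'   `mut_res` (author numbering).
#' @param start author number of the first residue of `sequence`.
#' @return the mutated sequence string; errors if a stated wild residue
#'   does not match the sequence.
#' @export
apply_mutations <- function(sequence, mutations, start = 1L) {
  letters1 <- strsplit(sequence, "")[[1]]
  for (k in seq_len(nrow(mutations))) {
    idx <- mutations$real_position[k] - start + 1L
    if (idx < 1 || idx > length(letters1))
      stop("mutation position ", mutations$real_position[k],
           " outside the sequence")
    if (letters1[idx] != mutations$wild_res[k])
      stop("wild residue mismatch at ", mutations$real_position[k],
           ": sequence has ", letters1[idx], ", table says ",
           mutations$wild_res[k])
    letters1[idx] <- mutations$mut_res[k]
  }
  paste(letters1, collapse = "")
}
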