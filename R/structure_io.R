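#' Read one chain of a PDB structure
#'
#' Parses a PDB file and returns a single-chain polymer structure holding
#' only heavy-atom `ATOM` records. Hydrogens (and deuteriums), all
#' `HETATM` records (waters, ligands, ions, and modified residues),
#' and unselected alternate locations are removed. For multi-model files
#' only the first model is used.
#'
#' Alternate locations are resolved per atom by keeping the altloc with
#' the highest occupancy; ties go to the lexicographically smallest
#' altloc identifier.
#'
#' @param path path to a PDB file.
#' @param chain single chain identifier to extract.
#' @param model model number (1-based; only the first model is supported
#'   and `model` must be 1).
#' @return An object of class `prot_structure`: a list with elements
#'   `id` (label `"file.chain"`), `atoms` (data frame of atom records with
#'   columns `serial`, `name`, `element`, `res_name`, `res_seq`, `icode`,
#'   `chain_id`, `x`, `y`, `z`, `occupancy`, `altloc`, `res_index`) and
#'   `residues` (data frame with `res_index`, `res_name`, `res_seq`,
#'   `icode`, `one_letter`).
#' @export
read_structure <- function(path, chain, model = 1L) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (model != 1L) stop("only the first model is supported")
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  het <- at[at$type == "HETATM" & at$chain %in% chain, , drop = FALSE]
  if (nrow(het) > 0) {
    warning(sprintf("dropping %d HETATM records (waters/ligands/modified residues)",
                    nrow(het)))
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!chain %in% at$chain) stop("chain '", chain, "' not found in ", path)
  at <- at[at$chain == chain, , drop = FALSE]
  # strip hydrogens/deuteriums
  elem <- .element_of(at$elety, at$elesy)
  at <- at[!elem %in% c("H", "D"), , drop = FALSE]
  if (nrow(at) == 0) stop("no polymer heavy atoms in chain '", chain, "'")
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = .element_of(at$elety, at$elesy),
    res_name = at$resid,
    res_seq = at$resno,
    icode = ifelse(is.na(at$insert) | at$insert == "", " ", at$insert),
    chain_id = at$chain,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt) | at$alt == "", " ", at$alt),
    stringsAsFactors = FALSE
  )
  atoms <- .resolve_altlocs(atoms)
  id <- paste0(sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE),
               ".", chain)
  .new_structure(atoms, id)
}

# element symbol from PDB element field, falling back to the atom name
.element_of <- function(name, elesy) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  fallback <- toupper(substr(gsub("[0-9']", "", trimws(name)), 1, 1))
  ifelse(nzchar(el), el, fallback)
}

# keep, per (res_seq, icode, atom name), the altloc with highest occupancy;
# tie -> lexicographically smallest altloc
.resolve_altlocs <- function(atoms) {
  key <- paste(atoms$res_seq, atoms$icode, atoms$name, sep = "|")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$res_seq, atoms$icode, atoms$name,
                                   sep = "|")), , drop = FALSE]
  atoms[order(atoms$res_seq, atoms$icode, atoms$serial), , drop = FALSE]
}

.new_structure <- function(atoms, id) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) > 0) {
    ord <- order(atoms$res_seq, atoms$icode)
    atoms <- atoms[ord, , drop = FALSE]
    rk <- paste(atoms$res_seq, atoms$icode, sep = "|")
    atoms$res_index <- match(rk, unique(rk))
    first <- !duplicated(rk)
    residues <- data.frame(
      res_index = atoms$res_index[first],
      res_name = atoms$res_name[first],
      res_seq = atoms$res_seq[first],
      icode = atoms$icode[first],
      stringsAsFactors = FALSE
    )
    residues$one_letter <- unname(
      ifelse(residues$res_name %in% names(.AA321),
             .AA321[residues$res_name], "X"))
  } else {
    atoms$res_index <- integer(0)
    residues <- data.frame(res_index = integer(0), res_name = character(0),
                           res_seq = integer(0), icode = character(0),
                           one_letter = character(0), stringsAsFactors = FALSE)
  }
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, residues = residues),
            class = "prot_structure")
}

#' @export
print.prot_structure <- function(x, ...) {
  cat(sprintf("<prot_structure %s: %d residues, %d atoms>\n",
              x$id, nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

#' One-letter sequence of a structure
#'
#' One letter per residue in chain order; nonstandard residues map to `X`.
#'
#' @param x a `prot_structure`.
#' @return a character scalar of length-`nrow(x$residues)` letters.
#' @export
sequence_of <- function(x) {
  stopifnot(inherits(x, "prot_structure"))
  paste(x$residues$one_letter, collapse = "")
}

#' Read a single-record FASTA file
#'
#' @param path path to a FASTA file holding exactly one amino-acid record.
#' @return list with `header` and `sequence` (uppercase, whitespace removed).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty FASTA file: ", path)
  hdr <- grep("^>", lines)
  if (length(hdr) != 1)
    stop("expected 1 record, found ", length(hdr))
  seq <- toupper(gsub("\\s", "", paste(lines[-hdr], collapse = "")))
  if (!nzchar(seq)) stop("FASTA record has an empty sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seq))
    stop("unexpected characters in amino-acid sequence")
  list(header = sub("^>\\s*", "", lines[hdr]), sequence = seq)
}

#' Write a sequence as FASTA
#' @param sequence character scalar.
#' @param header record header (without `>`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequence, header, path) {
  chunks <- substring(sequence, seq(1, nchar(sequence), 60),
                      pmin(seq(1, nchar(sequence), 60) + 59, nchar(sequence)))
  writeLines(c(paste0(">", header), chunks), path)
  invisible(path)
}

#' Write a structure as a PDB file
#'
#' Serializes the heavy-atom records of a `prot_structure` using
#' fixed-width `ATOM` records (coordinates to 3 decimals), suitable for
#' round-tripping through [read_structure()].
#'
#' @param x a `prot_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "prot_structure"))
  a <- x$atoms
  name4 <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                  sprintf("%-4s", a$name))
  rec <- sprintf(
    "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000, name4, a$altloc, a$res_name, a$chain_id,
    a$res_seq, a$icode, a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(rec, "TER", "END"), path)
  invisible(path)
}
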