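# shared fixture builders for the test suite

# hand-rolled PDB text lines for reader edge cases (chains, altlocs, HETATM)
pdb_line <- function(type = "ATOM", serial, name, altloc = " ", res, chain,
                     resno, icode = " ", x, y, z, occ = 1, element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name4, altloc, res, chain, resno, icode,
          x, y, z, occ, 0, element)
}

write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    if (sum(q^2) > 1e-8) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# a small rigid family on disk: wild chain + n transformed copies
make_family_dir <- function(wild, n = 3, seed = 42, noise = 0) {
  fam <- tempfile("family")
  dir.create(fam)
  set.seed(seed)
  for (k in seq_len(n)) {
    m <- transform_structure(wild, random_rotation(), runif(3, -8, 8),
                             id = sprintf("mem%d.A", k))
    if (noise > 0) m <- perturb_structure(m, noise, seed = seed + k)
    write_structure(m, file.path(fam, sprintf("mem%d.pdb", k)))
  }
  fam
}

structure_coords <- function(x) as.matrix(x$atoms[, c("x", "y", "z")])

# compact (helical) chain: guarantees non-trivial interaction networks
fixture_helical <- function(sequence = "KDSFWKDSFW") {
  build_peptide(sequence, phi = -60, psi = -45, id = "helical.A")
}

mid_window <- c(aromatic_stacking = 2.5, disulfide_bridge = 1.85,
                hydrogen_bond = 2.5, hydrophobic = 2.9,
                repulsive = 4.0, salt_bridge = 4.0)
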