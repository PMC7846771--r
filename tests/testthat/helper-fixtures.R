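# Small fixtures built in code: a hand-written PDB text (heavy atoms only,
# so the proton-construction path is exercised), tiny methyl sets with
# explicit coordinates, and peak-list writers.

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, nm, resid, chain, resno, xyz[1], xyz[2], xyz[3])
}

# Leu1-Val2-Ile3 with idealised heavy-atom geometry (no protons).
# Returns the path of a written PDB file; with n_models > 1 the later
# models are rigidly shifted so ensemble minima are well defined.
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb"), n_models = 1,
                           shift = c(0, 0, 0)) {
  atoms <- list(
    list("CA",  "LEU", 1, c(0.0, 0.0, 0.0)),
    list("CB",  "LEU", 1, c(1.53, 0.0, 0.0)),
    list("CG",  "LEU", 1, c(2.1, 1.4, 0.0)),
    list("CD1", "LEU", 1, c(3.63, 1.4, 0.0)),
    list("CD2", "LEU", 1, c(1.55, 2.2, 1.2)),
    list("N",   "VAL", 2, c(6.0, 0.0, 0.0)),
    list("CA",  "VAL", 2, c(7.0, 1.0, 0.0)),
    list("CB",  "VAL", 2, c(8.4, 0.4, 0.0)),
    list("CG1", "VAL", 2, c(9.5, 1.5, 0.0)),
    list("CG2", "VAL", 2, c(8.6, -0.5, 1.2)),
    list("CA",  "ILE", 3, c(0.0, 8.0, 0.0)),
    list("CB",  "ILE", 3, c(1.5, 8.2, 0.0)),
    list("CG1", "ILE", 3, c(2.2, 8.4, 1.35)),
    list("CD1", "ILE", 3, c(3.7, 8.6, 1.4)))
  lines <- character(0)
  for (m in seq_len(n_models)) {
    off <- (m - 1) * shift
    lines <- c(lines, sprintf("MODEL     %4d", m),
               vapply(seq_along(atoms), function(i) {
                 a <- atoms[[i]]
                 pdb_atom_line(i, a[[1]], a[[2]], "A", a[[3]], a[[4]] + off)
               }, character(1)),
               "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# methyl_set with explicit carbon positions (protons built tetrahedrally
# around each carbon along fixed axes); types: one-letter codes, L/V give
# two methyls
toy_methyl_set <- function(carbons, residue_types) {
  sim <- synth_structure(n_methyls = nrow(carbons),
                         residue_types = residue_types,
                         carbon_positions = carbons, seed = 7)
  sim$methyls
}

# equal-distance proton triplets: two methyls whose nine pairwise proton
# distances are all d (degenerate arrangement: all protons collapsed)
coincident_protons <- function(center) {
  matrix(rep(center, each = 3), 3, 3)
}
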