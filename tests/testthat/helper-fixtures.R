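# Write a minimal (optionally multi-model) PDB file: one chain, `n_res`
# residues with atoms N, CA, C, coordinates supplied per model as a
# n_atoms x 3 matrix (angstrom).
write_test_pdb <- function(path, models) {
  atoms_per_res <- c("N", "CA", "C")
  lines <- character(0)
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    xyz <- models[[m]]
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    serial <- 0L
    row <- 0L
    n_res <- nrow(xyz) / length(atoms_per_res)
    for (res in seq_len(n_res)) {
      for (an in atoms_per_res) {
        serial <- serial + 1L
        row <- row + 1L
        lines <- c(lines, paste0(
          "ATOM  ", sprintf("%5d", serial), " ", sprintf("%-4s", an), " ",
          sprintf("%3s", "ALA"), " A", sprintf("%4d", res), "    ",
          sprintf("%8.3f%8.3f%8.3f", xyz[row, 1], xyz[row, 2], xyz[row, 3]),
          "  1.00  0.00"))
      }
    }
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# Coordinates (angstrom) for n_res residues x 3 atoms, vaguely chain-like.
test_pdb_coords <- function(n_res, jitter = 0, seed = 1) {
  set.seed(seed)
  n_atoms <- 3 * n_res
  base <- cbind(seq_len(n_atoms) * 1.5, rep(c(0, 1, 0), n_res),
                rep(c(0, 0, 1), n_res))
  base + matrix(rnorm(n_atoms * 3, 0, jitter), n_atoms, 3)
}
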