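# Shared fixtures and independent oracles for the test suite.

# Brute-force PDF oracle: direct unweighted double loop over pairs and the
# full grid, no truncation windows, no accumulation tricks. Must stay
# independent of calc_pdf's implementation.
oracle_pdf <- function(model, rgrid, scale = 1, sigma0 = 0.05) {
  xyz <- as.matrix(model[, c("x", "y", "z")])
  z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, Cl = 17, Ag = 47)
  f <- z[model$element]
  fbar <- mean(f)
  n <- nrow(xyz)
  g <- numeric(length(rgrid))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      sig <- sqrt((model$biso[i] + model$biso[j]) / (8 * pi^2) + sigma0^2)
      w <- f[i] * f[j] / fbar^2
      g <- g + 2 * w * dnorm(rgrid, d, sig)
    }
  }
  scale * g / ifelse(rgrid > 0, rgrid, Inf)
}

random_model <- function(n, seed, elements = c("Ag", "Cl", "C", "N", "O"),
                         biso_max = 1, box = 8) {
  set.seed(seed)
  repeat {
    xyz <- matrix(runif(3 * n, 0, box), ncol = 3)
    if (min(dist(xyz)) > 0.8) break
  }
  cluster_model(tibble::tibble(
    element = sample(elements, n, replace = TRUE),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    biso = runif(n, 0, biso_max)))
}

two_atom_model <- function(d = 2.8, element = "Ag", biso = 0) {
  cluster_model(tibble::tibble(element = element, x = c(0, d), y = 0, z = 0,
                               biso = biso))
}

# Minimal PDB with HETATM silver/chloride and a few DNA atoms.
write_toy_pdb <- function(path, n_ag = 3, n_dna = 5) {
  fmt <- "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  afmt <- "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  lines <- character(0)
  for (i in seq_len(n_ag)) {
    lines <- c(lines, sprintf(fmt, i, "AG", "AG", "X", i,
                              2.8 * i, 0, 0, "AG"))
  }
  for (i in seq_len(n_dna)) {
    lines <- c(lines, sprintf(afmt, n_ag + i, "C1'", "DA", "A", i,
                              0, 1.5 * i, 4, "C"))
  }
  writeLines(c(lines, "END"), path)
  path
}

# Minimal mmCIF with the standard PDBx atom_site loop (the full 21-field
# column set, Cartesian coordinates).
write_toy_cif <- function(path, model) {
  head <- c("data_toy", "#", "loop_",
            "_atom_site.group_PDB", "_atom_site.id",
            "_atom_site.type_symbol", "_atom_site.label_atom_id",
            "_atom_site.label_alt_id", "_atom_site.label_comp_id",
            "_atom_site.label_asym_id", "_atom_site.label_entity_id",
            "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
            "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
            "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
            "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
            "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
            "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf(
    "HETATM %d %s %s . LIG A 1 1 ? %.3f %.3f %.3f 1.00 0.00 ? 1 LIG A %s 1",
    seq_len(nrow(model)), toupper(model$element), toupper(model$element),
    model$x, model$y, model$z, toupper(model$element))
  writeLines(c(head, rows, "#"), path)
  path
}

expect_rigid_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(as.matrix(a) - as.matrix(b))), tol)
}
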