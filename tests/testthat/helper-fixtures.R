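# Shared fixtures built in code at test time.

# A minimal model from explicit coordinates: one row per atom.
tiny_model <- function(coords, chain = "A", resno = seq_len(nrow(coords)),
                       atom = "CA", element = "C", resname = "ALA") {
  coords <- matrix(coords, ncol = 3)
  structure_model(data.frame(
    chain = chain, resno = resno, resname = resname,
    atom = atom, element = element,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE))
}

# Hand-written 3-atom PDB file; returns the path.
write_three_atom_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.500   3.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       2.500   4.000   3.500  1.00  0.00           C",
    "END"), path)
  path
}

# Two-model PDB with one CA whose coordinates differ between models.
write_two_model_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       5.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END"), path)
  path
}

# Altloc A (occupancy 0.6) and B (0.4) for the same atom.
write_altloc_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  path
}

# 14-restraint fixture against a one-member encounter ensemble in which
# exactly 6 restraints are satisfiable (probe atoms at staggered distances
# from a common tag atom).
encounter_fixture <- function() {
  n <- 14
  coords <- rbind(matrix(c(10 + seq_len(n), rep(0, 2 * n)), ncol = 3),
                  c(0, 0, 0))
  model <- tiny_model(coords, chain = c(rep("A", n), "B"),
                      resno = c(seq_len(n), 100),
                      atom = c(rep("N", n), "CB"),
                      element = c(rep("N", n), "C"))
  rs <- restraint_set(data.frame(
    chain_a = "A", resno_a = seq_len(n), atom_a = "N",
    chain_b = "B", resno_b = 100, atom_b = "CB",
    lower = 0, upper = c(rep(30, 6), rep(5, 8)),  # first 6 satisfiable
    source = "pre", status = "retained"))
  list(model = model, restraints = rs)
}

default_settings <- function() {
  acquisition_settings(field_mhz = 850, delta_total = 7.7e-3,
                       lb_f1 = 15, lb_f2 = 15, r2_dia_h = 25, r2_dia_mq = 30)
}
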