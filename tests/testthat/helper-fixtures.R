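# Shared fixtures, all generated in code.

# hand-written 3-residue PDB with a known B-factor on one CA
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 26.32           C",
    "ATOM      3  C   ALA A   1       2.009   1.423   0.000  1.00 10.00           C",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00 10.00           N",
    "ATOM      5  CA  GLY A   2       4.123   2.745   0.000  1.00 12.00           C",
    "ATOM      6  C   GLY A   2       5.602   2.401   0.000  1.00 10.00           C",
    "ATOM      7  N   SER A   3       6.420   3.441   0.000  1.00 10.00           N",
    "ATOM      8  CA  SER A   3       7.876   3.301   0.000  1.00 11.00           C",
    "ATOM      9  C   SER A   3       8.400   4.731   0.000  1.00 10.00           C",
    "END"), path)
  path
}

write_two_model_pdb <- function(path = tempfile(fileext = ".pdb"),
                                drop_atom_in_model = NA) {
  atoms <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 26.32           C",
    "ATOM      3  C   ALA A   1       2.009   1.423   0.000  1.00 10.00           C")
  lines <- character(0)
  for (m in 1:3) {
    body <- atoms
    if (!is.na(drop_atom_in_model) && m == drop_atom_in_model) {
      body <- body[-2]
    }
    lines <- c(lines, sprintf("MODEL     %4d", m), body, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# rigid-residue two-block Gaussian system on compact, well-separated clusters
two_block_system <- function(n_frames = 5000, seed = 11, rho_in = 0.9,
                             sep = 40) {
  octa <- rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 4.3, 0),
                c(2.5, 1.4, 4), c(5, 4, 3), c(0, 4, 3))
  ca <- rbind(octa, sweep(octa, 2, c(sep, 0, 0), `+`))
  tpl <- template_from_ca(ca, chain = "A")
  rho <- matrix(0, 12, 12)
  rho[1:6, 1:6] <- rho_in
  rho[7:12, 7:12] <- rho_in
  diag(rho) <- 1
  ens <- gaussian_ensemble(tpl, sigma = 1, rho = rho, n_frames = n_frames,
                           seed = seed)
  list(ens = ens, mask = selection_mask(ens, elety = "CA"),
       truth = rep(1:2, each = 6))
}

# random rigid motion applied to every frame of an ensemble
apply_rigid_motion <- function(ens, seed = 1) {
  set.seed(seed)
  th <- runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  R <- Rz %*% Rx
  shift <- runif(3, -20, 20)
  ens$xyz <- t(apply(ens$xyz, 1, function(fr) {
    m <- matrix(fr, ncol = 3, byrow = TRUE)
    as.numeric(t(sweep(m %*% t(R), 2, shift, `+`)))
  }))
  ens
}
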