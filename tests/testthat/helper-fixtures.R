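# Shared fixtures, built once per test run.

# 20-residue, 5-model low-noise helix with protons; mixed residue types,
# one glycine to exercise the HA3 beta-substitution
tidy_helix <- make_ensemble(
  20, 5, ss_plan = "helix", noise_sd = 2,
  restypes = c(rep("ALA", 6), "GLY", rep("LEU", 7), "PRO", rep("LYS", 5)),
  protons = TRUE, seed = 11)

# 60-residue ensemble with a disordered N-terminus (1-8) and a short
# disordered interior stretch (25-27) inside an otherwise rigid helix
segmented_ensemble <- function(seed = 7, n_models = 10) {
  noise <- rep(2, 60); noise[1:8] <- 80; noise[25:27] <- 80
  make_ensemble(60, n_models, ss_plan = "helix", noise_sd = noise,
                protons = TRUE, seed = seed)
}

# hand-built two-residue molecule with explicit coordinates, M models;
# atoms: list of list(chain, seq, restype, atom, xyz = M x 3 matrix)
build_mol <- function(atoms, M = 1) {
  df <- do.call(rbind, lapply(atoms, function(a)
    data.frame(chain = a$chain %||% "A", seq = a$seq, ins = "",
               restype = a$restype, atom = a$atom,
               element = rogval:::element_of(a$atom),
               stringsAsFactors = FALSE)))
  xyz <- array(NA_real_, c(length(atoms), 3, M))
  for (i in seq_along(atoms)) {
    m <- atoms[[i]]$xyz
    if (is.null(dim(m))) m <- matrix(m, nrow = M, ncol = 3, byrow = TRUE)
    xyz[i, , ] <- t(m)
  }
  new_molecule(df, xyz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_rog <- function(x, level) {
  expect_equal(as.character(x), level)
}
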