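# Restraint analytics: effective distances, violation statistics, classes,
# duplicates, and the simplified NOE completeness.

# molecule with two residues and two proton pairs at controlled distances
two_res_mol <- function(d_pair1, d_pair2 = NULL, M = 1) {
  atoms <- list(
    list(seq = 1, restype = "ALA", atom = "CA", xyz = c(0, 0, 0)),
    list(seq = 1, restype = "ALA", atom = "HA", xyz = c(0, 1, 0)),
    list(seq = 1, restype = "ALA", atom = "H", xyz = c(0, -9, 0)),
    list(seq = 2, restype = "ALA", atom = "CA", xyz = c(d_pair1, 0, 0)),
    list(seq = 2, restype = "ALA", atom = "HA", xyz = c(d_pair1, 1, 0)),
    list(seq = 2, restype = "ALA", atom = "H",
         xyz = c(d_pair2 %||% d_pair1, -9, 0)))
  build_mol(atoms, M = M)
}

restraint_between <- function(mol, a, b, upper, lower = 0) {
  df <- data.frame(chain_a = "A", seq_a = a[1], atom_a = a[2],
                   chain_b = "A", seq_b = b[1], atom_b = b[2],
                   stringsAsFactors = FALSE)
  rogval:::.make_distance_restraint(df, lower, upper, FALSE, mol, "iupac")
}

test_that("effective distance is Euclidean for one pair and r^-6 for groups", {
  mol <- two_res_mol(3.70)
  r1 <- restraint_between(mol, c(1, "HA"), c(2, "HA"), 5)
  expect_equal(effective_distance(r1, mol, 1), 3.70)
  # two contributions both at distance d -> d * 2^(-1/6)
  d <- 3.70
  r2 <- rogval:::.make_distance_restraint(data.frame(
    chain_a = "A", seq_a = c(1, 1), atom_a = c("HA", "H"),
    chain_b = "A", seq_b = c(2, 2), atom_b = c("HA", "H"),
    stringsAsFactors = FALSE), 0, 5, FALSE, mol, "iupac")
  expect_equal(effective_distance(r2, mol, 1), d * 2^(-1 / 6))
})

test_that("k identical pairs collapse to d * k^(-1/6)", {
  for (k in c(2, 3, 6)) {
    d <- 4.2
    atoms <- c(list(list(seq = 1, restype = "ALA", atom = "CA",
                         xyz = c(0, 0, 0))),
               lapply(seq_len(k), function(i)
                 list(seq = 2, restype = "LYS", atom = paste0("HZ", i),
                      xyz = c(d, 0, 0))))
    mol <- build_mol(atoms)
    rows <- data.frame(chain_a = "A", seq_a = 1, atom_a = "CA",
                       chain_b = "A", seq_b = 2,
                       atom_b = paste0("HZ", seq_len(k)),
                       stringsAsFactors = FALSE)
    r <- rogval:::.make_distance_restraint(rows, 0, 9, FALSE, mol, "iupac")
    expect_equal(effective_distance(r, mol, 1), d * k^(-1 / 6))
  }
})

test_that("restraints to missing atoms go red with undefined distances", {
  mol <- two_res_mol(3.7)
  r <- restraint_between(mol, c(1, "HA"), c(9, "HA"), 5)
  expect_length(r$unresolved, 1)
  expect_true(is.na(effective_distance(r, mol, 1)))
  vs <- violation_stats(r, mol)
  expect_rog(vs$rog, "red")
  expect_true(is.na(vs$max))
})

test_that("violation statistics score against the max and RMS cutoffs", {
  # 10 models; vary the distance of the HA(1)-HA(2) pair per model
  make10 <- function(dists) {
    atoms <- list(
      list(seq = 1, restype = "ALA", atom = "HA",
           xyz = matrix(0, length(dists), 3)),
      list(seq = 2, restype = "ALA", atom = "HA",
           xyz = cbind(dists, 0, 0)))
    build_mol(atoms, M = length(dists))
  }
  mol <- make10(rep(3.9, 10))
  r <- restraint_between(mol, c(1, "HA"), c(2, "HA"), 4.0)
  vs <- violation_stats(r, mol)
  expect_equal(vs$max, 0)
  expect_rog(vs$rog, "green")

  mol <- make10(c(4.35, rep(3.9, 9)))
  vs <- violation_stats(restraint_between(mol, c(1, "HA"), c(2, "HA"), 4.0),
                        mol)
  expect_equal(vs$max, 0.35)
  expect_equal(vs$rms, sqrt(0.35^2 / 10), tolerance = 1e-6) # about 0.1107
  expect_rog(vs$rog, "orange")                              # max only
  expect_equal(unname(vs$count_above), c(1, 1, 0))

  mol <- make10(rep(4.60, 10))
  vs <- violation_stats(restraint_between(mol, c(1, "HA"), c(2, "HA"), 4.0),
                        mol)
  expect_equal(vs$max, 0.60)
  expect_rog(vs$rog, "red")
})

test_that("lower-bound and dihedral violations use the same machinery", {
  mol <- two_res_mol(2.0)
  vs <- violation_stats(restraint_between(mol, c(1, "HA"), c(2, "HA"), 9,
                                          lower = 2.5), mol)
  expect_equal(vs$max, 0.5)
  expect_rog(vs$rog, "red")
  # dihedral restraint: helix phi constrained to a wrap-around interval
  mol2 <- tidy_helix
  tf <- tempfile(fileext = ".aco")
  writeLines(c("10 LEU PHI -70.0 -40.0",     # satisfied (phi ~ -57)
               "10 LEU PHI 150.0 -150.0"), tf)  # excess ~ 93 deg -> red
  rl <- read_dihedral_restraints(tf, mol2, "cyana_aco")
  vs1 <- violation_stats(rl$restraints[[1]], mol2)
  vs2 <- violation_stats(rl$restraints[[2]], mol2)
  expect_equal(vs1$max, 0)
  expect_rog(vs1$rog, "green")
  expect_gt(vs2$max, 10)
  expect_rog(vs2$rog, "red")
})

test_that("violation invariants hold across random restraints", {
  mol <- segmented_ensemble(seed = 17, n_models = 6)
  df <- make_restraints(mol, cutoff = 4.5, padding = 0.1, seed = 5)
  tf <- tempfile(); write_distance_restraints(df, tf)
  rl <- read_distance_restraints(tf, mol, "tabular")
  for (r in rl$restraints[seq_len(min(40, length(rl$restraints)))]) {
    vs <- violation_stats(r, mol)
    expect_lte(vs$rms, vs$max + 1e-12)
    cnt <- vs$count_above
    expect_true(all(diff(unname(cnt)) <= 0))   # monotone in threshold
  }
})

test_that("injected violations are recovered to numerical precision", {
  mol <- segmented_ensemble(seed = 23, n_models = 8)
  df <- make_restraints(mol, inject = list(list(index = 7, delta = 0.4),
                                           list(index = 12, delta = 0.73)),
                        seed = 5)
  tf <- tempfile(); write_distance_restraints(df, tf)
  rl <- read_distance_restraints(tf, mol, "tabular")
  for (inj in list(c(7, 0.4), c(12, 0.73))) {
    vs <- violation_stats(rl$restraints[[inj[1]]], mol)
    expect_equal(vs$max, inj[2], tolerance = 1e-6)
  }
})

test_that("sequence-separation classes follow the 1/2-4/5 boundaries", {
  mol <- make_ensemble(60, 2, noise_sd = 2, protons = TRUE, seed = 3)
  pair <- function(s1, s2) restraint_between(mol, c(s1, "HA"), c(s2, "HA"), 9)
  expect_equal(classify_restraint(pair(10, 10)), "intra_residual")
  expect_equal(classify_restraint(pair(10, 11)), "sequential")
  expect_equal(classify_restraint(pair(10, 12)), "medium_range")
  expect_equal(classify_restraint(pair(10, 13)), "medium_range")
  expect_equal(classify_restraint(pair(10, 14)), "medium_range")
  expect_equal(classify_restraint(pair(10, 15)), "long_range")
  multi <- rogval:::.make_distance_restraint(data.frame(
    chain_a = "A", seq_a = c(10, 10), atom_a = "HA",
    chain_b = "A", seq_b = c(40, 55), atom_b = "HA",
    stringsAsFactors = FALSE), 0, 9, FALSE, mol, "iupac")
  expect_equal(classify_restraint(multi), "ambiguous")
})

test_that("duplicates are detected on atom sets regardless of order and bounds", {
  mol <- two_res_mol(3.0)
  mk <- function(a, b, upper) restraint_between(mol, a, b, upper)
  rl <- rogval:::new_restraint_list("t", "distance", list(
    mk(c(1, "HA"), c(2, "HA"), 4.0),
    mk(c(2, "HA"), c(1, "HA"), 5.0),    # reversed order, different bound
    mk(c(1, "H"), c(2, "H"), 4.5),
    mk(c(1, "H"), c(2, "H"), 4.5)))     # identical line
  dup <- find_duplicates(rl)
  expect_length(dup, 2)
  expect_equal(attr(dup, "n_duplicates"), 2L)
  g1 <- dup[[which(vapply(dup, function(g) 1 %in% g$members, TRUE))]]
  expect_setequal(g1$members, c(1, 2))
  expect_equal(g1$retained, 1L)          # 4.0 is the more restrictive upper
})

test_that("the duplicate relation is symmetric and transitive on fixtures", {
  mol <- segmented_ensemble(seed = 31, n_models = 3)
  df <- make_restraints(mol, duplicates = 6, seed = 9)
  tf <- tempfile(); write_distance_restraints(df, tf)
  rl <- read_distance_restraints(tf, mol, "tabular")
  dup <- find_duplicates(rl)
  expect_equal(attr(dup, "n_duplicates"), 6L)
  sigs <- vapply(rl$restraints, rogval:::.restraint_signature, "")
  for (g in dup) {
    expect_equal(length(unique(sigs[g$members])), 1)      # all equal
    expect_false(any(sigs[g$members][1] == sigs[-g$members]))
  }
})

test_that("NOE completeness counts expected, observed and matched pairs", {
  mk_list <- function(mol, df) {
    tf <- tempfile(); write_distance_restraints(df, tf)
    read_distance_restraints(tf, mol, "tabular")
  }
  base_df <- function(upper) data.frame(
    chain_a = "A", seq_a = 1, res_a = "ALA", atom_a = "HA",
    chain_b = "A", seq_b = 2, res_b = "ALA", atom_b = "HA",
    lower = 0, upper = upper, hbond = FALSE, stringsAsFactors = FALSE)
  # pair at 3 A with a matching restraint: 100 %
  mol <- two_res_mol(3.0, d_pair2 = 10)
  cp <- completeness(mol, list(mk_list(mol, base_df(4))), cutoff = 4)
  expect_equal(cp$overall_completeness, 100)
  # same coordinates, no restraints: 0 %
  cp0 <- completeness(mol, list(), cutoff = 4)
  expect_equal(cp0$overall_completeness, 0)
  expect_equal(cp0$n_expected, 1)
  # restraint present but pair at 5 A: expected 0, observed 1, matched 0
  mol5 <- two_res_mol(5.0, d_pair2 = 10)
  cp5 <- completeness(mol5, list(mk_list(mol5, base_df(6))), cutoff = 4)
  expect_equal(cp5$n_expected, 0)
  expect_equal(cp5$n_observed, 1)
  expect_equal(cp5$n_matched, 0)
  # no protons is an error
  molh <- build_mol(list(list(seq = 1, restype = "ALA", atom = "CA",
                              xyz = c(0, 0, 0))))
  expect_error(completeness(molh, list()), "protonated")
})

test_that("hydrogen-bond restraints are excluded from observed pairs", {
  mol <- two_res_mol(3.0, d_pair2 = 10)
  df <- data.frame(chain_a = "A", seq_a = 1, res_a = "ALA", atom_a = "HA",
                   chain_b = "A", seq_b = 2, res_b = "ALA", atom_b = "HA",
                   lower = 0, upper = 4, hbond = TRUE,
                   stringsAsFactors = FALSE)
  tf <- tempfile(); write_distance_restraints(df, tf)
  rl <- read_distance_restraints(tf, mol, "tabular")
  cp <- completeness(mol, list(rl), cutoff = 4)
  expect_equal(cp$n_observed, 0)
})
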