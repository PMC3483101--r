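# Coordinate, restraint, shift and metric file I/O.

test_that("PDB ensembles round-trip through write and read", {
  mol <- tidy_helix
  tf <- tempfile(fileext = ".pdb")
  write_pdb_ensemble(mol, tf)
  back <- read_pdb_ensemble(tf)
  expect_equal(back$M, mol$M)
  expect_equal(back$atoms$atom, mol$atoms$atom)
  expect_equal(back$atoms$seq, mol$atoms$seq)
  expect_equal(back$atoms$restype, mol$atoms$restype)
  expect_lt(max(abs(back$xyz - mol$xyz)), 1e-3)   # PDB has 3 decimals
})

test_that("models with differing atom sets are rejected naming the discrepancy", {
  mol <- make_ensemble(3, 2, noise_sd = 1, seed = 1)
  tf <- tempfile(fileext = ".pdb")
  write_pdb_ensemble(mol, tf)
  lines <- readLines(tf)
  # drop one CB line from MODEL 2
  m2 <- which(grepl("^MODEL", lines))[2]
  cb <- which(grepl("^ATOM", lines) & grepl(" CB ", lines))
  cb2 <- cb[cb > m2][1]
  writeLines(lines[-cb2], tf)
  expect_error(read_pdb_ensemble(tf), "model 2 differs.*CB")
})

test_that("files without coordinates are rejected", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), tf)
  expect_error(read_pdb_ensemble(tf), "no ATOM records")
  expect_error(read_pdb_ensemble(tempfile()), "no such file")
})

test_that("CYANA upl lines parse into bounded restraints", {
  mol <- tidy_helix
  tf <- tempfile(fileext = ".upl")
  writeLines(c("# comment", "14 PRO HA 17 LYS H 4.50"), tf)
  rl <- read_distance_restraints(tf, mol, "cyana_upl")
  expect_equal(length(rl$restraints), 1)
  r <- rl$restraints[[1]]
  expect_equal(r$lower, 0)
  expect_equal(r$upper, 4.5)
  expect_length(r$unresolved, 0)
  ct <- r$contributions[[1]]
  expect_equal(mol$atoms$atom[ct$a], "HA")
  expect_equal(mol$atoms$atom[ct$b], "H")   # HN -> H via convention
})

test_that("bad restraint lines and inverted bounds are parse errors", {
  mol <- tidy_helix
  tf <- tempfile(fileext = ".upl")
  writeLines(c("14 PRO HA 17 LYS H 4.50", "garbage line here"), tf)
  expect_error(read_distance_restraints(tf, mol, "cyana_upl"), "line 2")
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(paste(c("chain_a\tseq_a\tres_a\tatom_a\tchain_b\tseq_b\tres_b\tatom_b\tlower\tupper",
                     "A\t1\tALA\tHA\tA\t2\tALA\tH\t5.0\t3.0"),
                   collapse = "\n"), tf2)
  expect_error(read_distance_restraints(tf2, mol, "tabular"), "below lower")
})

test_that("pseudo-atom references expand and unresolved atoms are retained", {
  mol <- tidy_helix
  tf <- tempfile(fileext = ".upl")
  writeLines(c("8 LEU HA 10 LEU QD1 5.0",   # QD1 protons absent from fixture
               "8 LEU HA 99 LEU HN 5.0"), tf)
  rl <- read_distance_restraints(tf, mol, "cyana_upl")
  expect_length(rl$restraints[[1]]$unresolved, 1)
  expect_match(rl$restraints[[1]]$unresolved, "QD1")
  expect_match(rl$restraints[[2]]$unresolved, "99")
})

test_that("the tabular restraint dialect round-trips bounds and groups", {
  mol <- tidy_helix
  df <- make_restraints(mol, cutoff = 4, padding = 0.5, seed = 3)
  t1 <- tempfile(fileext = ".tsv")
  write_distance_restraints(df, t1)
  rl <- read_distance_restraints(t1, mol, "tabular")
  t2 <- tempfile(fileext = ".tsv")
  write_distance_restraints(rl, t2, mol)
  rl2 <- read_distance_restraints(t2, mol, "tabular")
  expect_equal(length(rl2$restraints), length(rl$restraints))
  sig <- function(rl) vapply(rl$restraints, rogval:::.restraint_signature, "")
  expect_identical(sig(rl2), sig(rl))
  expect_equal(vapply(rl2$restraints, `[[`, 1, "upper"),
               vapply(rl$restraints, `[[`, 1, "upper"))
})

test_that("dihedral restraints map angle names to topology quadruples", {
  mol <- tidy_helix
  tf <- tempfile(fileext = ".aco")
  writeLines(c("14 PRO PHI -120.0 -60.0", "10 LEU PSI 150.0 -150.0"), tf)
  rl <- read_dihedral_restraints(tf, mol, "cyana_aco")
  r <- rl$restraints[[1]]
  expect_equal(mol$atoms$atom[r$atoms], c("C", "N", "CA", "C"))
  expect_equal(mol$atoms$seq[r$atoms], c(13L, 14L, 14L, 14L))
  # wrap-around interval is accepted as-is
  expect_equal(rl$restraints[[2]]$lower, 150)
  expect_equal(rl$restraints[[2]]$upper, -150)
  writeLines("14 PRO BOGUS -10 10", tf)
  expect_error(read_dihedral_restraints(tf, mol, "cyana_aco"),
               "unknown dihedral angle")
})

test_that("shift tables parse from the tabular dialect and NMR-STAR loops", {
  mol <- tidy_helix
  sh <- make_shifts(mol, seed = 5)
  tf <- tempfile(fileext = ".tsv")
  write_shift_table(sh, tf)
  sl <- read_shift_table(tf)
  expect_equal(nrow(sl$shifts), nrow(sh))
  expect_equal(sl$shifts$value, sh$value)
  # duplicate atom row is an error
  write_shift_table(rbind(sh, sh[1, ]), tf)
  expect_error(read_shift_table(tf), "duplicate shift row")
  # NMR-STAR assigned chemical shift loop subset
  star <- c("loop_", "  _Atom_chem_shift.ID",
            "  _Atom_chem_shift.Comp_index_ID", "  _Atom_chem_shift.Comp_ID",
            "  _Atom_chem_shift.Atom_ID", "  _Atom_chem_shift.Val",
            "  _Atom_chem_shift.Val_err",
            "  1 2 ALA HA 4.32 0.02", "  2 2 ALA CA 52.4 0.1", "stop_")
  tf2 <- tempfile(fileext = ".str")
  writeLines(star, tf2)
  sl2 <- read_shift_table(tf2, "nmrstar_loop")
  expect_equal(sl2$shifts$seq, c(2L, 2L))
  expect_equal(sl2$shifts$value, c(4.32, 52.4))
  expect_equal(sl2$shifts$atom, c("HA", "CA"))
})

test_that("external metric tables allow gaps but reject non-numeric cells", {
  mol <- tidy_helix
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("chain\tseq\tramachandran_z\tjanin_z\tg_factor",
               "A\t2\t-0.5\t\t-0.2",
               "A\t99\t-1.5\t-0.1\t-0.1"), tf)
  em <- read_external_metrics(tf, mol)
  expect_true(is.na(em$janin_z[1]))
  recs <- attr(em, "records")
  expect_equal(recs$criterion, "metrics_unknown_residue")
  expect_match(recs$entity_path, "99")
  writeLines(c("chain\tseq\tramachandran_z", "A\t2\tnot_a_number"), tf)
  expect_error(read_external_metrics(tf, mol), "non-numeric")
})
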