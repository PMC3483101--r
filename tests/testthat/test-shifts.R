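# Chemical-shift Z-scoring, assignment consistency, residue-specific
# shift/conformation checks, peak agreement, and SS consensus.

ref_with <- function(restype, atom, mean, sd) {
  ref <- synthetic_reference_shifts()
  ref <- ref[!(ref$restype == restype & ref$atom == atom), ]
  rbind(ref, data.frame(restype = restype, atom = atom, mean = mean, sd = sd,
                        count = 100L, stringsAsFactors = FALSE))
}

test_that("shift Z-scores are standardised against the reference entry", {
  ref <- ref_with("ASN", "HD22", 7.15, 0.5556)
  expect_equal(shift_zscore(7.15, "ASN", "HD22", ref), 0)
  # a 2.5 ppm offset at this SD is 4.5 standard deviations
  expect_equal(shift_zscore(9.65, "ASN", "HD22", ref), 2.5 / 0.5556,
               tolerance = 1e-3)
  expect_true(is.na(shift_zscore(1.0, "ASN", "HD99", ref)))
  # linearity: shifting value and mean together leaves Z unchanged
  set.seed(3)
  for (c_off in rnorm(5, 0, 10)) {
    ref2 <- ref; ref2$mean <- ref2$mean + c_off
    expect_equal(shift_zscore(9.65 + c_off, "ASN", "HD22", ref2),
                 shift_zscore(9.65, "ASN", "HD22", ref), tolerance = 1e-9)
  }
})

test_that("shift lists are flagged for outliers and missing coordinates", {
  mol <- tidy_helix
  df <- make_shifts(mol, outliers = list(list(chain = "A", seq = 10,
                                              atom = "HA", z = 4.5)),
                    seed = 2)
  # add a shift for an atom that has no coordinates
  df <- rbind(df, data.frame(chain = "A", seq = 3, res = "ALA", atom = "HB1",
                             value = 1.4, sd = 0))
  sl <- structure(list(shifts = df, rog = rog("green")),
                  class = "rog_shift_list")
  an <- analyze_shifts(sl, mol)
  i <- which(an$table$seq == 10 & an$table$atom == "HA")
  expect_equal(an$table$z[i], 4.5, tolerance = 1e-9)
  expect_equal(an$table$rog[i], "orange")
  j <- which(an$table$atom == "HB1")
  expect_equal(an$table$rog[j], "red")
  expect_true("cs_no_coordinates" %in% an$records$criterion)
  expect_rog(an$rog, "red")     # list propagates the worst member
})

test_that("clean synthetic shifts produce no flags", {
  mol <- tidy_helix
  sl <- structure(list(shifts = make_shifts(mol, seed = 4),
                       rog = rog("green")), class = "rog_shift_list")
  an <- analyze_shifts(sl, mol)
  expect_false(any(abs(an$table$z) > 3, na.rm = TRUE))
  expect_equal(nrow(check_assignments(sl, mol)), 0)
})

test_that("assignment issues are flagged orange", {
  mol <- tidy_helix
  base <- data.frame(chain = "A", seq = 10, res = "LEU",
                     atom = c("HB2", "QB"), value = c(1.8, 2.8), sd = 0,
                     stringsAsFactors = FALSE)
  sl <- structure(list(shifts = base, rog = rog("green")),
                  class = "rog_shift_list")
  recs <- check_assignments(sl, mol)
  expect_equal(recs$criterion, "cs_stereo_conflict")
  expect_equal(recs$rog, "orange")
  # duplicate assignment
  dup <- base[c(1, 1), ]
  sl2 <- structure(list(shifts = dup, rog = rog("green")),
                   class = "rog_shift_list")
  expect_true("cs_duplicate_assignment" %in%
                check_assignments(sl2, mol)$criterion)
  # pseudo consistent with both members -> silent
  ok <- data.frame(chain = "A", seq = 10, res = "LEU",
                   atom = c("HB2", "HB3", "QB"), value = c(1.8, 1.82, 1.81),
                   sd = 0, stringsAsFactors = FALSE)
  sl3 <- structure(list(shifts = ok, rog = rog("green")),
                   class = "rog_shift_list")
  expect_equal(nrow(check_assignments(sl3, mol)), 0)
})

test_that("proline shift/peptide-bond consistency uses the CB-CG difference", {
  expect_null(proline_consistency(32.1, 22.5, "cis"))     # delta 9.6: cis
  rec <- proline_consistency(27.0, 22.5, "cis")           # delta 4.5: trans
  expect_equal(rec$criterion, "pro_omega_inconsistency")
  expect_equal(rec$rog, "orange")
  expect_null(proline_consistency(27.0, NA, "cis"))       # indeterminate
  expect_null(proline_consistency(27.0, 20.0, "trans"))   # delta 7: no call
})

test_that("leucine methyl shifts are checked against the chi2 consensus", {
  trans_chi2 <- rep(175, 10)
  gauche_chi2 <- rep(62, 10)
  expect_null(leucine_consistency(25.0, 23.0, trans_chi2))  # predicts trans
  rec <- leucine_consistency(23.0, 25.0, trans_chi2)        # predicts gauche+
  expect_equal(rec$criterion, "leu_sidechain_inconsistency")
  expect_equal(rec$rog, "orange")
  expect_null(leucine_consistency(23.0, 25.0, gauche_chi2))
  expect_null(leucine_consistency(NA, 25.0, trans_chi2))
  expect_null(leucine_consistency(23.0, 25.0, rep(-60, 10))) # indeterminate
})

test_that("peak positions are scored against assigned shifts per dimension", {
  df <- data.frame(chain = "A", seq = 5, res = "ALA", atom = c("H", "N"),
                   value = c(8.20, 118.0), sd = 0, stringsAsFactors = FALSE)
  sl <- structure(list(shifts = df, rog = rog("green")),
                  class = "rog_shift_list")
  peak <- function(h, n) list(positions = c(h, n),
                              assignments = c("A.5.H", "A.5.N"))
  p0 <- peak_position_check(peak(8.20, 118.0), sl)
  expect_equal(p0$z, c(0, 0))
  expect_rog(p0$rog, "green")
  p1 <- peak_position_check(peak(8.215, 118.0), sl)   # 1H off 0.015 -> Z 1.5
  expect_equal(p1$z[1], 1.5)
  expect_rog(p1$rog, "orange")
  p2 <- peak_position_check(peak(8.225, 118.0), sl)   # 1H off 0.025 -> Z 2.5
  expect_equal(p2$z[1], 2.5)
  expect_rog(p2$rog, "red")
  # 15N dimension uses the 0.15 ppm SD
  pn <- peak_position_check(peak(8.20, 118.225), sl)
  expect_equal(pn$z[2], 1.5)
  # unassigned dimension is orange
  pu <- peak_position_check(list(positions = c(8.2, 118),
                                 assignments = c("A.5.H", NA)), sl)
  expect_rog(pu$rog, "orange")
  expect_true("peak_unassigned" %in% pu$records$criterion)
})

test_that("peak ROG is monotone in the position offset", {
  df <- data.frame(chain = "A", seq = 5, res = "ALA", atom = "H",
                   value = 8.2, sd = 0, stringsAsFactors = FALSE)
  sl <- structure(list(shifts = df, rog = rog("green")),
                  class = "rog_shift_list")
  lev <- vapply(seq(0, 0.05, by = 0.005), function(off) {
    r <- peak_position_check(list(positions = 8.2 + off,
                                  assignments = "A.5.H"), sl)
    unclass(r$rog)
  }, 1L)
  expect_true(all(diff(lev) >= 0))
})

test_that("secondary-structure consensus collapses to three states", {
  expect_equal(consensus_secondary_structure(c("H", "H", "E")), "H")
  expect_equal(consensus_secondary_structure(c("E", "E", "E")), "E")
  expect_equal(consensus_secondary_structure(c("H", "E")), "C")  # tie
  expect_equal(consensus_secondary_structure(c("G", "G", "T")), "H")
  # I maps to helix only with the extension toggle
  expect_equal(consensus_secondary_structure(c("I", "I", "C")), "C")
  expect_equal(consensus_secondary_structure(c("I", "I", "C"),
                                             include_pi = TRUE), "H")
  # M copies of one string return that string's collapse exactly
  s <- "HHHTTEEEBGS"
  expect_equal(consensus_secondary_structure(rep(s, 7)), "HHHCCEEEEHC")
})
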