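# Dihedral primitives, circular statistics, D1/D2, omega deviation,
# superposition.

# independent brute-force dihedral oracle: explicit projection onto the
# plane perpendicular to the central bond, signed via the cross product
oracle_dihedral <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  u <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * u) * u
  v2 <- (p4 - p3) - sum((p4 - p3) * u) * u
  ang <- acos(max(-1, min(1, sum(v1 * v2) /
                            sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  s <- sign(sum(cross(v1, v2) * u))
  rogval::wrap_angle(if (s < 0) -ang else ang)
}

test_that("dihedral_angle follows the right-handed convention on planar and chiral cases", {
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  # trans maps to the -180 representative of the [-180, 180) range
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), -180)
  out_of_plane <- dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))
  expect_equal(abs(out_of_plane), 90)
  expect_equal(out_of_plane,
               oracle_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1)))
})

test_that("dihedral_angle agrees with the vector oracle and bio3d on random point sets", {
  set.seed(42)
  for (k in 1:25) {
    p <- matrix(rnorm(12), 4, 3)
    mine <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(mine, oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
    expect_equal(mine,
                 as.numeric(bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)),
                 tolerance = 1e-6)
    # reversing the atom order preserves the angle; mirroring flips the sign
    expect_equal(mine, dihedral_angle(p[4, ], p[3, ], p[2, ], p[1, ]),
                 tolerance = 1e-9)
    pm <- p; pm[, 3] <- -pm[, 3]
    expect_equal(rogval::wrap_angle(mine + dihedral_angle(pm[1, ], pm[2, ],
                                                          pm[3, ], pm[4, ])),
                 0, tolerance = 1e-9)
  }
})

test_that("collinear central bonds give an undefined dihedral", {
  expect_true(is.na(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                   c(3, 1, 0))))
})

test_that("circular variance matches its closed forms and invariances", {
  expect_equal(circular_variance(c(30, 30, 30)), 0)
  expect_equal(circular_variance(c(0, 180)), 1)
  expect_equal(circular_variance(c(0, 90)), 1 - sqrt(2) / 2)
  set.seed(1)
  for (k in 1:10) {
    x <- runif(8, -180, 180)
    cv <- circular_variance(x)
    expect_gte(cv, 0); expect_lte(cv, 1)
    # invariant under global rotation and relabelling
    expect_equal(circular_variance(x + runif(1, -360, 360)), cv,
                 tolerance = 1e-12)
    expect_equal(circular_variance(sample(x)), cv, tolerance = 1e-12)
  }
})

test_that("ideal helix fixture yields canonical phi/psi and topology-aware chi", {
  mol <- tidy_helix
  rt <- residue_table(mol)
  dd <- molecule_dihedrals(mol)
  interior <- dd$seq > 1 & dd$seq < 20
  phi <- dd[dd$angle == "PHI" & interior, ]
  psi <- dd[dd$angle == "PSI" & interior, ]
  expect_true(all(abs(phi$circular_mean + 57) < 5))
  expect_true(all(abs(psi$circular_mean + 47) < 5))
  # no phi at the N-terminus, no psi at the C-terminus
  expect_false(any(dd$angle == "PHI" & dd$seq == 1))
  expect_false(any(dd$angle == "PSI" & dd$seq == 20))
  # glycine has no chi series; fixtures lack side chains beyond CB anyway
  gly <- which(rt$restype == "GLY")
  expect_false("CHI1" %in% names(residue_dihedrals(mol, gly, rt)))
})

test_that("D2 of residue i is identical to D1 of residue i+1", {
  for (mol in list(tidy_helix, segmented_ensemble(seed = 3, n_models = 4))) {
    dd <- molecule_dihedrals(mol)
    d1 <- dd[dd$angle == "D1", ]
    d2 <- dd[dd$angle == "D2", ]
    expect_gt(nrow(d2), 0)
    for (i in seq_len(nrow(d2))) {
      j <- which(d1$seq == d2$seq[i] + 1 & d1$chain == d2$chain[i])
      expect_length(j, 1)
      expect_identical(d2$values[[i]], d1$values[[j]])
    }
  }
})

test_that("D1 matches the generic dihedral on extracted beta-carbon coordinates", {
  mol <- make_ensemble(6, 3, ss_plan = "strand", noise_sd = 1, seed = 5)
  dd <- molecule_dihedrals(mol)
  d1_3 <- dd[dd$angle == "D1" & dd$seq == 3, ]$values[[1]]
  at <- function(seq, name, m) mol$xyz[mol$lookup[paste("A", seq, "", name,
                                                        sep = "|")], , m]
  for (m in 1:3)
    expect_equal(d1_3[m], dihedral_angle(at(2, "CB", m), at(2, "CA", m),
                                         at(3, "CA", m), at(3, "CB", m)))
})

test_that("a two-residue chain defines D1 only for the second residue", {
  mol <- make_ensemble(2, 2, noise_sd = 1, seed = 2)
  dd <- molecule_dihedrals(mol)
  expect_identical(dd$seq[dd$angle == "D1"], 2L)
  expect_identical(dd$seq[dd$angle == "D2"], 1L)
})

test_that("omega deviation averages circular distance to the nearer reference", {
  expect_equal(omega_deviation(rep(179.7, 5))$deviation, 0)
  r <- omega_deviation(rep(170, 4), trans_ref = 180)
  expect_equal(r$deviation, 10)
  expect_equal(r$state, "trans")
  expect_equal(omega_deviation(c(165, 165), trans_ref = 180)$deviation, 15)
  # cis call
  expect_equal(omega_deviation(c(5, -5))$state, "cis")
  # wrap-around: -175 is 5 degrees from trans at 180
  expect_equal(omega_deviation(c(-175, 175), trans_ref = 180)$deviation, 5)
})

test_that("superposition is exact for copies and invariant under rigid motion", {
  mol <- tidy_helix
  # M identical copies -> RMSD 0 +/- 0
  xyz <- array(mol$xyz[, , 1], c(nrow(mol$atoms), 3, 4))
  copies <- new_molecule(mol$atoms, xyz)
  s0 <- superpose(copies)
  expect_equal(s0$rmsd_mean, 0, tolerance = 1e-8)
  expect_equal(s0$rmsd_sd, 0, tolerance = 1e-8)
  # rigidly moving one model leaves the RMSDs unchanged
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- mol
  moved$xyz[, , 2] <- t(R %*% t(moved$xyz[, , 2])) + rep(c(5, -3, 2),
                                                         each = nrow(mol$atoms))
  s1 <- superpose(mol); s2 <- superpose(moved)
  expect_equal(s1$rmsd_per_model, s2$rmsd_per_model, tolerance = 1e-6)
  expect_equal(s1$closest_model, s2$closest_model)
  # closest model minimises the RMSD to the mean
  expect_equal(s1$closest_model, which.min(s1$rmsd_per_model))
})

test_that("superposition refuses fewer than 3 atoms", {
  mol <- build_mol(list(
    list(seq = 1, restype = "ALA", atom = "CA", xyz = c(0, 0, 0)),
    list(seq = 2, restype = "ALA", atom = "CA", xyz = c(3.8, 0, 0))), M = 1)
  expect_error(superpose(mol), "fewer than 3")
})
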