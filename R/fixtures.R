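# Deterministic synthetic-data generator.  Chains are built from ideal
# internal coordinates (bond lengths/angles below) with per-model Gaussian
# noise on phi/psi; regions given a large angular noise SD (> ~40 deg) become
# disordered (circular variance > 0.2) by construction.  Absolute geometric
# accuracy is irrelevant here: only the statistical structure (ordered vs
# disordered regions, injected violations, forced shift outliers) matters.

# ideal backbone internal coordinates (Angstrom / degrees)
.GEOM <- list(b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
              b_CACB = 1.521, b_CH = 1.09, b_NH = 1.01,
              a_CACN = 116.2, a_CNCA = 121.7, a_NCAC = 111.2, a_CACO = 120.8)

# canonical (phi, psi) per secondary-structure plan code
.SS_ANGLES <- list(helix = c(-57, -47), strand = c(-120, 130),
                   coil = c(-75, 145))

# run `code` with a private RNG stream seeded by `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# NeRF placement: point d bonded to c with |cd| = bond, angle(b,c,d) = angle
# and dihedral(a,b,c,d) = torsion (degrees)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- .cross(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cbind(bc, .cross(n, bc), n)
  c + as.vector(m %*% (bond * c(-cos(ang), sin(ang) * cos(tor),
                                sin(ang) * sin(tor))))
}

# tetrahedral substituents on CA: CB-equivalent side and HA side.
# `flip` selects the branch; the CB branch is used for Gly HA3 as well, so
# the D1/D2 beta-substitution is geometrically consistent.
.ca_substituent <- function(n, ca, c, bond, flip = FALSE) {
  u1 <- n - ca; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c - ca; u2 <- u2 / sqrt(sum(u2^2))
  bis <- u1 + u2; bis <- bis / sqrt(sum(bis^2))
  perp <- .cross(u2, u1); perp <- perp / sqrt(sum(perp^2))
  s <- if (flip) -1 else 1
  ca + bond * (-0.616 * bis + s * 0.788 * perp)
}

.build_model <- function(restypes, phi, psi, omega, protons) {
  n_res <- length(restypes)
  rows <- list()
  add <- function(i, name, xyz) {
    rows[[length(rows) + 1L]] <<- list(seq = i, atom = name, xyz = xyz)
  }
  N <- c(0, 0, 0); CA <- c(.GEOM$b_NCA, 0, 0)
  C <- place_atom(c(0, 0, 1), N, CA, .GEOM$b_CAC, .GEOM$a_NCAC, 0)
  for (i in seq_len(n_res)) {
    add(i, "N", N); add(i, "CA", CA); add(i, "C", C)
    if (restypes[i] == "GLY") {
      add(i, "HA3", .ca_substituent(N, CA, C, .GEOM$b_CH))
      if (protons) add(i, "HA2", .ca_substituent(N, CA, C, .GEOM$b_CH, flip = TRUE))
    } else {
      add(i, "CB", .ca_substituent(N, CA, C, .GEOM$b_CACB))
      if (protons) add(i, "HA", .ca_substituent(N, CA, C, .GEOM$b_CH, flip = TRUE))
    }
    psi_i <- if (i < n_res) psi[i] else 140
    O <- place_atom(N, CA, C, .GEOM$b_CO, .GEOM$a_CACO, wrap_angle(psi_i + 180))
    add(i, "O", O)
    if (i < n_res) {
      N2 <- place_atom(N, CA, C, .GEOM$b_CN, .GEOM$a_CACN, psi[i])
      CA2 <- place_atom(CA, C, N2, .GEOM$b_NCA, .GEOM$a_CNCA, omega[i + 1])
      C2 <- place_atom(C, N2, CA2, .GEOM$b_CAC, .GEOM$a_NCAC, phi[i + 1])
      if (protons && restypes[i + 1] != "PRO") {
        # amide H trans to the carbonyl O across the peptide bond
        add(i + 1, "H", place_atom(CA, C, N2, .GEOM$b_NH, 119, 0))
      }
      N <- N2; CA <- CA2; C <- C2
    }
  }
  rows
}

#' Generate a synthetic multi-model ensemble
#'
#' Builds an `n_models`-member ensemble of an `n_res`-residue chain from
#' ideal internal coordinates. Each model draws phi/psi as the canonical
#' secondary-structure values plus Gaussian noise with per-residue standard
#' deviation `noise_sd`; omega stays trans with 1 degree noise. Residues
#' given `noise_sd` above roughly 40 degrees come out disordered
#' (phi/psi circular variance > 0.2).
#'
#' @param n_res number of residues.
#' @param n_models number of models M.
#' @param ss_plan per-residue plan, values in `"helix"`, `"strand"`,
#'   `"coil"`; recycled if scalar.
#' @param noise_sd per-residue angular noise SD in degrees (recycled).
#' @param restypes per-residue three-letter codes (recycled; default `"ALA"`
#'   interior with the requested types). Use `"GLY"` entries to exercise the
#'   HA3 beta-substitution.
#' @param chain chain identifier.
#' @param protons add HA/HA2 and amide H protons (HA3 is always present on
#'   glycine).
#' @param seed integer seed; same seed gives identical output.
#' @return a `"rog_molecule"`.
#' @export
make_ensemble <- function(n_res, n_models, ss_plan = "helix", noise_sd = 2,
                          restypes = "ALA", chain = "A", protons = FALSE,
                          seed = 1) {
  ss_plan <- rep_len(ss_plan, n_res)
  noise_sd <- rep_len(noise_sd, n_res)
  restypes <- toupper(rep_len(restypes, n_res))
  base <- t(vapply(ss_plan, function(s) .SS_ANGLES[[s]], numeric(2)))
  with_seed(seed, {
    models <- lapply(seq_len(n_models), function(m) {
      phi <- wrap_angle(base[, 1] + stats::rnorm(n_res, 0, noise_sd))
      psi <- wrap_angle(base[, 2] + stats::rnorm(n_res, 0, noise_sd))
      omega <- wrap_angle(180 + stats::rnorm(n_res, 0, 1))
      .build_model(restypes, phi, psi, omega, protons)
    })
    key <- function(rows) vapply(rows, function(r) paste(r$seq, r$atom), "")
    k1 <- key(models[[1]])
    xyz <- array(NA_real_, c(length(k1), 3, n_models))
    for (m in seq_len(n_models)) {
      stopifnot(identical(key(models[[m]]), k1))
      xyz[, , m] <- t(vapply(models[[m]], function(r) r$xyz, numeric(3)))
    }
    seqs <- vapply(models[[1]], function(r) as.integer(r$seq), 1L)
    names_ <- vapply(models[[1]], function(r) r$atom, "")
    ord <- order(seqs, match(names_, c("N", "H", "CA", "HA", "HA2", "HA3",
                                       "CB", "C", "O")))
    atoms <- data.frame(chain = chain, seq = seqs[ord], ins = "",
                        restype = restypes[seqs[ord]], atom = names_[ord],
                        element = element_of(names_[ord]),
                        stringsAsFactors = FALSE)
    new_molecule(atoms, xyz[ord, , , drop = FALSE])
  })
}

#' Generate distance restraints recovering a synthetic ensemble
#'
#' Takes proton pairs of model 1 that are within `cutoff` and not bonded to
#' the same heavy atom, and writes one restraint per pair with
#' `upper = distance + padding`, `lower = 0`. Injected entries override the
#' upper bound with (max distance over all models) minus `delta`, so the
#' restraint's maximum ensemble violation equals `delta` exactly. Exact
#' duplicate rows of the first `duplicates` restraints are appended.
#'
#' @param mol a protonated `"rog_molecule"` (see [make_ensemble()]).
#' @param cutoff pair selection cutoff in Angstrom.
#' @param padding slack added to the model-1 distance (Angstrom).
#' @param inject list of `list(index =, delta =)` violation injections.
#' @param duplicates number of duplicate rows to append.
#' @param seed integer seed (used when `max_restraints` subsamples).
#' @param max_restraints optional cap on the number of base restraints.
#' @return data.frame in the tabular restraint dialect (see
#'   [write_distance_restraints()]).
#' @export
make_restraints <- function(mol, cutoff = 4.0, padding = 0.5, inject = list(),
                            duplicates = 0, seed = 1, max_restraints = Inf) {
  h <- which(mol$atoms$element == "H")
  if (!length(h)) stop("molecule has no protons")
  x1 <- mol$xyz[h, , 1, drop = TRUE]
  d <- as.matrix(stats::dist(x1))
  parent <- paste(mol$atoms$chain[h], mol$atoms$seq[h])
  pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  keep <- parent[pairs[, 1]] != parent[pairs[, 2]]  # inter-residue only
  pairs <- pairs[keep, , drop = FALSE]
  df <- with_seed(seed, {
    if (nrow(pairs) > max_restraints)
      pairs <- pairs[sort(sample(nrow(pairs), max_restraints)), , drop = FALSE]
    ai <- h[pairs[, 1]]; bi <- h[pairs[, 2]]
    data.frame(chain_a = mol$atoms$chain[ai], seq_a = mol$atoms$seq[ai],
               res_a = mol$atoms$restype[ai], atom_a = mol$atoms$atom[ai],
               chain_b = mol$atoms$chain[bi], seq_b = mol$atoms$seq[bi],
               res_b = mol$atoms$restype[bi], atom_b = mol$atoms$atom[bi],
               lower = 0, upper = round(d[pairs] + padding, 3),
               hbond = FALSE, stringsAsFactors = FALSE)
  })
  for (inj in inject) {
    i <- inj$index
    ai <- mol$lookup[atom_key(df$chain_a[i], df$seq_a[i], df$atom_a[i])]
    bi <- mol$lookup[atom_key(df$chain_b[i], df$seq_b[i], df$atom_b[i])]
    dm <- sqrt(colSums((mol$xyz[ai, , ] - mol$xyz[bi, , ])^2))
    df$upper[i] <- max(dm) - inj$delta
  }
  if (duplicates > 0)
    df <- rbind(df, df[seq_len(min(duplicates, nrow(df))), ])
  rownames(df) <- NULL
  df
}

#' Generate a synthetic chemical-shift table
#'
#' Shift values are drawn as `mean + N(0, 0.2 * sd)` from the reference
#' statistics; atoms listed in `outliers` are instead forced to exactly
#' `mean + z * sd` so a known Z-score can be recovered.
#'
#' @param mol a `"rog_molecule"`.
#' @param ref reference shift statistics (see [synthetic_reference_shifts()]).
#' @param outliers list of `list(chain =, seq =, atom =, z =)`.
#' @param seed integer seed.
#' @return data.frame with columns `chain, seq, res, atom, value, sd`.
#' @export
make_shifts <- function(mol, ref = synthetic_reference_shifts(),
                        outliers = list(), seed = 1) {
  a <- mol$atoms
  if (!nrow(a)) stop("empty molecule")
  rk <- paste(a$restype, a$atom)
  m <- match(rk, paste(ref$restype, ref$atom))
  keep <- !is.na(m)
  df <- with_seed(seed, data.frame(
    chain = a$chain[keep], seq = a$seq[keep], res = a$restype[keep],
    atom = a$atom[keep],
    value = round(ref$mean[m[keep]] +
                    stats::rnorm(sum(keep), 0, 0.2 * ref$sd[m[keep]]), 3),
    sd = 0, stringsAsFactors = FALSE))
  for (o in outliers) {
    i <- which(df$chain == o$chain & df$seq == o$seq & df$atom == o$atom)
    j <- which(ref$restype == df$res[i[1]] & ref$atom == o$atom)
    df$value[i] <- ref$mean[j] + o$z * ref$sd[j]
  }
  df
}

#' Synthetic reference chemical-shift statistics
#'
#' A rule-based stand-in for database-derived per-(residue type, atom) shift
#' means and SDs, sufficient to exercise Z-scoring: amide H near 8.2 ppm,
#' HA near 4.3, aliphatic side-chain protons by branch depth, aromatics near
#' 7.1, CA/CB/C/N at typical protein values. Synthetic values, not measured
#' statistics.
#'
#' @return data.frame with columns `restype, atom, mean, sd, count`.
#' @export
synthetic_reference_shifts <- function() {
  pt <- PROTON_TABLE
  mean_h <- function(atom, parent) {
    ifelse(parent == "N" | substr(parent, 1, 1) == "N", 7.9,
    ifelse(atom == "HA" | atom %in% c("HA2", "HA3"), 4.3,
    ifelse(grepl("^H[DEZH]", atom) & substr(parent, 1, 1) == "C" &
             nchar(parent) == 3 & !grepl("[0-9]$", atom), 7.1,  # aromatic CH
    ifelse(grepl("^HB", atom), 1.9,
    ifelse(grepl("^HG", atom), 1.3,
           0.9)))))
  }
  h <- data.frame(restype = pt$restype, atom = pt$atom,
                  mean = mean_h(pt$atom, pt$parent),
                  sd = ifelse(pt$parent == "N", 0.6, 0.35),
                  stringsAsFactors = FALSE)
  heavy <- do.call(rbind, lapply(AMINO_ACIDS, function(r) {
    data.frame(restype = r, atom = c("CA", "CB", "C", "N"),
               mean = c(57, 33, 176, 119), sd = c(2.2, 2.5, 1.8, 4.5),
               stringsAsFactors = FALSE)
  }))
  out <- rbind(h, heavy)
  out$count <- 1000L
  out
}

#' Synthetic per-residue external-metric table
#'
#' Emulates the per-residue Z-scores a structure-validation package would
#' supply (Ramachandran Z, Janin Z, G-factor): baseline values drawn near
#' -0.3 with SD 0.3, and listed residues forced to given values.
#'
#' @param mol a `"rog_molecule"`.
#' @param force list of `list(chain =, seq =, metric =, value =)`.
#' @param seed integer seed.
#' @return data.frame `chain, seq, ramachandran_z, janin_z, g_factor`.
#' @export
make_external_metrics <- function(mol, force = list(), seed = 1) {
  rt <- residue_table(mol)
  df <- with_seed(seed, data.frame(
    chain = rt$chain, seq = rt$seq,
    ramachandran_z = round(stats::rnorm(nrow(rt), -0.3, 0.3), 3),
    janin_z = round(stats::rnorm(nrow(rt), -0.3, 0.3), 3),
    g_factor = round(stats::rnorm(nrow(rt), -0.3, 0.3), 3),
    stringsAsFactors = FALSE))
  for (f in force) {
    i <- which(df$chain == f$chain & df$seq == f$seq)
    df[i, f$metric] <- f$value
  }
  df
}

#' Synthetic D1/D2 reference density
#'
#' Builds a pluggable 2D histogram of (D1, D2) values from a generated
#' low-noise ensemble of the requested secondary structure, on a regular
#' grid over `[-180, 180)`. Used as the reference for D1/D2 Z-scoring in
#' tests and fixtures; a synthetic stand-in, not derived from crystal
#' structures.
#'
#' @param ss `"helix"`, `"strand"` or `"coil"`.
#' @param bin bin width in degrees.
#' @param n_res,n_models size of the generated calibration ensemble.
#' @param seed integer seed.
#' @return a `"d1d2_density"` object (see [d1d2_density()]).
#' @export
synthetic_d1d2_density <- function(ss = "helix", bin = 10, n_res = 40,
                                   n_models = 25, seed = 99) {
  mol <- make_ensemble(n_res, n_models, ss_plan = ss, noise_sd = 8, seed = seed)
  dd <- molecule_dihedrals(mol)
  d1 <- dd[dd$angle == "D1", ]; d2 <- dd[dd$angle == "D2", ]
  key <- paste(d1$chain, d1$seq); key2 <- paste(d2$chain, d2$seq)
  common <- intersect(key, key2)
  x <- unlist(d1$values[match(common, key)])
  y <- unlist(d2$values[match(common, key2)])
  d1d2_density(x, y, bin = bin)
}

#' Generate per-model secondary-structure code strings
#'
#' @param plan per-residue plan codes (`"helix"`, `"strand"`, `"coil"`),
#'   emitted as DSSP-style letters H/E/C.
#' @param n_models number of strings.
#' @param flip list of `list(model =, pos =, code =)` single-position edits.
#' @return character vector of length `n_models`.
#' @export
make_ss_strings <- function(plan, n_models, flip = list()) {
  code <- c(helix = "H", strand = "E", coil = "C")[plan]
  out <- rep(paste(code, collapse = ""), n_models)
  for (f in flip) substr(out[f$model], f$pos, f$pos) <- f$code
  out
}
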