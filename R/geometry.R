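# Dihedral geometry and circular statistics over the model dimension of an
# ensemble: phi/psi/omega/chi1/chi2, the D1/D2 virtual dihedrals summarising
# backbone direction over consecutive residue pairs, circular mean/variance,
# and iterative superposition onto the mean coordinates.

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap angles to [-180, 180) degrees
#' @param x angles in degrees.
#' @export
wrap_angle <- function(x) ((x + 180) %% 360) - 180

#' Dihedral angle of four points
#'
#' Right-handed (IUPAC) sign convention: looking down the 2-3 bond, a
#' clockwise rotation from the 1-2 bond projection to the 3-4 bond projection
#' is positive. The planar trans arrangement maps to -180 (the range is
#' `[-180, 180)`).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees, or `NA` when consecutive bond vectors are
#'   collinear (the torsion is undefined).
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  u2 <- b2 / sqrt(sum(b2^2))
  wrap_angle(atan2(sum(.cross(n1, n2) * u2), sum(n1 * n2)) * 180 / pi)
}

#' Circular mean of angles in degrees
#' @param x angles in degrees (`NA`s removed).
#' @return mean direction in degrees in `[-180, 180)`, `NA` if no data or if
#'   the resultant vector vanishes.
#' @export
circular_mean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  r <- x * pi / 180
  s <- mean(sin(r)); c <- mean(cos(r))
  if (s^2 + c^2 < 1e-24) return(NA_real_)
  wrap_angle(atan2(s, c) * 180 / pi)
}

#' Circular variance of angles in degrees
#'
#' Defined as one minus the mean resultant length of the unit vectors at the
#' observed angles: 0 when all angles coincide (mod 360), 1 when they cancel
#' completely.
#'
#' @param x angles in degrees (`NA`s removed).
#' @return value in `[0, 1]`, `NA` if no data.
#' @export
circular_variance <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  r <- x * pi / 180
  1 - sqrt(mean(sin(r))^2 + mean(cos(r))^2)
}

#' Smallest circular distance between two angles (degrees)
#' @param a,b angles in degrees (vectorised).
#' @return non-negative distance in `[0, 180]`.
#' @export
circular_distance <- function(a, b) abs(wrap_angle(a - b))

# ---- named dihedrals over the ensemble -------------------------------------

# coordinates of a named atom in residue row `i` of `rt` for all models:
# (3 x M) matrix, or NULL if absent
.res_atom_xyz <- function(mol, rt, i, name) {
  if (i < 1 || i > nrow(rt)) return(NULL)
  j <- mol$lookup[atom_key(rt$chain[i], rt$seq[i], name, rt$ins[i])]
  if (is.na(j)) return(NULL)
  mol$xyz[j, , , drop = TRUE]
}

.series_from_quad <- function(mol, a, b, c, d) {
  if (is.null(a) || is.null(b) || is.null(c) || is.null(d)) return(NULL)
  if (mol$M == 1) { a <- cbind(a); b <- cbind(b); c <- cbind(c); d <- cbind(d) }
  vapply(seq_len(mol$M), function(m)
    dihedral_angle(a[, m], b[, m], c[, m], d[, m]), numeric(1))
}

# beta-direction atom used by D1/D2: CB, or HA3 for glycine
.cbeq <- function(mol, rt, i) {
  if (i < 1 || i > nrow(rt)) return(NULL)
  if (rt$restype[i] == "GLY") .res_atom_xyz(mol, rt, i, "HA3")
  else .res_atom_xyz(mol, rt, i, "CB")
}

.same_chain <- function(rt, i, j) {
  i >= 1 && j <= nrow(rt) && i <= nrow(rt) && j >= 1 &&
    rt$chain[i] == rt$chain[j]
}

#' All named dihedral series of one residue across the ensemble
#'
#' Computes phi, psi, omega (using `CA(i-1), C(i-1), N(i), CA(i)`), chi1,
#' chi2, and the virtual dihedrals D1 (residues `i-1`,`i`:
#' `CB(i-1)-CA(i-1)-CA(i)-CB(i)`) and D2 (residues `i`,`i+1`), with glycine
#' contributing its HA3 proton in place of the missing CB. Angles undefined
#' for the residue (chain termini, missing atoms, no chi topology) are
#' omitted from the result rather than returned partially.
#'
#' @param mol a `"rog_molecule"`.
#' @param i residue row index into [residue_table()].
#' @param rt optional precomputed residue table.
#' @return named list of numeric vectors (degrees, one value per model).
#' @export
residue_dihedrals <- function(mol, i, rt = residue_table(mol)) {
  restype <- rt$restype[i]
  prev_ok <- .same_chain(rt, i - 1, i)
  next_ok <- .same_chain(rt, i, i + 1)
  at <- function(k, name) .res_atom_xyz(mol, rt, k, name)
  out <- list()
  if (prev_ok) {
    out$PHI <- .series_from_quad(mol, at(i - 1, "C"), at(i, "N"),
                                 at(i, "CA"), at(i, "C"))
    out$OMEGA <- .series_from_quad(mol, at(i - 1, "CA"), at(i - 1, "C"),
                                   at(i, "N"), at(i, "CA"))
    out$D1 <- .series_from_quad(mol, .cbeq(mol, rt, i - 1), at(i - 1, "CA"),
                                at(i, "CA"), .cbeq(mol, rt, i))
  }
  if (next_ok) {
    out$PSI <- .series_from_quad(mol, at(i, "N"), at(i, "CA"),
                                 at(i, "C"), at(i + 1, "N"))
    out$D2 <- .series_from_quad(mol, .cbeq(mol, rt, i), at(i, "CA"),
                                at(i + 1, "CA"), .cbeq(mol, rt, i + 1))
  }
  x4 <- CHI1_FOURTH[restype]
  if (!is.na(x4))
    out$CHI1 <- .series_from_quad(mol, at(i, "N"), at(i, "CA"),
                                  at(i, "CB"), at(i, x4))
  c2 <- CHI2_ATOMS[[restype]]
  if (!is.null(c2))
    out$CHI2 <- .series_from_quad(mol, at(i, c2[1]), at(i, c2[2]),
                                  at(i, c2[3]), at(i, c2[4]))
  Filter(Negate(is.null), out)
}

#' Dihedral series table for a whole molecule
#'
#' @param mol a `"rog_molecule"`.
#' @return data.frame with one row per defined (residue, angle) series:
#'   residue identity, `angle`, `circular_mean`, `circular_variance`, and a
#'   list-column `values` of per-model angles (degrees).
#' @export
molecule_dihedrals <- function(mol) {
  rt <- residue_table(mol)
  rows <- list()
  for (i in seq_len(nrow(rt))) {
    ds <- residue_dihedrals(mol, i, rt)
    for (ang in names(ds)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = rt$chain[i], seq = rt$seq[i], restype = rt$restype[i],
        angle = ang,
        circular_mean = circular_mean(ds[[ang]]),
        circular_variance = circular_variance(ds[[ang]]),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$values <- I(list(ds[[ang]]))
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Ensemble omega (peptide-bond) deviation of a residue
#'
#' Each model's omega is compared to the nearer of the cis and trans
#' reference values on the circle; the reported deviation is the average of
#' those per-model distances. The cis/trans call is the reference nearer to
#' the circular mean omega.
#'
#' @param omega numeric vector of per-model omega angles (degrees).
#' @param trans_ref,cis_ref reference peptide-bond angles (degrees).
#' @return list with `deviation` (degrees, >= 0) and `state`
#'   (`"cis"`/`"trans"`).
#' @export
omega_deviation <- function(omega, trans_ref = 179.7, cis_ref = 0) {
  omega <- omega[!is.na(omega)]
  if (!length(omega)) return(list(deviation = NA_real_, state = NA_character_))
  dev <- pmin(circular_distance(omega, trans_ref),
              circular_distance(omega, cis_ref))
  mu <- circular_mean(omega)
  state <- if (circular_distance(mu, cis_ref) <
               circular_distance(mu, trans_ref)) "cis" else "trans"
  list(deviation = mean(dev), state = state)
}

# ---- superposition ---------------------------------------------------------

#' Superpose an ensemble onto its mean coordinates
#'
#' Iterative procedure: all models are least-squares fitted (Kabsch) onto
#' model 1, the mean coordinates are computed, the models are re-fitted onto
#' the mean, and the loop repeats until the mean RMSD changes by less than
#' `tol` (default 1e-4 Angstrom) or `max_iter` iterations. Reported are the
#' per-model RMSDs to the mean structure, their mean and SD, and the index of
#' the model closest to the mean.
#'
#' @param mol a `"rog_molecule"`.
#' @param residues optional data.frame with `chain` and `seq` columns
#'   restricting the fitted atoms (default: every residue).
#' @param selection `"backbone"` (N, CA, C, O) or `"heavy"` (all non-H).
#' @param tol,max_iter convergence controls.
#' @return object of class `"rog_superposition"`: `rmsd_per_model`,
#'   `rmsd_mean`, `rmsd_sd`, `closest_model`, `selection`, `n_atoms`,
#'   `mean_xyz`.
#' @export
superpose <- function(mol, residues = NULL, selection = c("backbone", "heavy"),
                      tol = 1e-4, max_iter = 20) {
  selection <- match.arg(selection)
  a <- mol$atoms
  sel <- if (selection == "backbone") a$atom %in% c("N", "CA", "C", "O")
         else a$element != "H"
  if (!is.null(residues)) {
    rkey <- paste(a$chain, a$seq)
    sel <- sel & rkey %in% paste(residues$chain, residues$seq)
  }
  rows <- which(sel)
  if (length(rows) < 3) stop("fewer than 3 atoms selected for superposition")
  M <- mol$M
  # (M x 3n) xyz matrix, bio3d layout
  X <- t(vapply(seq_len(M), function(m) as.vector(t(mol$xyz[rows, , m])),
                numeric(3 * length(rows))))
  ref <- X[1, ]
  last <- Inf
  for (it in seq_len(max_iter)) {
    inds <- seq_len(3 * length(rows))
    fitted <- bio3d::fit.xyz(fixed = ref, mobile = X,
                             fixed.inds = inds, mobile.inds = inds)
    mean_xyz <- colMeans(fitted)
    rmsds <- sqrt(rowMeans((t(t(fitted) - mean_xyz))^2) * 3)
    if (abs(mean(rmsds) - last) < tol) { X <- fitted; break }
    last <- mean(rmsds); ref <- mean_xyz; X <- fitted
  }
  structure(list(rmsd_per_model = rmsds, rmsd_mean = mean(rmsds),
                 rmsd_sd = stats::sd(rmsds),
                 closest_model = which.min(rmsds),
                 selection = selection, n_atoms = length(rows),
                 mean_xyz = mean_xyz),
            class = "rog_superposition")
}

#' @export
print.rog_superposition <- function(x, ...) {
  cat(sprintf("<superposition> %s atoms (n=%d): RMSD to mean %.2f +/- %.2f A, closest model %d\n",
              x$selection, x$n_atoms, x$rmsd_mean, x$rmsd_sd, x$closest_model))
  invisible(x)
}
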