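# ROG scoring: residue criteria, hierarchy propagation (worst child wins),
# molecule-level %G/%R inequalities over the well-defined range, and the
# pluggable D1/D2 reference-density Z-score.

#' ROG scoring thresholds
#'
#' All cutoffs as named orange/red pairs, overridable individually. The
#' residue Z-metrics flag *at or below* the cutoff; omega and violation
#' metrics flag *at or above*. Note the D1D2 default (orange -1.0, red
#' -0.8) keeps the red cutoff less extreme than the orange one, mirroring
#' the manually calibrated published values; set `d1d2_strict = TRUE` to
#' swap them.
#'
#' @param ... named overrides, e.g. `omega = c(10, 15)`.
#' @param d1d2_strict swap the D1D2 orange/red cutoffs so red is the more
#'   extreme.
#' @return a named list of cutoffs, class `"rog_thresholds"`.
#' @export
rog_thresholds <- function(..., d1d2_strict = FALSE) {
  thr <- list(
    omega = c(9.4, 14.1),            # degrees, >= cutoff flags
    d1d2_z = c(-1.0, -0.8),          # Z, <= cutoff flags
    ramachandran_z = c(-1.0, -1.3),
    janin_z = c(-0.9, -1.2),
    g_factor = c(-1.0, -1.3),
    dr_max = c(0.3, 0.5),            # Angstrom
    dr_rms = c(0.15, 0.3),
    dh_max = c(3, 10),               # degrees
    dh_rms = c(3, 5),
    peak_z = c(1, 2),
    cs_z = 3,                        # |Z| above this flags a shift
    cs_flag_level = "orange",        # ROG level assigned to flagged shifts
    molecule_orange_margin = 20,     # %G <= margin + %R
    molecule_red_margin = 20,        # %G <= %R - margin
    omega_trans_ref = 179.7, omega_cis_ref = 0,
    pro_cis_delta = 8.0, pro_trans_delta = 6.0   # ppm, delta(CB)-delta(CG)
  )
  if (d1d2_strict) thr$d1d2_z <- rev(thr$d1d2_z)
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(thr)) stop("unknown threshold: ", nm)
    thr[[nm]] <- ov[[nm]]
  }
  class(thr) <- "rog_thresholds"
  thr
}

# score one low-is-bad Z metric against an orange/red cutoff pair
.score_z <- function(value, cuts) {
  if (is.na(value)) return("green")
  if (value <= cuts[2]) "red" else if (value <= cuts[1]) "orange" else "green"
}

#' Score one residue from its metric values
#'
#' Present metrics are scored independently (Z metrics flag at or below the
#' cutoffs, omega deviation at or above); absent (`NA`/missing) metrics are
#' skipped. The residue ROG is the worst over the scored criteria.
#'
#' @param metrics named list/vector with any of `omega_dev`, `d1d2_z`,
#'   `ramachandran_z`, `janin_z`, `g_factor`.
#' @param thr thresholds from [rog_thresholds()].
#' @param entity_path locator used in the emitted records.
#' @return list with `rog` and `records` (data.frame of per-criterion
#'   validation records for non-green findings).
#' @export
score_residue <- function(metrics, thr = rog_thresholds(),
                          entity_path = "residue") {
  records <- empty_records()
  levels <- "green"
  od <- metrics[["omega_dev"]]
  if (!is.null(od) && !is.na(od)) {
    lv <- if (od >= thr$omega[2]) "red" else
      if (od >= thr$omega[1]) "orange" else "green"
    levels <- c(levels, lv)
    if (lv != "green")
      records <- bind_records(records, validation_record(
        entity_path, "omega_deviation", od, lv,
        sprintf("ensemble omega deviation %.1f deg", od)))
  }
  zmap <- c(d1d2_z = "d1d2_z", ramachandran_z = "ramachandran_z",
            janin_z = "janin_z", g_factor = "g_factor")
  for (nm in names(zmap)) {
    v <- metrics[[nm]]
    if (is.null(v) || is.na(v)) next
    lv <- .score_z(v, thr[[zmap[nm]]])
    levels <- c(levels, lv)
    if (lv != "green")
      records <- bind_records(records, validation_record(
        entity_path, nm, v, lv, sprintf("%s = %.2f", nm, v)))
  }
  list(rog = rog_max(as.list(levels)), records = records)
}

#' Propagate ROG states upward
#'
#' An entity obtains the worst ROG over its children; a childless entity
#' keeps its own score (default green).
#'
#' @param children list of `"rog"` states (or level strings).
#' @param own the entity's own state.
#' @return a `"rog"` state.
#' @export
propagate_rog <- function(children, own = rog("green")) {
  rog_max(c(list(own), as.list(children)))
}

#' Molecule-level ROG from residue score percentages
#'
#' Evaluated over the well-defined residues only: with `%G` and `%R` the
#' percentages of green and red residues in the range, the molecule is red
#' iff `%G <= %R - 20`, else orange iff `%G <= 20 + %R`, else green.
#' Data-entity (restraint/shift/peak) scores are never included.
#'
#' @param pct_green,pct_red percentages in `[0, 100]`.
#' @param thr thresholds (margins configurable).
#' @return a `"rog"` state.
#' @export
score_molecule <- function(pct_green, pct_red, thr = rog_thresholds()) {
  if (pct_green <= pct_red - thr$molecule_red_margin) return(rog("red"))
  if (pct_green <= thr$molecule_orange_margin + pct_red) return(rog("orange"))
  rog("green")
}

# ---- D1/D2 reference density and Z-score -----------------------------------

#' Build a D1/D2 reference density from observations
#'
#' A 2D histogram on a regular grid over `[-180, 180)` with a half-count
#' pseudo-count per bin; log-densities plus their density-weighted mean and
#' SD are precomputed for Z-scoring.
#'
#' @param d1,d2 observed D1 and D2 angles (degrees).
#' @param bin bin width in degrees (must divide 360).
#' @return a `"d1d2_density"` object.
#' @export
d1d2_density <- function(d1, d2, bin = 10) {
  stopifnot(360 %% bin == 0)
  breaks <- seq(-180, 180, by = bin)
  ix <- findInterval(wrap_angle(d1), breaks, rightmost.closed = TRUE)
  iy <- findInterval(wrap_angle(d2), breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1
  counts <- matrix(0, nb, nb)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  dens <- (counts + 0.5) / (sum(counts) + 0.5 * nb * nb)
  logd <- log(dens)
  w <- dens / sum(dens)
  mu <- sum(w * logd)
  sdv <- sqrt(sum(w * (logd - mu)^2))
  structure(list(breaks = breaks, counts = counts, log_density = logd,
                 mean_logd = mu, sd_logd = sdv),
            class = "d1d2_density")
}

#' D1/D2 Z-score of a residue against a reference density
#'
#' For each model the log reference density at the observed (D1, D2) is
#' compared with the density-weighted mean log-density of the reference;
#' the per-model `(logdens - mean) / SD` values are averaged over the
#' ensemble.
#'
#' @param d1,d2 per-model D1 and D2 angles of the residue (degrees).
#' @param density a `"d1d2_density"`.
#' @return dimensionless Z (negative = less likely than typical), `NA` if
#'   no model has both angles.
#' @export
d1d2_zscore <- function(d1, d2, density) {
  ok <- !is.na(d1) & !is.na(d2)
  if (!any(ok)) return(NA_real_)
  ix <- findInterval(wrap_angle(d1[ok]), density$breaks,
                     rightmost.closed = TRUE)
  iy <- findInterval(wrap_angle(d2[ok]), density$breaks,
                     rightmost.closed = TRUE)
  z <- (density$log_density[cbind(ix, iy)] - density$mean_logd) /
    density$sd_logd
  mean(z)
}
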