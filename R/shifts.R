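# Chemical-shift plausibility and assignment-consistency checks, peak
# position agreement, and the three-state secondary-structure consensus.

# per-nucleus assumed shift uncertainty (ppm): 1H vs everything else
.dim_sd <- function(element) ifelse(element == "H", 0.01, 0.15)

#' Z-score of a chemical shift against reference statistics
#'
#' @param value observed shift (ppm).
#' @param restype three-letter residue type.
#' @param atom IUPAC atom (or pseudo-atom) name.
#' @param ref reference statistics table (`restype, atom, mean, sd`).
#' @return `(value - mean) / sd`, or `NA` when no reference entry exists.
#' @export
shift_zscore <- function(value, restype, atom, ref) {
  i <- which(ref$restype == restype & ref$atom == atom)
  if (!length(i) || is.na(ref$sd[i[1]]) || ref$sd[i[1]] <= 0)
    return(NA_real_)
  (value - ref$mean[i[1]]) / ref$sd[i[1]]
}

#' Validate a shift list against reference statistics and the molecule
#'
#' Emits: `cs_z` records for shifts whose |Z| exceeds the cutoff (flag
#' level configurable, default orange); red `cs_no_coordinates` records for
#' assigned atoms absent from the coordinates; green `cs_no_reference`
#' info records where the reference table has no entry. The list ROG is
#' the worst member record.
#'
#' @param shifts a `"rog_shift_list"`.
#' @param mol the molecule.
#' @param ref reference shift statistics.
#' @param thr thresholds.
#' @return list with `table` (per-shift data.frame incl. `z` and `rog`),
#'   `records`, and `rog` for the list.
#' @export
analyze_shifts <- function(shifts, mol, ref = synthetic_reference_shifts(),
                           thr = rog_thresholds()) {
  df <- shifts$shifts
  records <- empty_records()
  z <- rep(NA_real_, nrow(df))
  lev <- rep("green", nrow(df))
  for (i in seq_len(nrow(df))) {
    path <- paste(df$chain[i], df$seq[i], df$res[i], df$atom[i], sep = "/")
    res <- resolve_atom(mol, df$chain[i], df$seq[i], df$atom[i], "cyana")
    if (!res$resolved) {
      lev[i] <- "red"
      records <- bind_records(records, validation_record(
        path, "cs_no_coordinates", df$value[i], "red",
        "shift assigned to atom without coordinates"))
      next
    }
    z[i] <- shift_zscore(df$value[i], df$res[i], df$atom[i], ref)
    if (is.na(z[i])) {
      records <- bind_records(records, validation_record(
        path, "cs_no_reference", df$value[i], "green",
        "no reference statistics for this atom; shift not scored"))
      next
    }
    if (abs(z[i]) > thr$cs_z) {
      lev[i] <- thr$cs_flag_level
      records <- bind_records(records, validation_record(
        path, "cs_z", z[i], lev[i],
        sprintf("shift %.2f ppm is %.1f SD from reference", df$value[i],
                z[i])))
    }
  }
  tab <- cbind(df, z = z, rog = lev)
  list(table = tab, records = records,
       rog = rog_max(as.list(lev)))
}

#' Assignment-consistency checks on a shift list
#'
#' Orange records for: duplicate shift rows per atom reference; a stereo
#' pair where one partner and the joint pseudo-atom are both assigned with
#' conflicting values; a pseudo-atom whose value differs from the mean of
#' its assigned members by more than three per-nucleus SDs.
#'
#' @param shifts a `"rog_shift_list"`.
#' @param mol the molecule.
#' @return data.frame of validation records (possibly empty).
#' @export
check_assignments <- function(shifts, mol) {
  df <- shifts$shifts
  records <- empty_records()
  key <- paste(df$chain, df$seq, df$atom)
  for (k in unique(key[duplicated(key)]))
    records <- bind_records(records, validation_record(
      k, "cs_duplicate_assignment", NA, "orange",
      "atom has multiple shift assignments"))
  # pseudo-atom vs member consistency
  for (i in seq_len(nrow(df))) {
    members <- pseudo_members(df$res[i], df$atom[i])
    if (is.null(members)) next
    tol <- 3 * .dim_sd(element_of(members[1]))
    sel <- df$chain == df$chain[i] & df$seq == df$seq[i] & df$atom %in% members
    if (!any(sel)) next
    mvals <- df$value[sel]
    path <- paste(df$chain[i], df$seq[i], df$res[i], df$atom[i], sep = "/")
    if (abs(df$value[i] - mean(mvals)) > tol) {
      crit <- if (length(mvals) < length(members)) "cs_stereo_conflict"
              else "cs_pseudo_inconsistent"
      records <- bind_records(records, validation_record(
        path, crit, df$value[i] - mean(mvals), "orange",
        sprintf("pseudo-atom shift %.2f conflicts with member shift(s) %.2f",
                df$value[i], mean(mvals))))
    }
  }
  records
}

#' Proline peptide-bond / chemical-shift consistency
#'
#' The Cb-Cg shift difference predicts the peptide-bond state (>= the cis
#' threshold: cis; <= the trans threshold: trans; else indeterminate). An
#' orange record is returned when the prediction contradicts the geometric
#' cis/trans call from the ensemble omega angles.
#'
#' @param cb,cg proline CB and CG shifts (ppm); either may be `NA`.
#' @param omega_state geometric call, `"cis"` or `"trans"` (see
#'   [omega_deviation()]).
#' @param thr thresholds (`pro_cis_delta`, `pro_trans_delta`).
#' @param entity_path locator for the record.
#' @return a one-row record data.frame, or `NULL` when consistent or
#'   indeterminate.
#' @export
proline_consistency <- function(cb, cg, omega_state, thr = rog_thresholds(),
                                entity_path = "residue") {
  if (is.na(cb) || is.na(cg) || is.na(omega_state)) return(NULL)
  delta <- cb - cg
  predicted <- if (delta >= thr$pro_cis_delta) "cis"
               else if (delta <= thr$pro_trans_delta) "trans"
               else return(NULL)
  if (predicted == omega_state) return(NULL)
  validation_record(entity_path, "pro_omega_inconsistency", delta, "orange",
                    sprintf("CB-CG shift difference %.1f ppm predicts %s but geometry is %s",
                            delta, predicted, omega_state))
}

#' Leucine side-chain rotamer / methyl-shift consistency
#'
#' The sign of the Cd1-Cd2 shift difference predicts the chi2 rotamer
#' (positive: trans, negative: gauche+); an orange record is returned when
#' the prediction contradicts the ensemble-consensus chi2 rotamer. Chi2
#' circular means within 60 degrees of 180 are called trans, within 60
#' degrees of +60 gauche+; anything else is indeterminate.
#'
#' @param cd1,cd2 Leu CD1/CD2 shifts (ppm).
#' @param chi2 per-model chi2 angles (degrees).
#' @param entity_path locator for the record.
#' @return a one-row record data.frame, or `NULL`.
#' @export
leucine_consistency <- function(cd1, cd2, chi2, entity_path = "residue") {
  if (is.na(cd1) || is.na(cd2) || all(is.na(chi2))) return(NULL)
  mu <- circular_mean(chi2)
  geo <- if (circular_distance(mu, 180) <= 60) "trans"
         else if (circular_distance(mu, 60) <= 60) "gauche+"
         else return(NULL)
  predicted <- if (cd1 - cd2 > 0) "trans" else "gauche+"
  if (predicted == geo) return(NULL)
  validation_record(entity_path, "leu_sidechain_inconsistency", cd1 - cd2,
                    "orange",
                    sprintf("CD1-CD2 shift difference %.1f ppm predicts %s but chi2 consensus is %s",
                            cd1 - cd2, predicted, geo))
}

#' Peak position vs assigned shift consistency
#'
#' Each peak dimension with an assignment is compared against the assigned
#' atom's shift; `Z = |position - shift| / sd` with the per-nucleus assumed
#' SD (0.01 ppm for 1H, 0.15 ppm otherwise). Z at or above 1 is orange, at
#' or above 2 red; an unassigned dimension is orange.
#'
#' @param peak list with `positions` (ppm) and `assignments` (atom locator
#'   strings `"chain.seq.atom"` or `NA`).
#' @param shifts a `"rog_shift_list"`.
#' @param thr thresholds.
#' @param entity_path locator for records.
#' @return list with per-dimension `z`, `records` and the peak `rog`.
#' @export
peak_position_check <- function(peak, shifts, thr = rog_thresholds(),
                                entity_path = "peak") {
  stopifnot(length(peak$positions) == length(peak$assignments))
  df <- shifts$shifts
  z <- rep(NA_real_, length(peak$positions))
  records <- empty_records()
  lev <- "green"
  for (d in seq_along(peak$positions)) {
    asg <- peak$assignments[d]
    if (is.na(asg) || !nzchar(asg)) {
      lev <- as.character(rog_max("orange", lev))
      records <- bind_records(records, validation_record(
        entity_path, "peak_unassigned", NA, "orange",
        sprintf("dimension %d is unassigned", d)))
      next
    }
    parts <- strsplit(asg, ".", fixed = TRUE)[[1]]
    i <- which(df$chain == parts[1] & df$seq == as.integer(parts[2]) &
                 df$atom == parts[3])
    if (!length(i)) next
    sdv <- .dim_sd(element_of(parts[3]))
    z[d] <- abs(peak$positions[d] - df$value[i[1]]) / sdv
    dl <- if (z[d] >= thr$peak_z[2]) "red"
          else if (z[d] >= thr$peak_z[1]) "orange" else "green"
    if (dl != "green")
      records <- bind_records(records, validation_record(
        entity_path, "peak_z", z[d], dl,
        sprintf("dimension %d position is %.1f SD from assigned shift", d,
                z[d])))
    lev <- as.character(rog_max(dl, lev))
  }
  list(z = z, records = records, rog = rog(lev))
}

#' Three-state consensus secondary structure over an ensemble
#'
#' Per-model DSSP-style code strings are collapsed to helix (codes G, H,
#' optionally I), sheet (B, E) or other, and each residue takes the state
#' with the largest fraction over the models; ties resolve to other.
#'
#' @param ss_per_model character vector of equal-length code strings.
#' @param include_pi also map I (pi helix) to helix (default off).
#' @return single string of `H`/`E`/`C` consensus codes.
#' @export
consensus_secondary_structure <- function(ss_per_model, include_pi = FALSE) {
  stopifnot(length(unique(nchar(ss_per_model))) == 1)
  helix <- c("G", "H", if (include_pi) "I")
  n <- nchar(ss_per_model[1])
  codes <- vapply(seq_len(n), function(p) {
    st <- substring(ss_per_model, p, p)
    coll <- ifelse(st %in% helix, "H", ifelse(st %in% c("B", "E"), "E", "C"))
    counts <- c(H = sum(coll == "H"), E = sum(coll == "E"),
                C = sum(coll == "C"))
    best <- counts == max(counts)
    if (sum(best) > 1) "C" else names(counts)[best]
  }, "")
  paste(codes, collapse = "")
}
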