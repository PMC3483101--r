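# End-to-end validation of a project: per-residue criteria, restraint and
# shift analytics, interactions, range selection, superposition, and ROG
# aggregation up to the molecule level.

#' Validate a project
#'
#' Runs the full residue-based validation pipeline and aggregates ROG
#' states. Residue criteria (omega deviation, D1/D2 Z, and the external
#' Ramachandran/Janin/G-factor metrics when supplied) cascade to chain and
#' molecule level; experimental-data criticism (restraints, shifts, peaks)
#' is scored and reported but deliberately never included in the molecule
#' score.
#'
#' @param project a `"rog_project"`.
#' @param thr thresholds from [rog_thresholds()].
#' @param range `"auto"` (circular-variance selection), `"all"`, or a range
#'   spec string like `"A:9-60"`.
#' @param d1d2_ref optional `"d1d2_density"` reference for D1/D2 Z-scoring.
#' @param ref_shifts reference shift statistics table (default the
#'   synthetic built-in).
#' @param completeness_cutoff NOE completeness distance cutoff (Angstrom).
#' @return an object of class `"rog_validation"`.
#' @export
validate_project <- function(project, thr = rog_thresholds(), range = "auto",
                             d1d2_ref = NULL,
                             ref_shifts = synthetic_reference_shifts(),
                             completeness_cutoff = 4.0) {
  mol <- project$molecule
  rt <- residue_table(mol)
  dihedrals <- molecule_dihedrals(mol)
  records <- empty_records()

  rng <- if (identical(range, "auto"))
    select_range(mol, dihedrals = dihedrals)
  else if (identical(range, "all")) select_range(mol, method = "all")
  else select_range(mol, method = "user", user_spec = range)
  in_range <- paste(rt$chain, rt$seq) %in%
    paste(rng$included$chain, rng$included$seq)

  # ---- per-residue metrics and scores
  getser <- function(i, ang) {
    d <- dihedrals[dihedrals$chain == rt$chain[i] &
                     dihedrals$seq == rt$seq[i] & dihedrals$angle == ang, ]
    if (nrow(d)) d$values[[1]] else NULL
  }
  em <- project$external_metrics
  res_rows <- list()
  for (i in seq_len(nrow(rt))) {
    path <- residue_path(rt$chain[i], rt$seq[i], rt$restype[i])
    metrics <- list()
    omega_state <- NA_character_
    om <- getser(i, "OMEGA")
    if (!is.null(om) && rt$restype[i] %in% AMINO_ACIDS) {
      od <- omega_deviation(om, trans_ref = thr$omega_trans_ref,
                            cis_ref = thr$omega_cis_ref)
      metrics$omega_dev <- od$deviation
      omega_state <- od$state
    }
    if (!is.null(d1d2_ref)) {
      d1 <- getser(i, "D1"); d2 <- getser(i, "D2")
      if (!is.null(d1) && !is.null(d2))
        metrics$d1d2_z <- d1d2_zscore(d1, d2, d1d2_ref)
    }
    if (!is.null(em)) {
      r <- em[em$chain == rt$chain[i] & em$seq == rt$seq[i], , drop = FALSE]
      if (nrow(r)) {
        for (mcol in intersect(c("ramachandran_z", "janin_z", "g_factor"),
                               names(r)))
          metrics[[mcol]] <- r[[mcol]][1]
        if (is.null(metrics$d1d2_z) && !is.null(r$d1d2_z))
          metrics$d1d2_z <- r$d1d2_z[1]
      }
    }
    sc <- if (length(metrics) && rt$restype[i] %in% AMINO_ACIDS)
      score_residue(metrics, thr, path)
    else list(rog = rog("green"), records = empty_records())
    records <- bind_records(records, sc$records)
    row <- data.frame(chain = rt$chain[i], seq = rt$seq[i],
                      restype = rt$restype[i], in_range = in_range[i],
                      omega_dev = metrics$omega_dev %||% NA_real_,
                      omega_state = omega_state,
                      d1d2_z = metrics$d1d2_z %||% NA_real_,
                      ramachandran_z = metrics$ramachandran_z %||% NA_real_,
                      janin_z = metrics$janin_z %||% NA_real_,
                      g_factor = metrics$g_factor %||% NA_real_,
                      rog = as.character(sc$rog), stringsAsFactors = FALSE)
    res_rows[[i]] <- row
  }
  residues <- do.call(rbind, res_rows)

  # ---- chain and molecule aggregation (residue critiques only)
  chains <- do.call(rbind, lapply(split(residues, residues$chain),
                                  function(d) data.frame(
    chain = d$chain[1],
    rog = as.character(propagate_rog(as.list(d$rog))),
    stringsAsFactors = FALSE)))
  rownames(chains) <- NULL
  rr <- residues[residues$in_range & residues$restype %in% AMINO_ACIDS, ]
  pct <- function(lv) if (nrow(rr)) 100 * mean(rr$rog == lv) else 0
  pct_green <- pct("green"); pct_orange <- pct("orange"); pct_red <- pct("red")
  molecule_rog <- score_molecule(pct_green, pct_red, thr)

  # ---- superposition over the selected range
  sup <- tryCatch(superpose(mol, residues = rng$included,
                            selection = "backbone"),
                  error = function(e) NULL)

  # ---- restraints
  dr_lists <- lapply(project$distance_restraints, analyze_restraint_list,
                     mol = mol, thr = thr)
  dh_lists <- lapply(project$dihedral_restraints, analyze_restraint_list,
                     mol = mol, thr = thr)
  for (rl in c(dr_lists, dh_lists)) {
    kind <- if (rl$kind == "distance") "dr" else "dh"
    for (i in seq_along(rl$restraints)) {
      r <- rl$restraints[[i]]
      if (length(r$unresolved)) {
        records <- bind_records(records, validation_record(
          paste0(rl$name, "#", i), paste0(kind, "_unresolved"), NA, "red",
          paste("unresolved atom reference(s):",
                paste(r$unresolved, collapse = ", "))))
      } else if (as.character(rl$stats[[i]]$rog) != "green") {
        records <- bind_records(records, validation_record(
          paste0(rl$name, "#", i), paste0(kind, "_max_violation"),
          rl$stats[[i]]$max, as.character(rl$stats[[i]]$rog),
          sprintf("max violation %.2f, RMS %.2f", rl$stats[[i]]$max,
                  rl$stats[[i]]$rms)))
      }
    }
  }

  # ---- NOE completeness
  compl <- if (length(dr_lists) && any(mol$atoms$element == "H"))
    tryCatch(completeness(mol, dr_lists, cutoff = completeness_cutoff),
             error = function(e) NULL)
  else NULL

  # ---- shifts, assignment consistency, residue-type specific checks
  shift_analysis <- NULL
  if (!is.null(project$shifts)) {
    shift_analysis <- analyze_shifts(project$shifts, mol, ref_shifts, thr)
    records <- bind_records(records, shift_analysis$records,
                            check_assignments(project$shifts, mol))
    sdf <- project$shifts$shifts
    shift_of <- function(i, atom) {
      j <- which(sdf$chain == rt$chain[i] & sdf$seq == rt$seq[i] &
                   sdf$atom == atom)
      if (length(j)) sdf$value[j[1]] else NA_real_
    }
    for (i in seq_len(nrow(rt))) {
      path <- residue_path(rt$chain[i], rt$seq[i], rt$restype[i])
      if (rt$restype[i] == "PRO") {
        records <- bind_records(records, proline_consistency(
          shift_of(i, "CB"), shift_of(i, "CG"), residues$omega_state[i],
          thr, path))
      }
      if (rt$restype[i] == "LEU") {
        chi2 <- getser(i, "CHI2")
        if (!is.null(chi2))
          records <- bind_records(records, leucine_consistency(
            shift_of(i, "CD1"), shift_of(i, "CD2"), chi2, path))
      }
    }
  }

  # ---- peaks
  peak_results <- lapply(seq_along(project$peaks), function(k) {
    if (is.null(project$shifts)) return(NULL)
    pk <- peak_position_check(project$peaks[[k]], project$shifts, thr,
                              entity_path = paste0("peak#", k))
    records <<- bind_records(records, pk$records)
    pk
  })

  # ---- interactions
  sb <- detect_salt_bridges(mol)
  records <- bind_records(records, sb$records)
  ds <- detect_disulfides(mol)

  # ---- secondary structure consensus
  ss_consensus <- if (!is.null(project$ss))
    consensus_secondary_structure(project$ss) else NULL

  structure(list(
    name = project$name, molecule = mol, residues = residues,
    chains = chains, molecule_rog = molecule_rog,
    pct_green = pct_green, pct_orange = pct_orange, pct_red = pct_red,
    range = rng, superposition = sup,
    distance_restraints = dr_lists, dihedral_restraints = dh_lists,
    completeness = compl, shift_analysis = shift_analysis,
    peak_results = peak_results,
    salt_bridges = sb$summaries, disulfides = ds,
    ss_consensus = ss_consensus,
    records = records, thresholds = thr), class = "rog_validation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rog_validation <- function(x, ...) {
  cat(sprintf("<validation '%s'> molecule ROG %s (%%G %.0f / %%O %.0f / %%R %.0f over %d range residues)\n",
              x$name, as.character(x$molecule_rog), x$pct_green,
              x$pct_orange, x$pct_red, nrow(x$range$included)))
  if (!is.null(x$superposition)) print(x$superposition)
  if (!is.null(x$completeness)) print(x$completeness)
  cat(sprintf("%d validation record(s)\n", nrow(x$records)))
  invisible(x)
}
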