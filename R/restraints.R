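# Restraint analytics: r^-6 effective distances, per-ensemble violation
# statistics with ROG scoring, sequence-range classes, duplicate detection,
# and a simplified inter-residue NOE completeness to 4 A.

#' Effective distance of a (possibly ambiguous) distance restraint
#'
#' A single atom pair gives the Euclidean distance; multiple pairs (from
#' pseudo-atom groups or ambiguous contributions) are combined as
#' `(sum over pairs d^-6)^(-1/6)`, the standard NOE ensemble-averaging form
#' (`method = "center"` instead averages group centroid positions).
#'
#' @param restraint a `"rog_distance_restraint"`.
#' @param mol the molecule.
#' @param model model index.
#' @param method `"r6"` (default) or `"center"`.
#' @return distance in Angstrom, or `NA` when any referenced atom is
#'   unresolved.
#' @export
effective_distance <- function(restraint, mol, model, method = c("r6", "center")) {
  method <- match.arg(method)
  if (length(restraint$unresolved)) return(NA_real_)
  acc <- 0; n <- 0
  for (ct in restraint$contributions) {
    if (method == "center") {
      pa <- colMeans(mol$xyz[ct$a, , model, drop = FALSE][, , 1, drop = FALSE])
      pb <- colMeans(mol$xyz[ct$b, , model, drop = FALSE][, , 1, drop = FALSE])
      acc <- acc + sqrt(sum((pa - pb)^2))^(-6); n <- n + 1
    } else {
      for (i in ct$a) for (j in ct$b) {
        d2 <- sum((mol$xyz[i, , model] - mol$xyz[j, , model])^2)
        acc <- acc + d2^(-3)
      }
    }
  }
  acc^(-1 / 6)
}

# signed excess of angle theta outside the circular interval [lower, upper]
# (interval runs counterclockwise from lower to upper; wrap-around allowed)
.circular_excess <- function(theta, lower, upper) {
  span <- (upper - lower) %% 360
  pos <- (theta - lower) %% 360
  if (pos <= span) return(0)
  min(circular_distance(theta, lower), circular_distance(theta, upper))
}

#' Ensemble violation statistics of one restraint
#'
#' For distance restraints the per-model violation is
#' `max(0, d - upper, lower - d)` on the effective distance; for dihedral
#' restraints it is the circular excess outside the bound interval. ROG
#' scoring follows the standard cutoffs: distance max 0.3/0.5 A and RMS
#' 0.15/0.3 A (orange/red), dihedral max 3/10 deg and RMS 3/5 deg; a
#' restraint with unresolved atoms is red with undefined statistics.
#'
#' @param restraint a distance or dihedral restraint.
#' @param mol the molecule.
#' @param thresholds violation count thresholds (defaults 0.1/0.3/0.5 A for
#'   distances, 1/3/5 deg for dihedrals).
#' @param thr ROG threshold set (see [rog_thresholds()]).
#' @return an `"rog_violation_stats"` object: `per_model`, `max`, `rms`,
#'   `count_above` (named by threshold), `rog`.
#' @export
violation_stats <- function(restraint, mol, thresholds = NULL,
                            thr = rog_thresholds()) {
  is_dist <- inherits(restraint, "rog_distance_restraint")
  if (is.null(thresholds))
    thresholds <- if (is_dist) c(0.1, 0.3, 0.5) else c(1, 3, 5)
  if (length(restraint$unresolved)) {
    res <- list(per_model = rep(NA_real_, mol$M), max = NA_real_,
                rms = NA_real_,
                count_above = stats::setNames(rep(NA_integer_,
                                                  length(thresholds)),
                                              thresholds),
                rog = rog("red"))
    return(structure(res, class = "rog_violation_stats"))
  }
  viol <- vapply(seq_len(mol$M), function(m) {
    if (is_dist) {
      d <- effective_distance(restraint, mol, m)
      max(0, d - restraint$upper, restraint$lower - d)
    } else {
      p <- lapply(restraint$atoms, function(i) mol$xyz[i, , m])
      theta <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
      if (is.na(theta)) return(NA_real_)
      .circular_excess(theta, restraint$lower, restraint$upper)
    }
  }, numeric(1))
  vmax <- max(viol, na.rm = TRUE)
  vrms <- sqrt(mean(viol^2, na.rm = TRUE))
  counts <- vapply(thresholds, function(t) sum(viol >= t, na.rm = TRUE),
                   integer(1))
  cut <- if (is_dist) list(max = thr$dr_max, rms = thr$dr_rms)
         else list(max = thr$dh_max, rms = thr$dh_rms)
  level <- "green"
  if (vmax >= cut$max[1] || vrms >= cut$rms[1]) level <- "orange"
  if (vmax >= cut$max[2] || vrms >= cut$rms[2]) level <- "red"
  structure(list(per_model = viol, max = vmax, rms = vrms,
                 count_above = stats::setNames(counts, thresholds),
                 rog = rog(level)),
            class = "rog_violation_stats")
}

#' Sequence-range class of a distance restraint
#'
#' Sequence separation `s` on the single contributing residue pair:
#' 0 intra-residual, 1 sequential, 2-4 medium-range, >= 5 long-range.
#' Restraints whose contributions span more than one distinct residue pair,
#' or cross chains, are ambiguous.
#'
#' @param restraint a `"rog_distance_restraint"`.
#' @return one of `"intra_residual"`, `"sequential"`, `"medium_range"`,
#'   `"long_range"`, `"ambiguous"`.
#' @export
classify_restraint <- function(restraint) {
  pairs <- unique(vapply(restraint$contributions, function(ct) {
    p <- sort(c(paste(ct$a_res, collapse = ":"),
                paste(ct$b_res, collapse = ":")))
    paste(p, collapse = "|")
  }, ""))
  if (length(pairs) > 1) return("ambiguous")
  ct <- restraint$contributions[[1]]
  if (ct$a_res[1] != ct$b_res[1]) return("ambiguous")   # inter-chain
  s <- abs(as.integer(ct$a_res[2]) - as.integer(ct$b_res[2]))
  if (s == 0) "intra_residual"
  else if (s == 1) "sequential"
  else if (s <= 4) "medium_range"
  else "long_range"
}

# canonical signature of a restraint's contribution set: unordered set of
# unordered atom-group pairs, identified by atom reference, bounds ignored
.restraint_signature <- function(restraint) {
  sig <- vapply(restraint$contributions, function(ct) {
    ga <- paste(sort(c(paste(ct$a_res, collapse = ":"), ct$a_name)),
                collapse = "~")
    gb <- paste(sort(c(paste(ct$b_res, collapse = ":"), ct$b_name)),
                collapse = "~")
    paste(sort(c(ga, gb)), collapse = "|")
  }, "")
  paste(sort(unique(sig)), collapse = ";")
}

#' Find duplicate restraints in a list
#'
#' Two restraints are duplicates iff their contribution sets are equal as
#' unordered sets of unordered atom-group pairs, regardless of bounds. In
#' each duplicate group the member with the most restrictive upper bound is
#' marked as retained.
#'
#' @param rlist a `"rog_restraint_list"` of kind `"distance"`.
#' @return list of duplicate groups, each `list(members = indices,
#'   retained = index)`; `attr(, "n_duplicates")` counts the redundant
#'   restraints (group size minus one, summed).
#' @export
find_duplicates <- function(rlist) {
  sigs <- vapply(rlist$restraints, .restraint_signature, "")
  groups <- split(seq_along(sigs), sigs)
  groups <- groups[lengths(groups) > 1]
  out <- lapply(unname(groups), function(ix) {
    uppers <- vapply(rlist$restraints[ix], function(r) r$upper, numeric(1))
    list(members = ix, retained = ix[which.min(uppers)])
  })
  attr(out, "n_duplicates") <- sum(vapply(out, function(g)
    length(g$members) - 1L, 1L))
  out
}

# observable protons: C/N-bound, with magnetically equivalent groups
# (methyls, fast-flipping aromatic pairs) collapsed to one representative.
# returns data.frame: atom row of representative, residue identity, members
.observable_protons <- function(mol) {
  a <- mol$atoms
  rows <- list()
  rt <- residue_table(mol)
  for (i in seq_len(nrow(rt))) {
    if (!rt$restype[i] %in% AMINO_ACIDS) next
    rres <- residue_atom_rows(mol, rt$chain[i], rt$seq[i], rt$ins[i])
    pt <- PROTON_TABLE[PROTON_TABLE$restype == rt$restype[i], ]
    pt <- pt[substring(pt$parent, 1, 1) %in% c("C", "N"), ]
    present <- pt$atom[pt$atom %in% a$atom[rres]]
    if (!length(present)) next
    eq <- EQUIVALENT_GROUPS[[rt$restype[i]]]
    grouped <- character()
    if (!is.null(eq)) for (g in eq) {
      gm <- intersect(g, present)
      if (length(gm)) {
        rows[[length(rows) + 1L]] <- list(
          chain = rt$chain[i], seq = rt$seq[i], rep = gm[1], members = gm)
        grouped <- c(grouped, gm)
      }
    }
    for (atm in setdiff(present, grouped))
      rows[[length(rows) + 1L]] <- list(chain = rt$chain[i], seq = rt$seq[i],
                                        rep = atm, members = atm)
  }
  rows
}

#' Simplified inter-residue NOE completeness
#'
#' Observables are the carbon/nitrogen-bound protons, with methyl and
#' equivalent aromatic protons collapsed to a single observable. A pair of
#' observables from different residues is *expected* when its r^-6 effective
#' distance is at most `cutoff` in at least half of the models; it is
#' *observed* when any non-hydrogen-bond distance restraint links the two
#' groups; *matched* when both. Overall completeness is
#' `100 * matched / expected`.
#'
#' @param mol a protonated molecule.
#' @param distance_lists list of `"rog_restraint_list"` objects.
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @return an `"rog_completeness"` object: `per_residue` data.frame
#'   (`observable_atoms`, `expected`, `observed`, `matched`) and
#'   `overall_completeness` (percent).
#' @export
completeness <- function(mol, distance_lists, cutoff = 4.0) {
  obs <- .observable_protons(mol)
  if (!length(obs))
    stop("no observable protons in coordinates; provide a protonated input")
  n <- length(obs)
  okey <- vapply(obs, function(o) paste(o$chain, o$seq, o$rep), "")
  # map every member proton atom row -> observable index
  member_map <- integer(nrow(mol$atoms))
  for (k in seq_len(n)) {
    for (m in obs[[k]]$members) {
      j <- mol$lookup[atom_key(obs[[k]]$chain, obs[[k]]$seq, m)]
      if (!is.na(j)) member_map[j] <- k
    }
  }
  # expected pairs: effective distance <= cutoff in >= half the models
  half <- mol$M / 2
  expected <- matrix(FALSE, n, n)
  xyz <- mol$xyz
  midx <- lapply(obs, function(o) {
    vapply(o$members, function(m)
      mol$lookup[atom_key(o$chain, o$seq, m)], 1L)
  })
  res_of <- vapply(obs, function(o) paste(o$chain, o$seq), "")
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (res_of[i] == res_of[j]) next
    cnt <- 0
    for (m in seq_len(mol$M)) {
      s <- 0
      for (p in midx[[i]]) for (q in midx[[j]])
        s <- s + sum((xyz[p, , m] - xyz[q, , m])^2)^(-3)
      if (s^(-1 / 6) <= cutoff) cnt <- cnt + 1
    }
    if (cnt >= half) expected[i, j] <- TRUE
  }
  # observed pairs from restraints
  observed <- matrix(FALSE, n, n)
  for (rl in distance_lists) for (r in rl$restraints) {
    if (isTRUE(r$hbond) || length(r$unresolved)) next
    for (ct in r$contributions) {
      oa <- unique(member_map[ct$a]); ob <- unique(member_map[ct$b])
      for (i in oa[oa > 0]) for (j in ob[ob > 0]) {
        if (res_of[i] == res_of[j]) next
        lo <- min(i, j); hi <- max(i, j)
        observed[lo, hi] <- TRUE
      }
    }
  }
  matched <- expected & observed
  per_res_key <- unique(res_of)
  per_residue <- do.call(rbind, lapply(per_res_key, function(rk) {
    ix <- which(res_of == rk)
    inv <- function(mm) sum(mm[ix, , drop = FALSE]) + sum(mm[, ix, drop = FALSE])
    data.frame(residue = rk, observable_atoms = length(ix),
               expected = inv(expected), observed = inv(observed),
               matched = inv(matched), stringsAsFactors = FALSE)
  }))
  overall <- if (sum(expected)) 100 * sum(matched) / sum(expected) else NA_real_
  structure(list(per_residue = per_residue,
                 n_expected = sum(expected), n_observed = sum(observed),
                 n_matched = sum(matched),
                 overall_completeness = overall),
            class = "rog_completeness")
}

#' @export
print.rog_completeness <- function(x, ...) {
  cat(sprintf("<NOE completeness> expected %d, observed %d, matched %d -> %.1f%%\n",
              x$n_expected, x$n_observed, x$n_matched,
              x$overall_completeness))
  invisible(x)
}

#' Analyse every restraint of a list
#'
#' Runs [violation_stats()] (and for distance lists [classify_restraint()]
#' and [find_duplicates()]) over a restraint list, attaches per-restraint
#' ROG states, and propagates the worst state to the list.
#'
#' @param rlist a `"rog_restraint_list"`.
#' @param mol the molecule.
#' @param thr ROG thresholds.
#' @return the list with `stats` (per-restraint violation stats), `classes`,
#'   `duplicates`, `table` (flat per-restraint data.frame) and updated
#'   `rog`.
#' @export
analyze_restraint_list <- function(rlist, mol, thr = rog_thresholds()) {
  stats_ <- lapply(rlist$restraints, violation_stats, mol = mol, thr = thr)
  for (i in seq_along(rlist$restraints))
    rlist$restraints[[i]]$rog <- stats_[[i]]$rog
  rlist$stats <- stats_
  if (rlist$kind == "distance") {
    rlist$classes <- vapply(rlist$restraints, classify_restraint, "")
    rlist$duplicates <- find_duplicates(rlist)
  }
  id <- seq_along(rlist$restraints)
  tab <- data.frame(
    id = id,
    class = if (rlist$kind == "distance") rlist$classes else
      vapply(rlist$restraints, function(r) r$angle_name, ""),
    max_violation = vapply(stats_, function(s) s$max, numeric(1)),
    rms_violation = vapply(stats_, function(s) s$rms, numeric(1)),
    rog = vapply(stats_, function(s) as.character(s$rog), ""),
    stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(stats_, function(s)
    as.integer(s$count_above)))
  colnames(counts) <- paste0("n_above_", names(stats_[[1]]$count_above))
  rlist$table <- cbind(tab, counts)
  rlist$rog <- rog_max(lapply(stats_, function(s) s$rog))
  rlist
}
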