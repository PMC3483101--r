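# Per-model detection and ensemble summarisation of salt bridges and
# disulfide bonds from coordinates.

.SB_BASIC <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ")
.SB_ACIDIC <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))

.group_rows <- function(mol, chain, seq, names_) {
  idx <- vapply(names_, function(nm)
    mol$lookup[atom_key(chain, seq, nm)], 1L)
  idx[!is.na(idx)]
}

#' Detect salt bridges across an ensemble
#'
#' Every Arg/Lys against every Glu/Asp residue pair is classified per
#' model: *salt bridge* when the charged-group centroids are within
#' `dist_cut` AND at least one side-chain N-O atom pair is within
#' `dist_cut`; *ionic interaction* when exactly one of the two conditions
#' holds; none otherwise. Pairs missing their charged-group atoms are
#' skipped with an info record.
#'
#' @param mol a `"rog_molecule"`.
#' @param dist_cut distance criterion in Angstrom (default 4.0).
#' @param min_positive only report pairs classified salt bridge or ionic in
#'   at least this many models (default 1; set 0 to report all pairs).
#' @return list with `summaries` (data.frame: pair identity,
#'   `n_salt_bridge`, `n_ionic`, `n_none`, `M`) and `records`.
#' @export
detect_salt_bridges <- function(mol, dist_cut = 4.0, min_positive = 1) {
  rt <- residue_table(mol)
  basic <- which(rt$restype %in% names(.SB_BASIC))
  acidic <- which(rt$restype %in% names(.SB_ACIDIC))
  records <- empty_records()
  rows <- list()
  for (i in basic) for (j in acidic) {
    bn <- .group_rows(mol, rt$chain[i], rt$seq[i],
                      .SB_BASIC[[rt$restype[i]]])
    ao <- .group_rows(mol, rt$chain[j], rt$seq[j],
                      .SB_ACIDIC[[rt$restype[j]]])
    pair_path <- paste(residue_path(rt$chain[i], rt$seq[i], rt$restype[i]),
                       residue_path(rt$chain[j], rt$seq[j], rt$restype[j]),
                       sep = "--")
    if (length(bn) < length(.SB_BASIC[[rt$restype[i]]]) ||
        length(ao) < length(.SB_ACIDIC[[rt$restype[j]]])) {
      records <- bind_records(records, validation_record(
        pair_path, "skipped_pair", NA, "green",
        "side-chain charged-group atoms missing; pair not classified"))
      next
    }
    n_sb <- 0L; n_ion <- 0L
    for (m in seq_len(mol$M)) {
      cb <- colMeans(matrix(mol$xyz[bn, , m], ncol = 3))
      ca <- colMeans(matrix(mol$xyz[ao, , m], ncol = 3))
      centroid_ok <- sqrt(sum((cb - ca)^2)) <= dist_cut
      dmin <- min(vapply(bn, function(p) min(vapply(ao, function(q)
        sqrt(sum((mol$xyz[p, , m] - mol$xyz[q, , m])^2)), 1)), numeric(1)))
      pair_ok <- dmin <= dist_cut
      if (centroid_ok && pair_ok) n_sb <- n_sb + 1L
      else if (centroid_ok || pair_ok) n_ion <- n_ion + 1L
    }
    if (n_sb + n_ion >= max(min_positive, 0L) || min_positive == 0)
      rows[[length(rows) + 1L]] <- data.frame(
        chain_a = rt$chain[i], seq_a = rt$seq[i], res_a = rt$restype[i],
        chain_b = rt$chain[j], seq_b = rt$seq[j], res_b = rt$restype[j],
        n_salt_bridge = n_sb, n_ionic = n_ion,
        n_none = mol$M - n_sb - n_ion, M = mol$M, stringsAsFactors = FALSE)
  }
  list(summaries = if (length(rows)) do.call(rbind, rows) else NULL,
       records = records)
}

#' Detect disulfide bonds across an ensemble
#'
#' For every cysteine pair, per model: *bonded* when the Sg-Sg distance is
#' at most `sg_cut` (default 2.5 A); otherwise *potential* when the Cb-Cb
#' distance is at most `cb_cut` (default 4.5 A) and, when both Sg atoms are
#' present, the Cb-Sg-Sg'-Cb' dihedral magnitude lies within 90 +/- 30
#' degrees (pairs lacking Sg are judged on the Cb distance alone).
#'
#' @param mol a `"rog_molecule"`.
#' @param sg_cut,cb_cut distance cutoffs (Angstrom).
#' @param chi_window dihedral magnitude window around 90 degrees.
#' @param min_positive only report pairs positive in at least this many
#'   models (0 reports all).
#' @return data.frame: pair identity, `n_bonded`, `n_potential`, `n_none`,
#'   `M`; `NULL` when there are no reportable pairs.
#' @export
detect_disulfides <- function(mol, sg_cut = 2.5, cb_cut = 4.5,
                              chi_window = 30, min_positive = 1) {
  rt <- residue_table(mol)
  cys <- which(rt$restype == "CYS")
  if (length(cys) < 2) return(NULL)
  rows <- list()
  pairs <- utils::combn(cys, 2)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    at <- function(r, nm) mol$lookup[atom_key(rt$chain[r], rt$seq[r], nm)]
    sgi <- at(i, "SG"); sgj <- at(j, "SG")
    cbi <- at(i, "CB"); cbj <- at(j, "CB")
    if (is.na(cbi) || is.na(cbj)) next
    n_bond <- 0L; n_pot <- 0L
    for (m in seq_len(mol$M)) {
      have_sg <- !is.na(sgi) && !is.na(sgj)
      if (have_sg &&
          sqrt(sum((mol$xyz[sgi, , m] - mol$xyz[sgj, , m])^2)) <= sg_cut) {
        n_bond <- n_bond + 1L
        next
      }
      cb_ok <- sqrt(sum((mol$xyz[cbi, , m] - mol$xyz[cbj, , m])^2)) <= cb_cut
      if (!cb_ok) next
      if (have_sg) {
        chi <- dihedral_angle(mol$xyz[cbi, , m], mol$xyz[sgi, , m],
                              mol$xyz[sgj, , m], mol$xyz[cbj, , m])
        if (!is.na(chi) && abs(abs(chi) - 90) <= chi_window)
          n_pot <- n_pot + 1L
      } else {
        n_pot <- n_pot + 1L
      }
    }
    if (n_bond + n_pot >= max(min_positive, 0L) || min_positive == 0)
      rows[[length(rows) + 1L]] <- data.frame(
        chain_a = rt$chain[i], seq_a = rt$seq[i],
        chain_b = rt$chain[j], seq_b = rt$seq[j],
        n_bonded = n_bond, n_potential = n_pot,
        n_none = mol$M - n_bond - n_pot, M = mol$M,
        stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}
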