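# Well-defined residue range selection by phi/psi circular variance, used
# for superposition and molecule-level scoring.

.runs <- function(idx) {
  # contiguous runs in a sorted integer vector -> data.frame(first, last)
  if (!length(idx)) return(data.frame(first = integer(), last = integer()))
  brk <- c(0, which(diff(idx) != 1), length(idx))
  data.frame(first = idx[brk[-length(brk)] + 1], last = idx[brk[-1]])
}

#' Select the well-defined residue range of an ensemble
#'
#' Per chain, in order: (1) with a single model, or when the molecule
#' contains no amino acids, the full sequence is used; (2) residues whose
#' phi/psi circular variance is at most `cv_cut` are included (the residue
#' cv is the worse of cv(phi) and cv(psi); at termini the available one is
#' used); (3) excluded gaps of at most `gap_fill` residues flanked on both
#' sides by included residues are re-introduced (gaps touching a chain
#' terminus are not); (4) included fragments of `min_fragment` residues or
#' fewer are dropped; (5) an empty result resets to all residues.
#'
#' @param mol a `"rog_molecule"`.
#' @param cv_cut circular-variance inclusion cutoff (default 0.2).
#' @param gap_fill maximum gap length to re-include (default 4).
#' @param min_fragment fragments of at most this many residues are pruned
#'   (default 4, i.e. kept fragments have >= 5 residues).
#' @param method `"cv"` (default), `"all"`, or `"user"` with `user_spec`.
#' @param user_spec range string like `"A:9-60,A:70-100"` (1-based,
#'   inclusive) for `method = "user"`.
#' @param dihedrals optional precomputed [molecule_dihedrals()] table.
#' @return object of class `"rog_range"`: `included` (data.frame
#'   `chain`,`seq`), `segments` (`chain`,`first`,`last` in sequence
#'   numbers), `method`, and per-residue `cv` values.
#' @export
select_range <- function(mol, cv_cut = 0.2, gap_fill = 4, min_fragment = 4,
                         method = c("cv", "all", "user"), user_spec = NULL,
                         dihedrals = NULL) {
  method <- match.arg(method)
  rt <- residue_table(mol)
  aa <- rt$restype %in% AMINO_ACIDS
  full <- function(meth) {
    seg <- do.call(rbind, lapply(split(seq_len(nrow(rt)), rt$chain),
                                 function(ix) {
      r <- .runs(ix)
      data.frame(chain = rt$chain[r$first], first = rt$seq[r$first],
                 last = rt$seq[r$last], stringsAsFactors = FALSE)
    }))
    rownames(seg) <- NULL
    structure(list(included = rt[c("chain", "seq")], segments = seg,
                   method = meth, cv = rep(NA_real_, nrow(rt))),
              class = "rog_range")
  }
  if (method == "all") return(full("all"))
  if (method == "user") {
    spec <- parse_range_spec(user_spec)
    inc <- rep(FALSE, nrow(rt))
    for (k in seq_len(nrow(spec)))
      inc <- inc | (rt$chain == spec$chain[k] & rt$seq >= spec$first[k] &
                      rt$seq <= spec$last[k])
    return(.range_from_inclusion(rt, inc, "user", rep(NA_real_, nrow(rt))))
  }
  if (mol$M == 1 || !any(aa)) return(full("all"))
  if (is.null(dihedrals)) dihedrals <- molecule_dihedrals(mol)
  cv <- rep(NA_real_, nrow(rt))
  for (i in seq_len(nrow(rt))) {
    d <- dihedrals[dihedrals$chain == rt$chain[i] & dihedrals$seq == rt$seq[i] &
                     dihedrals$angle %in% c("PHI", "PSI"), ]
    if (nrow(d)) cv[i] <- max(d$circular_variance, na.rm = TRUE)
  }
  inc <- rep(FALSE, nrow(rt))
  for (ch in unique(rt$chain)) {
    ix <- which(rt$chain == ch)
    sel <- !is.na(cv[ix]) & cv[ix] <= cv_cut
    # gap re-inclusion: short excluded runs flanked by included residues
    gaps <- .runs(ix[!sel])
    for (g in seq_len(nrow(gaps))) {
      len <- gaps$last[g] - gaps$first[g] + 1
      flanked <- gaps$first[g] > ix[1] && gaps$last[g] < ix[length(ix)]
      if (len <= gap_fill && flanked)
        sel[match(gaps$first[g]:gaps$last[g], ix)] <- TRUE
    }
    # prune short fragments
    frags <- .runs(ix[sel])
    for (g in seq_len(nrow(frags))) {
      len <- frags$last[g] - frags$first[g] + 1
      if (len <= min_fragment)
        sel[match(frags$first[g]:frags$last[g], ix)] <- FALSE
    }
    inc[ix] <- sel
  }
  if (!any(inc)) return(full("all"))
  .range_from_inclusion(rt, inc, "cv", cv)
}

.range_from_inclusion <- function(rt, inc, method, cv) {
  segs <- do.call(rbind, lapply(split(which(inc), rt$chain[inc]),
                                function(ix) {
    r <- .runs(ix)
    data.frame(chain = rt$chain[r$first], first = rt$seq[r$first],
               last = rt$seq[r$last], stringsAsFactors = FALSE)
  }))
  rownames(segs) <- NULL
  structure(list(included = rt[inc, c("chain", "seq")],
                 segments = segs, method = method, cv = cv),
            class = "rog_range")
}

#' @export
print.rog_range <- function(x, ...) {
  segs <- paste0(x$segments$chain, ":", x$segments$first, "-",
                 x$segments$last, collapse = ",")
  cat(sprintf("<range (%s)> %d residue(s): %s\n", x$method,
              nrow(x$included), segs))
  invisible(x)
}

#' Parse a user range specification
#'
#' @param spec string like `"A:9-60,A:70-100"` (chain:first-last, 1-based,
#'   inclusive, comma-separated).
#' @return data.frame with `chain`, `first`, `last`.
#' @export
parse_range_spec <- function(spec) {
  parts <- strsplit(trimws(strsplit(spec, ",")[[1]]), ":")
  out <- lapply(parts, function(p) {
    if (length(p) != 2) stop("bad range segment: ", paste(p, collapse = ":"))
    fl <- as.integer(strsplit(p[2], "-")[[1]])
    if (length(fl) != 2 || anyNA(fl) || fl[2] < fl[1])
      stop("bad range segment: ", p[2])
    data.frame(chain = p[1], first = fl[1], last = fl[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Aggregate segment statistics over many range selections
#'
#' @param ranges list of `"rog_range"` objects.
#' @param n_residues total residue counts of the corresponding molecules.
#' @return list with `mean_segment_length`, `segments_per_chain` and
#'   `pct_excluded`.
#' @export
summarize_segments <- function(ranges, n_residues) {
  if (!length(ranges)) stop("no ranges supplied")
  seg_len <- unlist(lapply(ranges, function(r)
    r$segments$last - r$segments$first + 1))
  n_seg <- sum(vapply(ranges, function(r) nrow(r$segments), 1L))
  n_chain <- sum(vapply(ranges, function(r)
    length(unique(r$included$chain)), 1L))
  n_inc <- sum(vapply(ranges, function(r) nrow(r$included), 1L))
  list(mean_segment_length = mean(seg_len),
       segments_per_chain = n_seg / n_chain,
       pct_excluded = 100 * (1 - n_inc / sum(n_residues)))
}
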