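# Readers and writers: PDB ensembles (via bio3d), CYANA .upl/.aco restraint
# lines, the package's tab-separated restraint/shift/metric dialects, and the
# assigned-chemical-shift loop subset of NMR-STAR.

#' Read a multi-model PDB file into a molecule
#'
#' All models must contain the identical atom set; the first discrepancy is
#' reported as an error. Alternate locations are reduced to the first altloc
#' per atom with an `altloc_dropped` validation record (attached as the
#' `"records"` attribute).
#'
#' @param path PDB file with `MODEL`/`ENDMDL` records (or a single implicit
#'   model).
#' @return a `"rog_molecule"`; the model count is its `M` field.
#' @export
read_pdb_ensemble <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  atom_lines <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(atom_lines)) stop("no ATOM records in ", path)
  # pre-scan: per-model atom identity must match
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    ids_of <- function(block) {
      al <- block[grepl("^(ATOM  |HETATM)", block)]
      paste(substr(al, 22, 22), trimws(substr(al, 23, 27)),
            trimws(substr(al, 13, 16)), trimws(substr(al, 17, 17)))
    }
    ends <- c(model_starts[-1] - 1, length(lines))
    ref <- ids_of(lines[model_starts[1]:ends[1]])
    ref_na <- sub(" [^ ]*$", "", ref)   # without altloc
    for (k in seq_along(model_starts)[-1]) {
      ids <- ids_of(lines[model_starts[k]:ends[k]])
      ids_na <- sub(" [^ ]*$", "", ids)
      if (!setequal(ref_na, ids_na)) {
        miss <- c(setdiff(ref_na, ids_na), setdiff(ids_na, ref_na))
        stop("model ", k, " differs in atom set: ", miss[1])
      }
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  n_total <- nrow(a)
  M <- nrow(pdb$xyz)
  xyz_all <- array(NA_real_, c(n_total, 3, M))
  for (m in seq_len(M)) xyz_all[, , m] <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
  # first altloc wins
  records <- empty_records()
  key <- paste(a$chain, a$resno, a$insert, a$elety)
  keep <- !duplicated(key)
  if (any(!keep)) {
    dropped <- unique(key[!keep])
    records <- bind_records(records, validation_record(
      path, "altloc_dropped", length(dropped), "green",
      paste("kept first altloc for", length(dropped), "atom(s)")))
  }
  a <- a[keep, , drop = FALSE]
  xyz_all <- xyz_all[keep, , , drop = FALSE]
  ins <- ifelse(is.na(a$insert) | a$insert == "?", "", a$insert)
  elem <- ifelse(is.na(a$elesy) | a$elesy == "", element_of(a$elety), a$elesy)
  atoms <- data.frame(chain = ifelse(is.na(a$chain), "A", a$chain),
                      seq = as.integer(a$resno), ins = ins,
                      restype = toupper(a$resid), atom = a$elety,
                      element = trimws(elem), stringsAsFactors = FALSE)
  mol <- new_molecule(atoms, xyz_all)
  attr(mol, "records") <- records
  mol
}

#' Write a molecule as a multi-model PDB file
#'
#' @param mol a `"rog_molecule"`.
#' @param path output path.
#' @export
write_pdb_ensemble <- function(mol, path) {
  a <- mol$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(mol$M)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    name4 <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                    sprintf("%-4s", a$atom))
    writeLines(sprintf(
      "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), name4, "", a$restype, a$chain, a$seq, a$ins,
      mol$xyz[, 1, m], mol$xyz[, 2, m], mol$xyz[, 3, m], 1, 0,
      a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- restraint lists -------------------------------------------------------

new_restraint_list <- function(name, kind, restraints) {
  structure(list(name = name, kind = kind, restraints = restraints,
                 rog = rog("green")),
            class = "rog_restraint_list")
}

#' @export
print.rog_restraint_list <- function(x, ...) {
  cat(sprintf("<restraint list '%s'> %s, %d restraints, ROG %s\n", x$name,
              x$kind, length(x$restraints), as.character(x$rog)))
  invisible(x)
}

# one distance restraint from contribution rows (one row per atom-pair
# contribution, columns chain_a/seq_a/atom_a/chain_b/seq_b/atom_b)
.make_distance_restraint <- function(rows, lower, upper, hbond, mol,
                                     convention, source_line = "") {
  if (upper < lower)
    stop("upper bound ", upper, " below lower bound ", lower,
         if (nzchar(source_line)) paste0(" at: ", source_line))
  contributions <- list(); unresolved <- character()
  for (r in seq_len(nrow(rows))) {
    ra <- resolve_atom(mol, rows$chain_a[r], rows$seq_a[r], rows$atom_a[r],
                       convention)
    rb <- resolve_atom(mol, rows$chain_b[r], rows$seq_b[r], rows$atom_b[r],
                       convention)
    if (!ra$resolved) unresolved <- c(unresolved, ra$ref)
    if (!rb$resolved) unresolved <- c(unresolved, rb$ref)
    contributions[[r]] <- list(
      a = ra$indices, b = rb$indices,
      a_res = c(rows$chain_a[r], rows$seq_a[r]),
      b_res = c(rows$chain_b[r], rows$seq_b[r]),
      a_name = rows$atom_a[r], b_name = rows$atom_b[r])
  }
  structure(list(contributions = contributions, lower = lower, upper = upper,
                 hbond = isTRUE(hbond), unresolved = unresolved,
                 source_line = source_line, rog = rog("green")),
            class = "rog_distance_restraint")
}

#' Read distance restraints
#'
#' Supported dialects: `"cyana_upl"` (whitespace columns `seq res atom seq
#' res atom upper`, lower bound 0, chain defaulting to the molecule's first
#' chain) and `"tabular"` (tab-separated with header `chain_a seq_a res_a
#' atom_a chain_b seq_b res_b atom_b lower upper hbond [id]`; rows sharing an
#' `id` become contributions of one ambiguous restraint). Pseudo-atom names
#' expand to their member atom groups; references that do not resolve are
#' kept as unresolved markers on the restraint.
#'
#' @param path restraint file.
#' @param mol the `"rog_molecule"` the references resolve against.
#' @param dialect `"cyana_upl"` or `"tabular"`.
#' @param name list name (defaults to the file name).
#' @param convention atom naming convention of the file (`"cyana"` for
#'   `.upl`, `"iupac"` default for tabular).
#' @return a `"rog_restraint_list"` of kind `"distance"`.
#' @export
read_distance_restraints <- function(path, mol,
                                     dialect = c("cyana_upl", "tabular"),
                                     name = basename(path),
                                     convention = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(convention))
    convention <- if (dialect == "cyana_upl") "cyana" else "iupac"
  restraints <- list()
  if (dialect == "cyana_upl") {
    chain1 <- mol$atoms$chain[1]
    lines <- readLines(path)
    for (ln in seq_along(lines)) {
      line <- trimws(lines[ln])
      if (!nzchar(line) || startsWith(line, "#")) next
      tok <- strsplit(line, "[[:space:]]+")[[1]]
      if (length(tok) < 7 || is.na(suppressWarnings(as.numeric(tok[7]))) ||
          is.na(suppressWarnings(as.integer(tok[1]))) ||
          is.na(suppressWarnings(as.integer(tok[4]))))
        stop("unparseable restraint line ", ln, " in ", path, ": ", line)
      rows <- data.frame(chain_a = chain1, seq_a = as.integer(tok[1]),
                         atom_a = tok[3], chain_b = chain1,
                         seq_b = as.integer(tok[4]), atom_b = tok[6],
                         stringsAsFactors = FALSE)
      restraints[[length(restraints) + 1L]] <- .make_distance_restraint(
        rows, 0, as.numeric(tok[7]), FALSE, mol, convention, line)
    }
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("chain_a", "seq_a", "atom_a", "chain_b", "seq_b", "atom_b",
             "upper")
    if (!all(req %in% names(df)))
      stop("tabular restraint file lacks columns: ",
           paste(setdiff(req, names(df)), collapse = ", "))
    if (is.null(df$lower)) df$lower <- 0
    if (is.null(df$hbond)) df$hbond <- FALSE
    if (is.null(df$id)) df$id <- seq_len(nrow(df))
    for (id in unique(df$id)) {
      rows <- df[df$id == id, , drop = FALSE]
      restraints[[length(restraints) + 1L]] <- .make_distance_restraint(
        rows, rows$lower[1], rows$upper[1], rows$hbond[1], mol, convention,
        paste("id", id))
    }
  }
  new_restraint_list(name, "distance", restraints)
}

#' Write distance restraints in the tabular dialect
#'
#' @param x a `"rog_restraint_list"` (distance kind) or a restraint
#'   data.frame as produced by [make_restraints()].
#' @param path output path.
#' @param mol molecule (needed to name atoms when `x` is a restraint list).
#' @export
write_distance_restraints <- function(x, path, mol = NULL) {
  if (is.data.frame(x)) {
    df <- x
  } else {
    rows <- list()
    for (i in seq_along(x$restraints)) {
      r <- x$restraints[[i]]
      for (ct in r$contributions) {
        rows[[length(rows) + 1L]] <- data.frame(
          chain_a = ct$a_res[1], seq_a = as.integer(ct$a_res[2]),
          res_a = if (length(ct$a)) mol$atoms$restype[ct$a[1]] else "UNK",
          atom_a = ct$a_name,
          chain_b = ct$b_res[1], seq_b = as.integer(ct$b_res[2]),
          res_b = if (length(ct$b)) mol$atoms$restype[ct$b[1]] else "UNK",
          atom_b = ct$b_name,
          lower = r$lower, upper = r$upper, hbond = r$hbond, id = i,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- dihedral restraints ---------------------------------------------------

# atoms of a named backbone/side-chain dihedral of residue row i:
# list of (residue offset, atom name)
.angle_topology <- function(restype, angle) {
  switch(angle,
    PHI = list(c(-1, "C"), c(0, "N"), c(0, "CA"), c(0, "C")),
    PSI = list(c(0, "N"), c(0, "CA"), c(0, "C"), c(1, "N")),
    OMEGA = list(c(-1, "CA"), c(-1, "C"), c(0, "N"), c(0, "CA")),
    CHI1 = {
      x4 <- CHI1_FOURTH[restype]
      if (is.na(x4)) NULL
      else list(c(0, "N"), c(0, "CA"), c(0, "CB"), c(0, x4))
    },
    CHI2 = {
      a <- CHI2_ATOMS[[restype]]
      if (is.null(a)) NULL else lapply(seq_along(a), function(k) c(0, a[k]))
    },
    NULL)
}

#' Read dihedral-angle restraints
#'
#' Dialects: `"cyana_aco"` (`seq res angle lower upper`) and `"tabular"`
#' (tab-separated, header `chain seq res angle lower upper`). Angle names
#' (`PHI`, `PSI`, `OMEGA`, `CHI1`, `CHI2`) are mapped to atom quadruples via
#' the residue topology. Bounds are interpreted on the circle, so
#' wrap-around intervals such as `[150, -150]` are legal.
#'
#' @param path restraint file.
#' @param mol the molecule to resolve against.
#' @param dialect `"cyana_aco"` or `"tabular"`.
#' @param name list name.
#' @return a `"rog_restraint_list"` of kind `"dihedral"`.
#' @export
read_dihedral_restraints <- function(path, mol,
                                     dialect = c("cyana_aco", "tabular"),
                                     name = basename(path)) {
  dialect <- match.arg(dialect)
  rt <- residue_table(mol)
  if (dialect == "cyana_aco") {
    lines <- readLines(path)
    rows <- list()
    for (ln in seq_along(lines)) {
      line <- trimws(lines[ln])
      if (!nzchar(line) || startsWith(line, "#")) next
      tok <- strsplit(line, "[[:space:]]+")[[1]]
      if (length(tok) < 5 || is.na(suppressWarnings(as.integer(tok[1]))) ||
          anyNA(suppressWarnings(as.numeric(tok[4:5]))))
        stop("unparseable dihedral restraint line ", ln, ": ", line)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = mol$atoms$chain[1], seq = as.integer(tok[1]),
        angle = toupper(tok[3]), lower = as.numeric(tok[4]),
        upper = as.numeric(tok[5]), stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    df$angle <- toupper(df$angle)
  }
  restraints <- lapply(seq_len(nrow(df)), function(k) {
    i <- which(rt$chain == df$chain[k] & rt$seq == df$seq[k])
    unresolved <- character(); idx <- integer()
    if (!length(i)) {
      unresolved <- paste(df$chain[k], df$seq[k], df$angle[k], sep = ".")
    } else {
      topo <- .angle_topology(rt$restype[i], df$angle[k])
      if (is.null(topo))
        stop("unknown dihedral angle name '", df$angle[k], "' for ",
             rt$restype[i], " ", df$seq[k])
      for (t in topo) {
        j <- i + as.integer(t[1])
        ok <- j >= 1 && j <= nrow(rt) && rt$chain[j] == rt$chain[i]
        ai <- if (ok) mol$lookup[atom_key(rt$chain[j], rt$seq[j], t[2],
                                          rt$ins[j])] else NA
        if (is.na(ai))
          unresolved <- c(unresolved,
                          paste(df$chain[k], df$seq[k] + as.integer(t[1]),
                                t[2], sep = "."))
        else idx <- c(idx, ai)
      }
    }
    structure(list(chain = df$chain[k], seq = df$seq[k],
                   angle_name = df$angle[k], atoms = idx,
                   lower = df$lower[k], upper = df$upper[k],
                   unresolved = unresolved, rog = rog("green")),
              class = "rog_dihedral_restraint")
  })
  new_restraint_list(name, "dihedral", restraints)
}

# ---- shift tables ----------------------------------------------------------

#' Read a chemical-shift table
#'
#' `"tabular"`: tab-separated with header `chain seq res atom value [sd]`.
#' `"nmrstar_loop"`: the assigned-chemical-shift loop subset of NMR-STAR
#' (`_Atom_chem_shift.*` tags). Pseudo-atom names are kept as group
#' references and resolved on demand. An exact duplicate atom reference is
#' an error (one shift per atom reference per list).
#'
#' @param path input file.
#' @param format `"tabular"` or `"nmrstar_loop"`.
#' @return a `"rog_shift_list"`: data.frame `shifts` plus a `rog` state.
#' @export
read_shift_table <- function(path, format = c("tabular", "nmrstar_loop")) {
  format <- match.arg(format)
  if (format == "tabular") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("chain", "seq", "res", "atom", "value")
    if (!all(req %in% names(df)))
      stop("shift table lacks columns: ",
           paste(setdiff(req, names(df)), collapse = ", "))
    if (is.null(df$sd)) df$sd <- NA_real_
  } else {
    lines <- readLines(path)
    tag_lines <- grep("^[[:space:]]*_Atom_chem_shift\\.", lines)
    if (!length(tag_lines)) stop("no _Atom_chem_shift loop in ", path)
    tags <- sub("^[[:space:]]*_Atom_chem_shift\\.", "",
                trimws(lines[tag_lines]))
    data_start <- max(tag_lines) + 1
    body <- lines[data_start:length(lines)]
    body <- body[!grepl("^[[:space:]]*(#|$)", body)]
    stop_at <- grep("^[[:space:]]*(stop_|loop_)", body)
    if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1)]
    tok <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(lengths(tok) != length(tags))
    if (length(bad)) stop("malformed NMR-STAR row: ", body[bad[1]])
    m <- do.call(rbind, tok)
    colnames(m) <- tags
    col <- function(x, default = NA) if (x %in% tags) m[, x] else default
    chain <- col("Auth_asym_ID", col("Entity_assembly_ID", "A"))
    chain[chain %in% c(".", "?")] <- "A"
    df <- data.frame(chain = chain,
                     seq = as.integer(col("Comp_index_ID")),
                     res = toupper(col("Comp_ID")),
                     atom = col("Atom_ID"),
                     value = as.numeric(col("Val")),
                     sd = suppressWarnings(as.numeric(col("Val_err"))),
                     stringsAsFactors = FALSE)
  }
  key <- paste(df$chain, df$seq, df$atom)
  if (anyDuplicated(key))
    stop("duplicate shift row for atom ", key[duplicated(key)][1])
  structure(list(shifts = df, rog = rog("green")), class = "rog_shift_list")
}

#' Write a shift table in the tabular dialect
#' @param x a `"rog_shift_list"` or a shifts data.frame.
#' @param path output path.
#' @export
write_shift_table <- function(x, path) {
  df <- if (inherits(x, "rog_shift_list")) x$shifts else x
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-residue external validation metrics
#'
#' Tab-separated table with header `chain seq` plus any of
#' `ramachandran_z`, `janin_z`, `g_factor`, `d1d2_z`. Missing cells are
#' allowed (that criterion is skipped for the residue). Rows referring to
#' residues absent from the molecule produce `metrics_unknown_residue`
#' warning records attached as the `"records"` attribute.
#'
#' @param path input file.
#' @param mol optional molecule to check residue references against.
#' @return data.frame of the table (with attached records).
#' @export
read_external_metrics <- function(path, mol = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chain", "seq") %in% names(df)))
    stop("external metrics table needs 'chain' and 'seq' columns")
  metric_cols <- intersect(c("ramachandran_z", "janin_z", "g_factor",
                             "d1d2_z"), names(df))
  for (cc in metric_cols) {
    if (!is.numeric(df[[cc]])) {
      bad <- suppressWarnings(is.na(as.numeric(df[[cc]])) & !is.na(df[[cc]]) &
                                df[[cc]] != "")
      if (any(bad))
        stop("non-numeric value '", df[[cc]][bad][1], "' in column ", cc)
      df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    }
  }
  records <- empty_records()
  if (!is.null(mol)) {
    rt <- residue_table(mol)
    known <- paste(df$chain, df$seq) %in% paste(rt$chain, rt$seq)
    for (i in which(!known))
      records <- bind_records(records, validation_record(
        paste(df$chain[i], df$seq[i], sep = "/"), "metrics_unknown_residue",
        NA, "green", "metric row for residue absent from molecule"))
  }
  attr(df, "records") <- records
  df
}

#' Read reference chemical-shift statistics
#'
#' Tab-separated table `restype atom mean sd [count]`.
#' @param path input file.
#' @return data.frame usable wherever [synthetic_reference_shifts()] is.
#' @export
read_reference_shifts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("restype", "atom", "mean", "sd")
  if (!all(req %in% names(df)))
    stop("reference shift table lacks columns: ",
         paste(setdiff(req, names(df)), collapse = ", "))
  if (is.null(df$count)) df$count <- NA_integer_
  df
}
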