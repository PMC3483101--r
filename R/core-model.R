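# In-memory project model: project -> molecule -> chain -> residue -> atom,
# plus restraint lists, shift list, peak lists and validation records.
# The molecule is a flat atom table with an (natoms x 3 x M) coordinate array;
# residues and chains are views on it, which keeps per-model numerics vectorised.

#' Construct a molecule container
#'
#' @param atoms data.frame with columns `chain`, `seq` (integer author
#'   numbering, kept verbatim), `ins` (insertion code, `""` if none),
#'   `restype` (three-letter code, uppercase), `atom` (IUPAC atom name) and
#'   `element`.
#' @param xyz numeric array of dimension `c(nrow(atoms), 3, M)` holding the
#'   coordinates (Angstrom) of every atom in each of the `M` models.
#' @return object of class `"rog_molecule"`.
#' @export
new_molecule <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms), length(dim(xyz)) == 3,
            dim(xyz)[1] == nrow(atoms), dim(xyz)[2] == 3)
  if (is.null(atoms$ins)) atoms$ins <- ""
  key <- atom_key(atoms$chain, atoms$seq, atoms$atom, atoms$ins)
  if (anyDuplicated(key))
    stop("duplicate atom name within a residue: ", key[duplicated(key)][1])
  mol <- list(atoms = atoms, xyz = xyz, M = dim(xyz)[3],
              lookup = stats::setNames(seq_len(nrow(atoms)), key))
  class(mol) <- "rog_molecule"
  mol
}

atom_key <- function(chain, seq, atom, ins = "") {
  paste(chain, seq, ins, atom, sep = "|")
}

#' @export
print.rog_molecule <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<rog_molecule> %d models, %d chains, %d residues, %d atoms\n",
              x$M, length(unique(x$atoms$chain)), nrow(rt), nrow(x$atoms)))
  invisible(x)
}

#' Residue-level view of a molecule
#'
#' @param mol a `"rog_molecule"`.
#' @return data.frame with one row per residue (`chain`, `seq`, `ins`,
#'   `restype`) in file order.
#' @export
residue_table <- function(mol) {
  a <- mol$atoms
  key <- paste(a$chain, a$seq, a$ins, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], seq = a$seq[first], ins = a$ins[first],
             restype = a$restype[first], stringsAsFactors = FALSE)
}

# atom row indices of one residue
residue_atom_rows <- function(mol, chain, seq, ins = "") {
  which(mol$atoms$chain == chain & mol$atoms$seq == seq & mol$atoms$ins == ins)
}

# coordinates of atom row `i` in model `m` (length-3 vector)
atom_xyz <- function(mol, i, m) mol$xyz[i, , m]

#' Resolve an atom reference against a molecule
#'
#' Translates `atom_name` from the given naming convention to IUPAC, expands
#' pseudo-atom names (e.g. Leu `QD1` to `HD11`,`HD12`,`HD13`) into the member
#' atoms present in the molecule, and looks the atoms up. References that do
#' not resolve are returned as unresolved markers, never dropped, so that the
#' owning restraint can be flagged rather than silently shrunk.
#'
#' @param mol a `"rog_molecule"`.
#' @param chain chain identifier.
#' @param seq residue sequence number (author numbering).
#' @param atom_name atom or pseudo-atom name in the given convention.
#' @param convention `"iupac"`, `"cyana"` or `"xplor"`.
#' @return list with `indices` (integer atom rows, possibly several for a
#'   pseudo-atom), `resolved` flag, and `ref` (the locator string).
#' @export
resolve_atom <- function(mol, chain, seq, atom_name, convention = "iupac") {
  ref <- paste(chain, seq, atom_name, sep = ".")
  rows <- residue_atom_rows(mol, chain, seq)
  if (!length(rows))
    return(list(indices = integer(), resolved = FALSE, ref = ref))
  restype <- mol$atoms$restype[rows[1]]
  name <- translate_atom_name(atom_name, restype, convention)
  members <- pseudo_members(restype, name)
  wanted <- if (is.null(members)) name else members
  idx <- rows[match(wanted, mol$atoms$atom[rows])]
  idx <- idx[!is.na(idx)]
  if (!length(idx))
    return(list(indices = integer(), resolved = FALSE, ref = ref))
  if (is.null(members) && length(idx) > 1)
    stop("ambiguous atom reference ", ref, ": candidates ",
         paste(mol$atoms$atom[idx], collapse = ", "))
  list(indices = idx, resolved = TRUE, ref = ref)
}

#' Construct a validation project
#'
#' A project bundles the molecule with all experimental data lists and the
#' validation records accumulated for them.
#'
#' @param name project name.
#' @param molecule a `"rog_molecule"`.
#' @param distance_restraints,dihedral_restraints lists of restraint lists
#'   (see [read_distance_restraints()]).
#' @param shifts optional shift list (see [read_shift_table()]).
#' @param peaks optional list of peak lists.
#' @param external_metrics optional per-residue metric table
#'   (see [read_external_metrics()]).
#' @param ss optional per-model secondary-structure strings.
#' @return object of class `"rog_project"`.
#' @export
new_project <- function(name, molecule, distance_restraints = list(),
                        dihedral_restraints = list(), shifts = NULL,
                        peaks = list(), external_metrics = NULL, ss = NULL) {
  p <- list(name = name, molecule = molecule,
            distance_restraints = distance_restraints,
            dihedral_restraints = dihedral_restraints,
            shifts = shifts, peaks = peaks,
            external_metrics = external_metrics, ss = ss,
            records = empty_records())
  class(p) <- "rog_project"
  p
}

#' @export
print.rog_project <- function(x, ...) {
  cat(sprintf("<rog_project> '%s': %d DR list(s), %d DH list(s), %s shifts\n",
              x$name, length(x$distance_restraints),
              length(x$dihedral_restraints),
              if (is.null(x$shifts)) "no" else nrow(x$shifts$shifts)))
  print(x$molecule)
  invisible(x)
}

# ---- validation records ----------------------------------------------------

# closed registry of criterion keys (value units in parentheses)
CRITERIA <- c(
  "omega_deviation",      # degrees
  "d1d2_z", "ramachandran_z", "janin_z", "g_factor",   # Z / dimensionless
  "dr_max_violation", "dr_rms_violation",              # Angstrom
  "dr_unresolved",
  "dh_max_violation", "dh_rms_violation",              # degrees
  "dh_unresolved",
  "cs_z",                 # Z
  "cs_no_coordinates", "cs_no_reference", "cs_duplicate_assignment",
  "cs_stereo_conflict", "cs_pseudo_inconsistent",
  "peak_unassigned", "peak_z",
  "pro_omega_inconsistency", "leu_sidechain_inconsistency",
  "altloc_dropped", "metrics_unknown_residue", "skipped_pair"
)

empty_records <- function() {
  data.frame(entity_path = character(), criterion = character(),
             value = numeric(), rog = character(), message = character(),
             stringsAsFactors = FALSE)
}

#' Create a validation record
#'
#' @param entity_path locator of the entity the record is about, e.g.
#'   `"A/14/LEU"` or `"A/14/LEU/HA"`.
#' @param criterion key from the closed criterion registry.
#' @param value numeric value of the measured quantity (NA for qualitative
#'   records).
#' @param rog ROG level string or `"rog"` object.
#' @param message human-readable description.
#' @return one-row data.frame.
#' @export
validation_record <- function(entity_path, criterion, value, rog, message) {
  if (!criterion %in% CRITERIA)
    stop("unknown criterion key: ", criterion)
  data.frame(entity_path = entity_path, criterion = criterion,
             value = as.numeric(value),
             rog = if (inherits(rog, "rog")) as.character(rog) else rog,
             message = message, stringsAsFactors = FALSE)
}

bind_records <- function(...) {
  keep <- Filter(function(x) !is.null(x) && nrow(x), list(...))
  if (!length(keep)) return(empty_records())
  do.call(rbind, keep)
}

residue_path <- function(chain, seq, restype) paste(chain, seq, restype, sep = "/")
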