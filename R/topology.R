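# Reference topology for the 20 standard amino acids: proton -> bonded heavy
# atom, pseudo-atom expansions (CYANA-style Q names), magnetic-equivalence
# groups, stereo pairs and chi1/chi2 atom quadruples.  IUPAC atom names
# throughout; other conventions are translated via `translate_atom_name()`.

# proton table: one row per proton, with the heavy atom it is bonded to.
.proton_rows <- function(res, ...) {
  p <- c(...)
  data.frame(restype = res, atom = names(p), parent = unname(p),
             stringsAsFactors = FALSE)
}

.build_proton_table <- function() {
  bb <- c(H = "N", HA = "CA")            # shared backbone protons (not GLY/PRO)
  rows <- list(
    .proton_rows("ALA", bb, HB1 = "CB", HB2 = "CB", HB3 = "CB"),
    .proton_rows("ARG", bb, HB2 = "CB", HB3 = "CB", HG2 = "CG", HG3 = "CG",
                 HD2 = "CD", HD3 = "CD", HE = "NE",
                 HH11 = "NH1", HH12 = "NH1", HH21 = "NH2", HH22 = "NH2"),
    .proton_rows("ASN", bb, HB2 = "CB", HB3 = "CB", HD21 = "ND2", HD22 = "ND2"),
    .proton_rows("ASP", bb, HB2 = "CB", HB3 = "CB"),
    .proton_rows("CYS", bb, HB2 = "CB", HB3 = "CB", HG = "SG"),
    .proton_rows("GLN", bb, HB2 = "CB", HB3 = "CB", HG2 = "CG", HG3 = "CG",
                 HE21 = "NE2", HE22 = "NE2"),
    .proton_rows("GLU", bb, HB2 = "CB", HB3 = "CB", HG2 = "CG", HG3 = "CG"),
    .proton_rows("GLY", c(H = "N"), HA2 = "CA", HA3 = "CA"),
    .proton_rows("HIS", bb, HB2 = "CB", HB3 = "CB", HD1 = "ND1", HD2 = "CD2",
                 HE1 = "CE1", HE2 = "NE2"),
    .proton_rows("ILE", bb, HB = "CB", HG12 = "CG1", HG13 = "CG1",
                 HG21 = "CG2", HG22 = "CG2", HG23 = "CG2",
                 HD11 = "CD1", HD12 = "CD1", HD13 = "CD1"),
    .proton_rows("LEU", bb, HB2 = "CB", HB3 = "CB", HG = "CG",
                 HD11 = "CD1", HD12 = "CD1", HD13 = "CD1",
                 HD21 = "CD2", HD22 = "CD2", HD23 = "CD2"),
    .proton_rows("LYS", bb, HB2 = "CB", HB3 = "CB", HG2 = "CG", HG3 = "CG",
                 HD2 = "CD", HD3 = "CD", HE2 = "CE", HE3 = "CE",
                 HZ1 = "NZ", HZ2 = "NZ", HZ3 = "NZ"),
    .proton_rows("MET", bb, HB2 = "CB", HB3 = "CB", HG2 = "CG", HG3 = "CG",
                 HE1 = "CE", HE2 = "CE", HE3 = "CE"),
    .proton_rows("PHE", bb, HB2 = "CB", HB3 = "CB", HD1 = "CD1", HD2 = "CD2",
                 HE1 = "CE1", HE2 = "CE2", HZ = "CZ"),
    .proton_rows("PRO", c(HA = "CA"), HB2 = "CB", HB3 = "CB",
                 HG2 = "CG", HG3 = "CG", HD2 = "CD", HD3 = "CD"),
    .proton_rows("SER", bb, HB2 = "CB", HB3 = "CB", HG = "OG"),
    .proton_rows("THR", bb, HB = "CB", HG1 = "OG1",
                 HG21 = "CG2", HG22 = "CG2", HG23 = "CG2"),
    .proton_rows("TRP", bb, HB2 = "CB", HB3 = "CB", HD1 = "CD1", HE1 = "NE1",
                 HE3 = "CE3", HZ2 = "CZ2", HZ3 = "CZ3", HH2 = "CH2"),
    .proton_rows("TYR", bb, HB2 = "CB", HB3 = "CB", HD1 = "CD1", HD2 = "CD2",
                 HE1 = "CE1", HE2 = "CE2", HH = "OH"),
    .proton_rows("VAL", bb, HB = "CB", HG11 = "CG1", HG12 = "CG1",
                 HG13 = "CG1", HG21 = "CG2", HG22 = "CG2", HG23 = "CG2")
  )
  do.call(rbind, rows)
}

PROTON_TABLE <- .build_proton_table()

# pseudo-atom name -> member protons, per residue type (CYANA convention)
PSEUDO_ATOMS <- list(
  ALA = list(QB = c("HB1", "HB2", "HB3")),
  ARG = list(QB = c("HB2", "HB3"), QG = c("HG2", "HG3"), QD = c("HD2", "HD3"),
             QH1 = c("HH11", "HH12"), QH2 = c("HH21", "HH22"),
             QQH = c("HH11", "HH12", "HH21", "HH22")),
  ASN = list(QB = c("HB2", "HB3"), QD2 = c("HD21", "HD22")),
  ASP = list(QB = c("HB2", "HB3")),
  CYS = list(QB = c("HB2", "HB3")),
  GLN = list(QB = c("HB2", "HB3"), QG = c("HG2", "HG3"),
             QE2 = c("HE21", "HE22")),
  GLU = list(QB = c("HB2", "HB3"), QG = c("HG2", "HG3")),
  GLY = list(QA = c("HA2", "HA3")),
  HIS = list(QB = c("HB2", "HB3")),
  ILE = list(QG1 = c("HG12", "HG13"), QG2 = c("HG21", "HG22", "HG23"),
             QD1 = c("HD11", "HD12", "HD13")),
  LEU = list(QB = c("HB2", "HB3"), QD1 = c("HD11", "HD12", "HD13"),
             QD2 = c("HD21", "HD22", "HD23"),
             QQD = c("HD11", "HD12", "HD13", "HD21", "HD22", "HD23")),
  LYS = list(QB = c("HB2", "HB3"), QG = c("HG2", "HG3"), QD = c("HD2", "HD3"),
             QE = c("HE2", "HE3"), QZ = c("HZ1", "HZ2", "HZ3")),
  MET = list(QB = c("HB2", "HB3"), QG = c("HG2", "HG3"),
             QE = c("HE1", "HE2", "HE3")),
  PHE = list(QB = c("HB2", "HB3"), QD = c("HD1", "HD2"), QE = c("HE1", "HE2"),
             QR = c("HD1", "HD2", "HE1", "HE2", "HZ")),
  PRO = list(QB = c("HB2", "HB3"), QG = c("HG2", "HG3"), QD = c("HD2", "HD3")),
  SER = list(QB = c("HB2", "HB3")),
  THR = list(QG2 = c("HG21", "HG22", "HG23")),
  TRP = list(QB = c("HB2", "HB3")),
  TYR = list(QB = c("HB2", "HB3"), QD = c("HD1", "HD2"), QE = c("HE1", "HE2")),
  VAL = list(QG1 = c("HG11", "HG12", "HG13"), QG2 = c("HG21", "HG22", "HG23"),
             QQG = c("HG11", "HG12", "HG13", "HG21", "HG22", "HG23"))
)

# magnetic-equivalence groups collapsed to one observable in NOE completeness:
# methyl rotors and fast-flipping aromatic ring pairs.
EQUIVALENT_GROUPS <- list(
  ALA = list(c("HB1", "HB2", "HB3")),
  ILE = list(c("HG21", "HG22", "HG23"), c("HD11", "HD12", "HD13")),
  LEU = list(c("HD11", "HD12", "HD13"), c("HD21", "HD22", "HD23")),
  LYS = list(c("HZ1", "HZ2", "HZ3")),
  MET = list(c("HE1", "HE2", "HE3")),
  PHE = list(c("HD1", "HD2"), c("HE1", "HE2")),
  THR = list(c("HG21", "HG22", "HG23")),
  TYR = list(c("HD1", "HD2"), c("HE1", "HE2")),
  VAL = list(c("HG11", "HG12", "HG13"), c("HG21", "HG22", "HG23"))
)

# prochiral stereo pairs whose members may carry a joint pseudo assignment
STEREO_PAIRS <- list(
  GLY = list(c("HA2", "HA3")),
  ARG = list(c("HB2", "HB3"), c("HG2", "HG3"), c("HD2", "HD3")),
  ASN = list(c("HB2", "HB3"), c("HD21", "HD22")),
  ASP = list(c("HB2", "HB3")), CYS = list(c("HB2", "HB3")),
  GLN = list(c("HB2", "HB3"), c("HG2", "HG3"), c("HE21", "HE22")),
  GLU = list(c("HB2", "HB3"), c("HG2", "HG3")),
  HIS = list(c("HB2", "HB3")),
  ILE = list(c("HG12", "HG13")),
  LEU = list(c("HB2", "HB3"), c("CD1", "CD2")),
  LYS = list(c("HB2", "HB3"), c("HG2", "HG3"), c("HD2", "HD3"),
             c("HE2", "HE3")),
  MET = list(c("HB2", "HB3"), c("HG2", "HG3")),
  PHE = list(c("HB2", "HB3")), PRO = list(c("HB2", "HB3"), c("HG2", "HG3"),
                                          c("HD2", "HD3")),
  SER = list(c("HB2", "HB3")), TRP = list(c("HB2", "HB3")),
  TYR = list(c("HB2", "HB3")),
  VAL = list(c("CG1", "CG2"))
)

# chi1: N-CA-CB-X; chi2: CA-CB-CG(*)-X
CHI1_FOURTH <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG",
                 GLU = "CG", HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG",
                 MET = "CG", PHE = "CG", PRO = "CG", SER = "OG", THR = "OG1",
                 TRP = "CG", TYR = "CG", VAL = "CG1")
CHI2_ATOMS <- list(
  ARG = c("CA", "CB", "CG", "CD"),  GLN = c("CA", "CB", "CG", "CD"),
  GLU = c("CA", "CB", "CG", "CD"),  ILE = c("CA", "CB", "CG1", "CD1"),
  LEU = c("CA", "CB", "CG", "CD1"), LYS = c("CA", "CB", "CG", "CD"),
  MET = c("CA", "CB", "CG", "SD"),  PHE = c("CA", "CB", "CG", "CD1"),
  PRO = c("CA", "CB", "CG", "CD"),  TRP = c("CA", "CB", "CG", "CD1"),
  TYR = c("CA", "CB", "CG", "CD1"), HIS = c("CA", "CB", "CG", "ND1"),
  ASN = c("CA", "CB", "CG", "OD1"), ASP = c("CA", "CB", "CG", "OD1")
)

AMINO_ACIDS <- sort(unique(PROTON_TABLE$restype))

#' Translate an atom name from another naming convention to IUPAC
#'
#' Supported conventions are `"iupac"` (identity), `"cyana"` and `"xplor"`.
#' Both CYANA and X-PLOR write the backbone amide proton as `HN`; pseudo-atom
#' names (`QB`, `QD1`, ...) are left untouched here and expanded downstream by
#' [resolve_atom()].
#'
#' @param name atom name as found in the input file.
#' @param restype three-letter residue type (uppercase).
#' @param convention one of `"iupac"`, `"cyana"`, `"xplor"`.
#' @return the IUPAC atom name.
#' @export
translate_atom_name <- function(name, restype, convention = "iupac") {
  convention <- match.arg(convention, c("iupac", "cyana", "xplor"))
  if (convention == "iupac") return(name)
  if (name == "HN") return("H")
  # X-PLOR digit-first methylene/methyl names, e.g. 1HB -> HB1
  if (convention == "xplor" && grepl("^[0-9]H", name)) {
    return(paste0(substring(name, 2), substring(name, 1, 1)))
  }
  name
}

#' Expand a pseudo-atom name into its member protons
#'
#' @param restype three-letter residue type.
#' @param name candidate pseudo-atom name (e.g. `"QD1"`).
#' @return character vector of member proton names, or `NULL` if `name` is
#'   not a pseudo-atom of that residue type.
#' @export
pseudo_members <- function(restype, name) {
  ps <- PSEUDO_ATOMS[[toupper(restype)]]
  if (is.null(ps)) return(NULL)
  ps[[name]]
}

# element from an IUPAC atom name
element_of <- function(name) {
  ifelse(grepl("^[0-9]*H", name), "H", substring(sub("^[0-9]+", "", name), 1, 1))
}
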