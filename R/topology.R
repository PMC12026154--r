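# Internal topology templates for the 20 standard amino acids: heavy-atom
# composition, intra-residue covalent bonds, semi-essential hydrogen rules
# and side-chain internal coordinates for the residues the synthetic builder
# can grow.  Atom names follow PDB v3 conventions.

.aa_three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
               Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
               L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
               S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.aa_one <- structure(names(.aa_three), names = .aa_three)

.backbone_atoms <- c("N", "CA", "C", "O")

# Side-chain heavy atoms per residue (backbone excluded; OXT optional).
.side_chain_atoms <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

# Intra-residue heavy-atom bonds (atom-name pairs).  Backbone N-CA, CA-C,
# C-O, C-OXT and CA-CB are common and added programmatically.
.side_chain_bonds <- list(
  ALA = NULL,
  ARG = rbind(c("CB", "CG"), c("CG", "CD"), c("CD", "NE"), c("NE", "CZ"),
              c("CZ", "NH1"), c("CZ", "NH2")),
  ASN = rbind(c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2")),
  ASP = rbind(c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
  CYS = rbind(c("CB", "SG")),
  GLN = rbind(c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"), c("CD", "NE2")),
  GLU = rbind(c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"), c("CD", "OE2")),
  GLY = NULL,
  HIS = rbind(c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2"), c("ND1", "CE1"),
              c("CD2", "NE2"), c("CE1", "NE2")),
  ILE = rbind(c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
  LEU = rbind(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
  LYS = rbind(c("CB", "CG"), c("CG", "CD"), c("CD", "CE"), c("CE", "NZ")),
  MET = rbind(c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
  PHE = rbind(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"), c("CD1", "CE1"),
              c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
  PRO = rbind(c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
  SER = rbind(c("CB", "OG")),
  THR = rbind(c("CB", "OG1"), c("CB", "CG2")),
  TRP = rbind(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"), c("CD1", "NE1"),
              c("NE1", "CE2"), c("CD2", "CE2"), c("CD2", "CE3"),
              c("CE3", "CZ3"), c("CZ3", "CH2"), c("CH2", "CZ2"),
              c("CZ2", "CE2")),
  TYR = rbind(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"), c("CD1", "CE1"),
              c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"), c("CZ", "OH")),
  VAL = rbind(c("CB", "CG1"), c("CB", "CG2"))
)

# Semi-essential hydrogens: polar (on N/O/S), on unsaturated carbons, and on
# carbons alpha to a heteroatom.  Each entry: parent heavy atom, number of
# hydrogens, local geometry (sp3 tetrahedral or sp2 planar).  The backbone
# amide H and the alpha H (CA is alpha to N) are shared by all residues and
# added programmatically; Gly gets two alpha hydrogens, Pro has no amide H.
.side_chain_hydrogens <- list(
  ALA = NULL,
  ARG = list(c("CD", 2, "sp3"), c("NE", 1, "sp2"), c("NH1", 2, "sp2"),
             c("NH2", 2, "sp2")),
  ASN = list(c("ND2", 2, "sp2")),
  ASP = NULL,
  CYS = list(c("CB", 2, "sp3"), c("SG", 1, "sp3")),
  GLN = list(c("NE2", 2, "sp2")),
  GLU = NULL,
  GLY = NULL,
  HIS = list(c("CD2", 1, "sp2"), c("CE1", 1, "sp2"), c("NE2", 1, "sp2")),
  ILE = NULL,
  LEU = NULL,
  LYS = list(c("CE", 2, "sp3"), c("NZ", 3, "sp3")),
  MET = list(c("CG", 2, "sp3"), c("CE", 3, "sp3")),
  PHE = list(c("CD1", 1, "sp2"), c("CD2", 1, "sp2"), c("CE1", 1, "sp2"),
             c("CE2", 1, "sp2"), c("CZ", 1, "sp2")),
  PRO = list(c("CD", 2, "sp3")),
  SER = list(c("CB", 2, "sp3"), c("OG", 1, "sp3")),
  THR = list(c("CB", 1, "sp3"), c("OG1", 1, "sp3")),
  TRP = list(c("CD1", 1, "sp2"), c("NE1", 1, "sp2"), c("CE3", 1, "sp2"),
             c("CZ2", 1, "sp2"), c("CZ3", 1, "sp2"), c("CH2", 1, "sp2")),
  TYR = list(c("CD1", 1, "sp2"), c("CD2", 1, "sp2"), c("CE1", 1, "sp2"),
             c("CE2", 1, "sp2"), c("OH", 1, "sp3")),
  VAL = NULL
)

# X-H bond lengths by heavy-atom element, Angstrom.
.h_bond_length <- c(N = 1.01, O = 0.96, S = 1.34, C = 1.09)

# Side-chain internal coordinates for residues the synthetic builder can
# grow: atom, three reference atoms, bond length, angle, dihedral (common
# rotamer).  CB is placed from backbone for every residue.
.side_chain_zmat <- list(
  ALA = NULL,
  GLY = NULL,
  SER = list(list("OG", c("N", "CA", "CB"), 1.41, 110.5, -60)),
  CYS = list(list("SG", c("N", "CA", "CB"), 1.81, 114.0, -60)),
  VAL = list(list("CG1", c("N", "CA", "CB"), 1.53, 110.5, 175),
             list("CG2", c("N", "CA", "CB"), 1.53, 110.5, -65)),
  LEU = list(list("CG", c("N", "CA", "CB"), 1.53, 116.3, -60),
             list("CD1", c("CA", "CB", "CG"), 1.53, 110.5, 180),
             list("CD2", c("CA", "CB", "CG"), 1.53, 110.5, 60)),
  PHE = list(list("CG", c("N", "CA", "CB"), 1.51, 113.8, -60),
             list("CD1", c("CA", "CB", "CG"), 1.39, 120.8, 90),
             list("CD2", c("CA", "CB", "CG"), 1.39, 120.8, -90),
             list("CE1", c("CB", "CG", "CD1"), 1.39, 121.0, 180),
             list("CE2", c("CB", "CG", "CD2"), 1.39, 121.0, 180),
             list("CZ", c("CG", "CD1", "CE1"), 1.39, 120.0, 0)),
  TYR = list(list("CG", c("N", "CA", "CB"), 1.51, 113.8, -60),
             list("CD1", c("CA", "CB", "CG"), 1.39, 120.8, 90),
             list("CD2", c("CA", "CB", "CG"), 1.39, 120.8, -90),
             list("CE1", c("CB", "CG", "CD1"), 1.39, 121.0, 180),
             list("CE2", c("CB", "CG", "CD2"), 1.39, 121.0, 180),
             list("CZ", c("CG", "CD1", "CE1"), 1.39, 120.0, 0),
             list("OH", c("CD1", "CE1", "CZ"), 1.38, 119.9, 180))
)

.vdw_radius <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
.atomic_mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)

.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

#' @noRd
infer_element <- function(name) {
  nm <- gsub("[[:space:]]", "", name)
  out <- character(length(nm))
  first_digit <- grepl("^[0-9]", nm)
  out[first_digit] <- "H"
  rest <- !first_digit
  out[rest] <- substr(gsub("[0-9']", "", nm[rest]), 1, 1)
  out[out == "" | is.na(out)] <- "X"
  out
}

#' Names for n hydrogens on a given parent heavy atom (e.g. OG -> HG,
#' ND2 -> HD21 HD22, backbone N -> H).
#' @noRd
hydrogen_names <- function(parent, n) {
  stem <- if (parent == "N") "" else substring(parent, 2)
  if (n == 1) paste0("H", stem) else paste0("H", stem, seq_len(n))
}

is_standard_resname <- function(res_name) res_name %in% names(.side_chain_atoms)

#' Heavy-atom template (backbone + side chain) for a residue name
#' @noRd
residue_template <- function(res_name) {
  sc <- .side_chain_atoms[[res_name]]
  if (is.null(sc)) stop("no template for residue '", res_name, "'")
  c(.backbone_atoms, sc)
}

#' Intra-residue heavy-atom bond table for a residue name
#' @noRd
residue_bond_template <- function(res_name) {
  b <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"))
  if (!(res_name %in% c("GLY"))) b <- rbind(b, c("CA", "CB"))
  sc <- .side_chain_bonds[[res_name]]
  if (!is.null(sc)) b <- rbind(b, sc)
  b
}
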