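# Hydropathic atom-constant parameter set.
#
# The scoring engine follows the HINT architecture (pairwise
# solvent-modulated logP-based scores) but ships its own open parameter
# table: hydrophobic atom constants `a` with sign carrying polarity
# (hydrophobic carbons/sulfurs positive, polar nitrogens/oxygens negative),
# values in the spirit of published atomic logP fragment contributions, a
# polarity class (hydrophobic, polar-neutral, acid, base, amphoteric, at
# neutral pH: Asp/Glu side-chain oxygens acid, Lys/Arg nitrogens base, His
# ring nitrogens amphoteric/neutral) and a hydrogen-bond role.

# side-chain entries: atom, a, class, role
.hint_side_values <- list(
  ALA = list(c("CB", 0.65, "hydrophobic", "none")),
  ARG = list(c("CB", 0.45, "hydrophobic", "none"),
             c("CG", 0.45, "hydrophobic", "none"),
             c("CD", 0.20, "hydrophobic", "none"),
             c("NE", -0.70, "base", "donor"),
             c("CZ", -0.20, "polar-neutral", "none"),
             c("NH1", -1.20, "base", "donor"),
             c("NH2", -1.20, "base", "donor")),
  ASN = list(c("CB", 0.45, "hydrophobic", "none"),
             c("CG", -0.25, "polar-neutral", "none"),
             c("OD1", -0.85, "polar-neutral", "acceptor"),
             c("ND2", -0.70, "polar-neutral", "donor")),
  ASP = list(c("CB", 0.45, "hydrophobic", "none"),
             c("CG", -0.30, "polar-neutral", "none"),
             c("OD1", -1.30, "acid", "acceptor"),
             c("OD2", -1.30, "acid", "acceptor")),
  CYS = list(c("CB", 0.45, "hydrophobic", "none"),
             c("SG", -0.20, "polar-neutral", "both")),
  GLN = list(c("CB", 0.45, "hydrophobic", "none"),
             c("CG", 0.45, "hydrophobic", "none"),
             c("CD", -0.25, "polar-neutral", "none"),
             c("OE1", -0.85, "polar-neutral", "acceptor"),
             c("NE2", -0.70, "polar-neutral", "donor")),
  GLU = list(c("CB", 0.45, "hydrophobic", "none"),
             c("CG", 0.45, "hydrophobic", "none"),
             c("CD", -0.30, "polar-neutral", "none"),
             c("OE1", -1.30, "acid", "acceptor"),
             c("OE2", -1.30, "acid", "acceptor")),
  GLY = list(),
  HIS = list(c("CB", 0.45, "hydrophobic", "none"),
             c("CG", 0.10, "hydrophobic", "none"),
             c("ND1", -0.75, "amphoteric", "acceptor"),
             c("CD2", 0.30, "hydrophobic", "none"),
             c("CE1", 0.20, "hydrophobic", "none"),
             c("NE2", -0.70, "amphoteric", "donor")),
  ILE = list(c("CB", 0.25, "hydrophobic", "none"),
             c("CG1", 0.45, "hydrophobic", "none"),
             c("CG2", 0.65, "hydrophobic", "none"),
             c("CD1", 0.65, "hydrophobic", "none")),
  LEU = list(c("CB", 0.45, "hydrophobic", "none"),
             c("CG", 0.25, "hydrophobic", "none"),
             c("CD1", 0.65, "hydrophobic", "none"),
             c("CD2", 0.65, "hydrophobic", "none")),
  LYS = list(c("CB", 0.45, "hydrophobic", "none"),
             c("CG", 0.45, "hydrophobic", "none"),
             c("CD", 0.45, "hydrophobic", "none"),
             c("CE", 0.20, "hydrophobic", "none"),
             c("NZ", -1.60, "base", "donor")),
  MET = list(c("CB", 0.45, "hydrophobic", "none"),
             c("CG", 0.30, "hydrophobic", "none"),
             c("SD", 0.50, "hydrophobic", "none"),
             c("CE", 0.40, "hydrophobic", "none")),
  PHE = list(c("CB", 0.45, "hydrophobic", "none"),
             c("CG", 0.20, "hydrophobic", "none"),
             c("CD1", 0.35, "hydrophobic", "none"),
             c("CD2", 0.35, "hydrophobic", "none"),
             c("CE1", 0.35, "hydrophobic", "none"),
             c("CE2", 0.35, "hydrophobic", "none"),
             c("CZ", 0.35, "hydrophobic", "none")),
  PRO = list(c("CB", 0.45, "hydrophobic", "none"),
             c("CG", 0.45, "hydrophobic", "none"),
             c("CD", 0.20, "hydrophobic", "none")),
  SER = list(c("CB", 0.30, "hydrophobic", "none"),
             c("OG", -0.90, "polar-neutral", "both")),
  THR = list(c("CB", 0.15, "hydrophobic", "none"),
             c("OG1", -0.90, "polar-neutral", "both"),
             c("CG2", 0.65, "hydrophobic", "none")),
  TRP = list(c("CB", 0.45, "hydrophobic", "none"),
             c("CG", 0.20, "hydrophobic", "none"),
             c("CD1", 0.30, "hydrophobic", "none"),
             c("CD2", 0.20, "hydrophobic", "none"),
             c("NE1", -0.55, "polar-neutral", "donor"),
             c("CE2", 0.20, "hydrophobic", "none"),
             c("CE3", 0.35, "hydrophobic", "none"),
             c("CZ2", 0.35, "hydrophobic", "none"),
             c("CZ3", 0.35, "hydrophobic", "none"),
             c("CH2", 0.35, "hydrophobic", "none")),
  TYR = list(c("CB", 0.45, "hydrophobic", "none"),
             c("CG", 0.20, "hydrophobic", "none"),
             c("CD1", 0.35, "hydrophobic", "none"),
             c("CD2", 0.35, "hydrophobic", "none"),
             c("CE1", 0.35, "hydrophobic", "none"),
             c("CE2", 0.35, "hydrophobic", "none"),
             c("CZ", 0.10, "hydrophobic", "none"),
             c("OH", -0.90, "polar-neutral", "both")),
  VAL = list(c("CB", 0.25, "hydrophobic", "none"),
             c("CG1", 0.65, "hydrophobic", "none"),
             c("CG2", 0.65, "hydrophobic", "none"))
)

.h_polar_a <- -0.35    # hydrogens on N/O/S
.h_carbon_a <- 0.10    # hydrogens on unsaturated / alpha carbons

#' Default hydropathic atom-constant table
#'
#' One row per (res_name, atom_name) for all heavy atoms of the 20 standard
#' residues (including OXT and terminal amine hydrogens) and all
#' semi-essential hydrogens, with columns `a` (hydrophobic atom constant,
#' sign carries polarity), `class` (hydrophobic, polar-neutral, acid, base,
#' amphoteric) and `role` (donor, acceptor, both, none).
#' @return data.frame
#' @export
default_hint_table <- function() {
  rows <- list()
  add <- function(res, atom, a, cls, role)
    rows[[length(rows) + 1L]] <<- data.frame(
      res_name = res, atom_name = atom, a = as.numeric(a), class = cls,
      role = role, stringsAsFactors = FALSE)
  for (rn in names(.side_chain_atoms)) {
    if (rn == "PRO") add(rn, "N", -0.35, "polar-neutral", "none")
    else add(rn, "N", -0.60, "polar-neutral", "donor")
    add(rn, "CA", 0.10, "hydrophobic", "none")
    add(rn, "C", -0.25, "polar-neutral", "none")
    add(rn, "O", -0.80, "polar-neutral", "acceptor")
    add(rn, "OXT", -1.30, "acid", "acceptor")
    # backbone hydrogens: amide H (or terminal H1-H3) and alpha H
    if (rn != "PRO") for (h in c("H", "H1", "H2", "H3"))
      add(rn, h, .h_polar_a, "polar-neutral", "none")
    if (rn == "GLY") for (h in c("HA1", "HA2"))
      add(rn, h, .h_carbon_a, "hydrophobic", "none")
    else add(rn, "HA", .h_carbon_a, "hydrophobic", "none")
    for (s in .hint_side_values[[rn]]) add(rn, s[1], s[2], s[3], s[4])
    spec <- .side_chain_hydrogens[[rn]]
    if (!is.null(spec)) for (s in spec) {
      el <- substr(s[1], 1, 1)
      hn <- hydrogen_names(s[1], as.integer(s[2]))
      for (h in hn) {
        if (el == "C") add(rn, h, .h_carbon_a, "hydrophobic", "none")
        else add(rn, h, .h_polar_a, "polar-neutral", "none")
      }
    }
  }
  do.call(rbind, rows)
}

#' Hydropathic scoring parameters
#'
#' @param table atom-constant table as from [default_hint_table()], or a
#'   path to a TSV with columns res_name, atom_name, a, class, role.
#' @param probe_radius SASA probe radius, Angstrom.
#' @param sphere_points SASA lattice points per atom.
#' @param delta length scale of the exponential distance function
#'   `R_ij = exp(-r_ij / delta)`, Angstrom.
#' @param exclusion_bond_depth pairs within this covalent bond-graph
#'   distance are excluded (3 skips 1-2, 1-3 and 1-4 pairs).
#' @param cutoff pair distance cutoff, Angstrom.
#' @param hb_dist,hb_angle hydrogen-bond geometry: maximum
#'   hydrogen-acceptor distance (Angstrom) and minimum donor-H-acceptor
#'   angle (degrees).
#' @return object of class `hint_params`
#' @export
hint_params <- function(table = default_hint_table(), probe_radius = 1.4,
                        sphere_points = 256, delta = 1.0,
                        exclusion_bond_depth = 3, cutoff = 9.0,
                        hb_dist = 2.5, hb_angle = 120) {
  if (is.character(table)) table <- read_hint_table(table)
  stopifnot(is.data.frame(table),
            all(c("res_name", "atom_name", "a", "class", "role") %in%
                  names(table)))
  carbon <- infer_element(table$atom_name) == "C"
  if (any(table$a == 0 & carbon))
    stop("a = 0 is not allowed for carbon atoms")
  structure(list(table = table, probe_radius = probe_radius,
                 sphere_points = as.integer(sphere_points), delta = delta,
                 exclusion_bond_depth = as.integer(exclusion_bond_depth),
                 cutoff = cutoff, hb_dist = hb_dist, hb_angle = hb_angle),
            class = "hint_params")
}

#' @export
print.hint_params <- function(x, ...) {
  cat("hint_params: ", nrow(x$table), " atom entries; R_ij = exp(-r/",
      x$delta, " A), cutoff ", x$cutoff, " A, bond-depth exclusion <= ",
      x$exclusion_bond_depth, ", probe ", x$probe_radius, " A x ",
      x$sphere_points, " points\n", sep = "")
  invisible(x)
}

#' Read an atom-constant table from TSV
#' @param path TSV with columns res_name, atom_name, a, class, role
#' @export
read_hint_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write an atom-constant table to TSV
#' @param table data.frame as from [default_hint_table()]
#' @param path output path
#' @export
write_hint_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
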