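# StructureModel and Trajectory containers.
#
# A structure_model holds an ordered atom table, the derived residue list
# and a covalent bond list built from residue topology templates plus
# peptide bonds and auto-detected disulfides (needed downstream to exclude
# covalently bonded pairs from hydropathic scoring without CONECT records).

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_seq`, `chain`, `x`, `y`, `z` and optionally
#'   `occupancy`, `b_factor`.  Blank elements are inferred from atom names.
#' @return object of class `structure_model` with components `atoms`,
#'   `residues` (ordered `chain`/`res_seq`/`res_name` table) and `bonds`
#'   (two-column matrix of atom indices, `i < j`).
#' @export
structure_model <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "res_name", "res_seq", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty atom table: no protein atoms")
  atoms$name <- trimws(atoms$name)
  atoms$res_name <- trimws(atoms$res_name)
  atoms$res_seq <- as.integer(atoms$res_seq)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element) || any(!nzchar(trimws(atoms$element)))) {
    el <- if (is.null(atoms$element)) rep("", nrow(atoms)) else trimws(atoms$element)
    blank <- !nzchar(el)
    el[blank] <- infer_element(atoms$name[blank])
    atoms$element <- el
  } else {
    atoms$element <- trimws(atoms$element)
  }
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$b_factor)) atoms$b_factor <- 0
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$res_seq, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain, res_seq, name): ",
         key[duplicated(key)][1])
  rownames(atoms) <- NULL
  model <- list(atoms = atoms,
                residues = derive_residues(atoms),
                bonds = derive_bonds(atoms))
  class(model) <- "structure_model"
  model
}

derive_residues <- function(atoms) {
  rid <- paste(atoms$chain, atoms$res_seq)
  first <- !duplicated(rid)
  data.frame(chain = atoms$chain[first], res_seq = atoms$res_seq[first],
             res_name = atoms$res_name[first], stringsAsFactors = FALSE)
}

# Covalent bonds: template intra-residue bonds by atom name, hydrogens to
# their nearest same-residue heavy atom (< 1.6 A), peptide C-N between
# consecutive residues of a chain (< 1.8 A), disulfide SG-SG <= 2.5 A.
derive_bonds <- function(atoms) {
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rid <- paste(atoms$chain, atoms$res_seq)
  bonds <- list()
  for (r in unique(rid)) {
    idx <- which(rid == r)
    rn <- atoms$res_name[idx[1]]
    nm <- atoms$name[idx]
    heavy <- idx[atoms$element[idx] != "H"]
    if (is_standard_resname(rn)) {
      tmpl <- residue_bond_template(rn)
      for (k in seq_len(nrow(tmpl))) {
        i <- idx[match(tmpl[k, 1], nm)]
        j <- idx[match(tmpl[k, 2], nm)]
        if (!is.na(i) && !is.na(j)) bonds[[length(bonds) + 1L]] <- c(i, j)
      }
    }
    hyd <- idx[atoms$element[idx] == "H"]
    for (h in hyd) {
      if (!length(heavy)) next
      d2 <- rowSums((xyz[heavy, , drop = FALSE] -
                       matrix(xyz[h, ], length(heavy), 3, byrow = TRUE))^2)
      k <- which.min(d2)
      if (d2[k] < 1.6^2) bonds[[length(bonds) + 1L]] <- c(heavy[k], h)
    }
  }
  # peptide bonds between residues consecutive in the file within a chain
  res_first <- which(!duplicated(rid))
  for (k in seq_along(res_first)[-1]) {
    i_prev <- which(rid == rid[res_first[k - 1]])
    i_cur <- which(rid == rid[res_first[k]])
    if (atoms$chain[i_prev[1]] != atoms$chain[i_cur[1]]) next
    ci <- i_prev[match("C", atoms$name[i_prev])]
    ni <- i_cur[match("N", atoms$name[i_cur])]
    if (!is.na(ci) && !is.na(ni) &&
        sum((xyz[ci, ] - xyz[ni, ])^2) < 1.8^2)
      bonds[[length(bonds) + 1L]] <- c(ci, ni)
  }
  # disulfides
  sg <- which(atoms$name == "SG")
  if (length(sg) > 1) {
    for (a in seq_along(sg)[-length(sg)]) for (b in (a + 1):length(sg)) {
      if (sum((xyz[sg[a], ] - xyz[sg[b], ])^2) <= 2.5^2)
        bonds[[length(bonds) + 1L]] <- c(sg[a], sg[b])
    }
  }
  if (!length(bonds)) return(matrix(integer(0), ncol = 2))
  b <- do.call(rbind, bonds)
  b <- cbind(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  unique(b[b[, 1] != b[, 2], , drop = FALSE])
}

#' Atom coordinates of a structure model
#' @param model a `structure_model`
#' @return n x 3 numeric matrix (Angstrom)
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure model
#' @param model a `structure_model`
#' @param xyz n x 3 matrix congruent with the atom table
#' @export
set_coords <- function(model, xyz) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.matrix(xyz)
  if (!all(dim(xyz) == c(nrow(model$atoms), 3)))
    stop("coordinate matrix not congruent with atom table")
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Check structure model invariants
#'
#' Verifies finite coordinates, unique atom identities, and the presence of
#' backbone N, CA, C in every residue (chain-terminal residues may lack N or
#' C).  Returns the model invisibly or raises an error.
#' @param model a `structure_model`
#' @export
validate_structure <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- coords(model)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  key <- with(model$atoms, paste(chain, res_seq, name))
  if (anyDuplicated(key)) stop("duplicate atom identity")
  rid <- with(model$atoms, paste(chain, res_seq))
  rids <- unique(rid)
  for (k in seq_along(rids)) {
    nm <- model$atoms$name[rid == rids[k]]
    if (!("CA" %in% nm)) stop("residue ", rids[k], " lacks CA")
    terminal <- k == 1 || k == length(rids) ||
      model$residues$chain[k] != model$residues$chain[max(k - 1, 1)] ||
      model$residues$chain[k] != model$residues$chain[min(k + 1, length(rids))]
    if (!terminal && !all(c("N", "C") %in% nm))
      stop("residue ", rids[k], " lacks backbone N or C")
  }
  if (nrow(model$bonds)) {
    if (any(model$bonds[, 1] == model$bonds[, 2])) stop("self-bond in bond list")
  }
  invisible(model)
}

residue_index <- function(model, chain, res_seq) {
  which(model$atoms$chain == chain & model$atoms$res_seq == res_seq)
}

#' @export
print.structure_model <- function(x, ...) {
  nres <- nrow(x$residues)
  nh <- sum(x$atoms$element == "H")
  cat("structure_model: ", nrow(x$atoms), " atoms (", nh, " H), ",
      nres, " residues, chains: ",
      paste(unique(x$atoms$chain), collapse = " "),
      ", ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' @export
summary.structure_model <- function(object, ...) {
  tab <- table(object$residues$res_name)
  cat("Residue composition:\n")
  print(tab)
  ss <- disulfides(object)
  if (nrow(ss)) {
    cat("Disulfides:\n")
    for (k in seq_len(nrow(ss)))
      cat("  ", ss$res_i[k], ss$seq_i[k], "-", ss$res_j[k], ss$seq_j[k], "\n")
  }
  invisible(object)
}

#' Disulfide bridges detected in a model
#' @param model a `structure_model`
#' @return data.frame of SG-SG pairs (chain/res_seq of both partners)
#' @export
disulfides <- function(model) {
  b <- model$bonds
  at <- model$atoms
  keep <- at$name[b[, 1]] == "SG" & at$name[b[, 2]] == "SG"
  b <- b[keep, , drop = FALSE]
  data.frame(chain_i = at$chain[b[, 1]], seq_i = at$res_seq[b[, 1]],
             res_i = at$res_name[b[, 1]], chain_j = at$chain[b[, 2]],
             seq_j = at$res_seq[b[, 2]], res_j = at$res_name[b[, 2]],
             stringsAsFactors = FALSE)
}

#' Construct a trajectory from a reference model and frame coordinates
#'
#' @param reference a `structure_model`
#' @param xyz matrix of frames, one row per frame, `3 * n_atoms` columns in
#'   x,y,z atom-major order, or a list of n x 3 coordinate matrices.
#' @param dt time step between frames, ps.
#' @return object of class `md_trajectory`
#' @export
md_trajectory <- function(reference, xyz, dt = 1) {
  stopifnot(inherits(reference, "structure_model"))
  if (is.list(xyz) && !is.matrix(xyz))
    xyz <- do.call(rbind, lapply(xyz, function(m) as.numeric(t(m))))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * nrow(reference$atoms))
    stop("frame width does not match reference atom count")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  structure(list(reference = reference, xyz = xyz, dt = dt),
            class = "md_trajectory")
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame as an n x 3 matrix
#' @param traj an `md_trajectory`
#' @param i frame index (1-based)
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= nrow(traj$xyz))
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory: ", nrow(x$xyz), " frames x ",
      nrow(x$reference$atoms), " atoms, dt = ", x$dt, " ps\n", sep = "")
  invisible(x)
}

#' Indices of atoms matching an atom-name selection
#' @noRd
select_atoms <- function(model, selection = "CA") {
  if (is.null(selection)) return(seq_len(nrow(model$atoms)))
  idx <- which(model$atoms$name %in% selection)
  if (!length(idx)) stop("empty atom selection: ", paste(selection, collapse = ","))
  idx
}
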