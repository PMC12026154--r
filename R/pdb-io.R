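# Fixed-column PDB reading and writing, including multi-model files used as
# the canonical text trajectory format.

parse_atom_lines <- function(lines, line_no, keep_hetatm, keep_waters,
                             keep_hydrogens, keep_altloc = "A") {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[is_atom]
  line_no <- line_no[is_atom]
  if (!length(lines)) return(NULL)
  bad <- nchar(lines) < 54
  if (any(bad))
    stop("malformed ATOM record at line ", line_no[which(bad)[1]],
         ": record shorter than coordinate fields")
  num <- function(s) suppressWarnings(as.numeric(s))
  x <- num(substr(lines, 31, 38))
  y <- num(substr(lines, 39, 46))
  z <- num(substr(lines, 47, 54))
  serial <- suppressWarnings(as.integer(substr(lines, 7, 11)))
  res_seq <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(res_seq)
  if (any(bad))
    stop("malformed ATOM record at line ", line_no[which(bad)[1]],
         ": non-numeric coordinate or residue number")
  icode <- trimws(substr(lines, 27, 27))
  if (any(nzchar(icode)))
    stop("insertion codes are not supported (line ",
         line_no[which(nzchar(icode))[1]], "); renumber the file first")
  atoms <- data.frame(
    serial = serial,
    name = trimws(substr(lines, 13, 16)),
    altloc = trimws(substr(lines, 17, 17)),
    res_name = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    res_seq = res_seq,
    x = x, y = y, z = z,
    occupancy = ifelse(is.na(num(substr(lines, 55, 60))), 1,
                       num(substr(lines, 55, 60))),
    b_factor = ifelse(is.na(num(substr(lines, 61, 66))), 0,
                      num(substr(lines, 61, 66))),
    element = trimws(substr(lines, 77, 78)),
    hetatm = substr(lines, 1, 6) == "HETATM",
    stringsAsFactors = FALSE)
  atoms <- atoms[atoms$altloc %in% c("", keep_altloc), ]
  atoms$altloc <- NULL
  if (!keep_waters) atoms <- atoms[!(atoms$res_name %in% .water_resnames), ]
  if (!keep_hetatm)
    atoms <- atoms[!atoms$hetatm | is_standard_resname(atoms$res_name), ]
  atoms$hetatm <- NULL
  el <- atoms$element
  blank <- !nzchar(el)
  el[blank] <- infer_element(atoms$name[blank])
  atoms$element <- el
  if (!keep_hydrogens) atoms <- atoms[atoms$element != "H", ]
  atoms
}

#' Read a protein structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records.  Waters and non-protein HETATM
#' records are dropped by default, as are hydrogens (semi-essential
#' hydrogens are rebuilt by [add_semi_essential_hydrogens()]).  Alternate
#' locations other than blank/'A' are dropped; insertion codes are rejected.
#' For multi-model files only the first model is read (see
#' [read_multimodel_trajectory()] for trajectories).
#'
#' @param path PDB file path.
#' @param keep_hetatm keep non-protein HETATM records.
#' @param keep_waters keep water molecules.
#' @param keep_hydrogens keep hydrogens present in the file.
#' @return a [structure_model()]
#' @export
read_pdb <- function(path, keep_hetatm = FALSE, keep_waters = FALSE,
                     keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ends <- which(substr(lines, 1, 6) %in% c("ENDMDL", "END   ") |
                  trimws(lines) == "END")
  if (length(ends)) lines <- lines[seq_len(ends[1] - 1)]
  atoms <- parse_atom_lines(lines, seq_along(lines), keep_hetatm,
                            keep_waters, keep_hydrogens)
  if (is.null(atoms) || nrow(atoms) == 0)
    stop("no protein atoms found in ", path)
  structure_model(atoms)
}

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL blocks must contain congruent atom sets; the first model
#' becomes the reference structure.
#'
#' @param path multi-model PDB file path.
#' @param dt time step between models, ps.
#' @inheritParams read_pdb
#' @return an [md_trajectory()]
#' @export
read_multimodel_trajectory <- function(path, dt = 1, keep_hetatm = FALSE,
                                       keep_waters = FALSE,
                                       keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 5)
  starts <- which(rec == "MODEL")
  if (!length(starts)) {
    model <- read_pdb(path, keep_hetatm, keep_waters, keep_hydrogens)
    return(md_trajectory(model, matrix(as.numeric(t(coords(model))), nrow = 1),
                         dt = dt))
  }
  ends <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(ends) < length(starts)) ends <- c(ends, length(lines) + 1L)
  frames <- vector("list", length(starts))
  ref_atoms <- NULL
  for (m in seq_along(starts)) {
    block <- seq(starts[m] + 1L, ends[m] - 1L)
    atoms <- parse_atom_lines(lines[block], block, keep_hetatm, keep_waters,
                              keep_hydrogens)
    if (is.null(atoms) || nrow(atoms) == 0)
      stop("model ", m, " contains no protein atoms")
    if (m == 1) {
      ref_atoms <- atoms
    } else {
      if (nrow(atoms) != nrow(ref_atoms))
        stop("atom count mismatch in model ", m, ": ", nrow(atoms),
             " vs ", nrow(ref_atoms), " in model 1")
      if (!all(atoms$name == ref_atoms$name &
                 atoms$res_seq == ref_atoms$res_seq))
        stop("atom identity mismatch in model ", m)
    }
    frames[[m]] <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  }
  md_trajectory(structure_model(ref_atoms), do.call(rbind, frames), dt = dt)
}

format_atom_record <- function(atoms, serial) {
  name <- atoms$name
  # PDB alignment: 1-3 char names start in column 14 unless two-letter element
  pad <- ifelse(nchar(name) >= 4 | nchar(atoms$element) == 2,
                substr(paste0(name, "    "), 1, 4),
                substr(paste0(" ", name, "   "), 1, 4))
  sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, pad, "", atoms$res_name, atoms$chain, atoms$res_seq, "",
          atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$b_factor,
          atoms$element)
}

#' Write a structure model to a PDB file
#'
#' Fixed-column ATOM records with coordinates to three decimals, so a
#' write/read round trip preserves coordinates to 1e-3 Angstrom.
#'
#' @param model a `structure_model`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  lines <- c(format_atom_record(model$atoms, seq_len(nrow(model$atoms))),
             "END")
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write PDB to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj an `md_trajectory`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  at <- traj$reference$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(nrow(traj$xyz))) {
    xyz <- frame_coords(traj, m)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    writeLines(c(sprintf("MODEL %8d", m),
                 format_atom_record(at, seq_len(nrow(at))),
                 "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}
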