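# Semi-essential hydrogen augmentation for hydropathic scoring: polar
# hydrogens (on N/O/S), hydrogens on unsaturated carbons, and hydrogens on
# carbons alpha to a heteroatom.  Placement is by ideal internal geometry
# from the heavy-atom frame, so it is deterministic.

#' Add semi-essential hydrogens to a structure model
#'
#' Adds only the hydrogens relevant to hydropathic scoring: polar hydrogens
#' on N/O/S donors, hydrogens on sp2 (unsaturated) carbons, and hydrogens on
#' carbons alpha to a heteroatom (including the backbone alpha hydrogen).
#' Hydrogens already present are discarded first.  Bond lengths are N-H
#' 1.01, O-H 0.96, S-H 1.34 and C-H 1.09 Angstrom; angles and dihedrals
#' follow ideal sp2/sp3 geometry.  N-terminal amine nitrogens receive three
#' hydrogens.
#'
#' @param model a `structure_model` with complete heavy atoms per residue
#'   template.
#' @return a new `structure_model` including the added hydrogens.
#' @export
add_semi_essential_hydrogens <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms[model$atoms$element != "H", ]
  model <- structure_model(at)
  at <- model$atoms
  xyz <- coords(model)
  adj <- bond_adjacency(model)
  rid <- paste(at$chain, at$res_seq)
  rids <- unique(rid)
  res_label <- function(i) paste0(at$res_name[i], " ", at$chain[i], ":",
                                  at$res_seq[i])

  new_rows <- vector("list", length(rids))
  for (k in seq_along(rids)) {
    idx <- which(rid == rids[k])
    rn <- at$res_name[idx[1]]
    if (!is_standard_resname(rn)) next
    jobs <- list()
    # backbone amide / terminal amine
    ni <- idx[match("N", at$name[idx])]
    if (!is.na(ni) && rn != "PRO") {
      nb <- adj[[ni]]
      if (length(nb) >= 2) jobs[[length(jobs) + 1L]] <- list(ni, 1L, "sp2", "H")
      else jobs[[length(jobs) + 1L]] <- list(ni, 3L, "sp3", NULL)
    }
    # alpha hydrogen(s): CA is alpha to the backbone nitrogen
    cai <- idx[match("CA", at$name[idx])]
    if (!is.na(cai)) {
      n_ha <- if (rn == "GLY") 2L else 1L
      jobs[[length(jobs) + 1L]] <- list(cai, n_ha, "sp3",
                                        if (n_ha == 1L) "HA" else NULL)
    }
    spec <- .side_chain_hydrogens[[rn]]
    if (!is.null(spec)) for (s in spec) {
      pi <- idx[match(s[1], at$name[idx])]
      if (is.na(pi))
        stop("cannot place hydrogens: residue ", res_label(idx[1]),
             " is missing heavy atom ", s[1])
      jobs[[length(jobs) + 1L]] <- list(pi, as.integer(s[2]), s[3], NULL)
    }
    placed <- lapply(jobs, function(j) {
      h_xyz <- place_hydrogens(j[[1]], j[[2]], j[[3]], at, xyz, adj,
                               res_label)
      nm <- if (!is.null(j[[4]]) && j[[2]] == 1L) j[[4]] else
        hydrogen_names(at$name[j[[1]]], j[[2]])
      list(names = nm, xyz = h_xyz)
    })
    if (!length(placed)) next
    hx <- do.call(rbind, lapply(placed, `[[`, "xyz"))
    new_rows[[k]] <- data.frame(
      serial = NA_integer_,
      name = unlist(lapply(placed, `[[`, "names")),
      res_name = rn, chain = at$chain[idx[1]], res_seq = at$res_seq[idx[1]],
      x = hx[, 1], y = hx[, 2], z = hx[, 3],
      occupancy = 1, b_factor = 0, element = "H",
      stringsAsFactors = FALSE)
  }
  hyd <- do.call(rbind, new_rows[!vapply(new_rows, is.null, logical(1))])
  if (is.null(hyd)) return(model)
  # interleave hydrogens after their residue's heavy atoms
  parts <- lapply(rids, function(r) {
    rbind(at[rid == r, c("name", "res_name", "chain", "res_seq", "x", "y",
                         "z", "occupancy", "b_factor", "element")],
          hyd[paste(hyd$chain, hyd$res_seq) == r, c("name", "res_name",
              "chain", "res_seq", "x", "y", "z", "occupancy", "b_factor",
              "element")])
  })
  all_at <- do.call(rbind, parts)
  all_at$serial <- seq_len(nrow(all_at))
  structure_model(all_at)
}

bond_adjacency <- function(model) {
  n <- nrow(model$atoms)
  adj <- vector("list", n)
  b <- model$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
    adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
  }
  adj
}

# Positions for n hydrogens on parent atom index p, from the heavy-atom
# neighbour frame.  Returns an n x 3 matrix.
place_hydrogens <- function(p, n_h, geom, at, xyz, adj, res_label) {
  nb <- sort(adj[[p]])
  nb <- nb[at$element[nb] != "H"]
  d <- .h_bond_length[[at$element[p]]]
  if (is.null(d)) d <- 1.09
  P <- xyz[p, ]
  if (length(nb) >= 3 && n_h == 1L) {
    u <- -vunit(colSums(t(vapply(nb, function(j) vunit(xyz[j, ] - P),
                                 numeric(3)))))
    return(matrix(P + d * u, 1, 3))
  }
  if (length(nb) == 2) {
    u1 <- vunit(xyz[nb[1], ] - P)
    u2 <- vunit(xyz[nb[2], ] - P)
    bis <- -vunit(u1 + u2)
    if (geom == "sp2" && n_h == 1L) return(matrix(P + d * bis, 1, 3))
    if (n_h == 2L) {
      perp <- vunit(vcross(u1, u2))
      half <- 0.5 * 109.47 * pi / 180
      h1 <- P + d * (cos(half) * bis + sin(half) * perp)
      h2 <- P + d * (cos(half) * bis - sin(half) * perp)
      return(rbind(h1, h2))
    }
    if (n_h == 1L) return(matrix(P + d * bis, 1, 3))
  }
  if (length(nb) == 1) {
    y <- nb[1]
    ref <- sort(adj[[y]])
    ref <- ref[ref != p & at$element[ref] != "H"]
    if (!length(ref))
      stop("cannot place hydrogens on ", at$name[p], " of residue ",
           res_label(p), ": no reference atom")
    r <- ref[1]
    ang <- if (geom == "sp2") 120 else 109.47
    dihs <- switch(as.character(n_h),
                   "1" = 180, "2" = if (geom == "sp2") c(0, 180) else c(60, 300),
                   "3" = c(180, 60, -60))
    return(do.call(rbind, lapply(dihs, function(dd)
      place_atom(xyz[r, ], xyz[y, ], P, d, ang, dd))))
  }
  stop("cannot place hydrogens on ", at$name[p], " of residue ",
       res_label(p), ": missing bonded heavy neighbours")
}
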