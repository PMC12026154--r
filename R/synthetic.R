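# Synthetic structures and trajectories with known ground truth.
#
# The toy protein emulates a lipocalin fold at toy scale: strand C-alpha
# traces on a cylinder (the "barrel", side chains pointing into the
# cavity), plus an adjacent ideal alpha-helical trace.  One barrel strand
# is oriented so that a designated helix C-alpha and a strand C-alpha
# differ exactly by `helix_offset` along the barrel-normal; the breathing
# generator displaces the helix along that normal, so the matched pair
# distance is d0 + A*sin(2*pi*t/period) + jitter exactly, with known d0 and
# amplitude.

#' Specification for the toy lipocalin-like fold
#'
#' @param n_strand_res residues per strand (odd counts centre a residue on
#'   the barrel equator, where the matched interface pair sits).
#' @param n_strands number of barrel strands.
#' @param n_helix_res residues in the helix-like segment.
#' @param barrel_radius C-alpha cylinder radius, Angstrom.
#' @param helix_offset resting helix-barrel distance d0, Angstrom: the
#'   exact C-alpha distance of the matched interface pair.
#' @param seed integer seed (the builder itself is deterministic; the seed
#'   is carried for downstream generators).
#' @return object of class `toy_spec`
#' @export
toy_spec <- function(n_strand_res = 9, n_strands = 8, n_helix_res = 13,
                     barrel_radius = 7, helix_offset = 4.25, seed = 1) {
  stopifnot(n_strand_res >= 1, n_strands >= 1, n_helix_res >= 1,
            barrel_radius > 0, helix_offset > 0)
  structure(list(n_strand_res = n_strand_res, n_strands = n_strands,
                 n_helix_res = n_helix_res, barrel_radius = barrel_radius,
                 helix_offset = helix_offset, seed = as.integer(seed)),
            class = "toy_spec")
}

#' Motion parameters for the synthetic trajectory generators
#'
#' @param sigma per-residue isotropic per-coordinate Gaussian amplitude,
#'   Angstrom; scalar (recycled) or one value per residue.
#' @param breathing_amplitude helix displacement amplitude A, Angstrom.
#' @param breathing_period oscillation period, frames.
#' @param n_frames number of frames.
#' @param jitter_sd Gaussian jitter on the breathing displacement,
#'   Angstrom.
#' @param seed integer seed.
#' @return object of class `motion_spec`
#' @export
motion_spec <- function(sigma = 0.5, breathing_amplitude = 1.65,
                        breathing_period = 100, n_frames = 1000,
                        jitter_sd = 0.05, seed = 1) {
  stopifnot(all(sigma >= 0), n_frames >= 2, breathing_period >= 1)
  structure(list(sigma = sigma, breathing_amplitude = breathing_amplitude,
                 breathing_period = breathing_period,
                 n_frames = as.integer(n_frames), jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "motion_spec")
}

# backbone + CB for a segment given its CA trace and per-residue frame
# vectors: ahat (chain direction), phat (in-plane perpendicular used for
# the peptide kink), cbhat (side-chain direction).
segment_atoms <- function(ca, ahat, phat, qhat, cbhat, res_names, chain,
                          seq0) {
  n <- nrow(ca)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    a <- list()
    add <- function(nm, p) a[[length(a) + 1L]] <<- c(list(nm), as.list(p))
    if (i == 1) add("N", ca[i, ] - 1.45 * ahat[i, ])
    else {
      m <- (ca[i - 1, ] + ca[i, ]) / 2
      add("N", m + 0.55 * ahat[i, ] + 0.35 * phat[i, ])
    }
    add("CA", ca[i, ])
    if (i == n) {
      cpos <- ca[i, ] + 1.52 * ahat[i, ]
      add("C", cpos)
      add("O", cpos + 1.23 * qhat[i, ])
    } else {
      m <- (ca[i, ] + ca[i + 1, ]) / 2
      cpos <- m - 0.55 * ahat[i, ] + 0.35 * phat[i, ]
      add("C", cpos)
      add("O", cpos + 1.23 * qhat[i, ])
    }
    if (res_names[i] != "GLY") {
      # tetrahedral CB from the placed backbone; of the two mirror
      # positions take the one facing the intended side-chain direction
      npos <- a[[1]][-1]; npos <- c(npos[[1]], npos[[2]], npos[[3]])
      cb1 <- place_atom(cpos, npos, ca[i, ], 1.53, 110.5, -122.6)
      cb2 <- place_atom(cpos, npos, ca[i, ], 1.53, 110.5, 122.6)
      cb <- if (sum((cb1 - ca[i, ]) * cbhat[i, ]) >=
                  sum((cb2 - ca[i, ]) * cbhat[i, ])) cb1 else cb2
      add("CB", cb)
    }
    df <- do.call(rbind, lapply(a, function(x)
      data.frame(name = x[[1]], x = x[[2]], y = x[[3]], z = x[[4]],
                 stringsAsFactors = FALSE)))
    df$res_name <- res_names[i]
    df$res_seq <- seq0 + i - 1L
    df$chain <- chain
    rows[[i]] <- df
  }
  do.call(rbind, rows)
}

#' Build the toy lipocalin-like structure
#'
#' Backbone (N, CA, C, O) plus CB on ideal internal geometry: antiparallel
#' strand traces on a cylinder (C-alpha spacing 3.4 Angstrom, side chains
#' pointing into the cavity) and an ideal helix trace (rise 1.5 Angstrom,
#' 100 degrees per residue, C-alpha radius 2.3 Angstrom) alongside.  The
#' body is poly-Leu with poly-Ala segment caps; the helix is poly-Ala.
#' The returned model carries a `toy` attribute with the helix residue
#' range, the matched interface C-alpha pair, the barrel-normal direction
#' and d0, used by [make_breathing_trajectory()].
#'
#' @param spec a [toy_spec()].
#' @return a `structure_model` (single chain A, residues numbered from 1).
#' @export
make_toy_protein <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  r_h <- 2.3
  rise <- 1.5
  twist <- 100 * pi / 180
  R <- spec$barrel_radius
  d0 <- spec$helix_offset
  ns <- spec$n_strands
  nr <- spec$n_strand_res
  nh <- spec$n_helix_res

  # helix axis parallel to z at distance x_ax; matched residue k* sits at
  # cylinder-radius R + d0 so its radial barrel partner is exactly d0 away
  x_ax <- R + d0
  k_star <- max(1L, ceiling(nh / 2))
  cos_phi_star <- -r_h / (2 * x_ax)
  phi_star <- acos(max(-1, min(1, cos_phi_star)))
  phis <- phi_star + twist * (seq_len(nh) - k_star)
  helix_z <- rise * (seq_len(nh) - (nh + 1) / 2)
  helix_ca <- cbind(x_ax + r_h * cos(phis), r_h * sin(phis), helix_z)
  p_star <- helix_ca[k_star, ]
  theta_1 <- atan2(p_star[2], p_star[1])   # interface strand angle
  u_norm <- c(cos(theta_1), sin(theta_1), 0)  # barrel-normal direction

  strand_z <- 3.4 * (seq_len(nr) - (nr + 1) / 2)
  m_star <- which.min(abs(strand_z - p_star[3]))
  strand_z <- strand_z - strand_z[m_star] + p_star[3]  # align matched CA z

  res_names_strand <- rep("LEU", nr)
  if (nr >= 2) res_names_strand[c(1, nr)] <- "ALA"
  parts <- list()
  seq0 <- 1L
  for (s in seq_len(ns)) {
    th <- theta_1 + (s - 1) * 2 * pi / ns
    radial <- c(cos(th), sin(th), 0)
    zdir <- if (s %% 2 == 1) 1 else -1       # antiparallel strands
    zs <- if (zdir == 1) strand_z else rev(strand_z)
    ca <- cbind(R * radial[1], R * radial[2], zs)
    n <- nr
    ahat <- matrix(rep(c(0, 0, zdir), n), n, 3, byrow = TRUE)
    phat <- matrix(rep(radial, n), n, 3, byrow = TRUE)
    qhat <- matrix(rep(vcross(c(0, 0, zdir), radial), n), n, 3, byrow = TRUE)
    cbhat <- -phat                            # side chains into the cavity
    parts[[s]] <- segment_atoms(ca, ahat, phat, qhat, cbhat,
                                res_names_strand, "A", seq0)
    seq0 <- seq0 + nr
  }
  helix_seq0 <- seq0
  n <- nh
  ahat <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    ahat[i, ] <- vunit(helix_ca[hi, ] - helix_ca[lo, ])
  }
  radial_h <- t(vapply(seq_len(n), function(i) {
    v <- c(helix_ca[i, 1] - x_ax, helix_ca[i, 2], 0)
    v <- v - sum(v * ahat[i, ]) * ahat[i, ]
    vunit(v)
  }, numeric(3)))
  qhat_h <- t(vapply(seq_len(n), function(i)
    vunit(vcross(ahat[i, ], radial_h[i, ])), numeric(3)))
  # side chains on the solvent face: outward barrel-normal, orthogonalised
  # against the local chain direction so CB clears the backbone
  cb_h <- t(vapply(seq_len(n), function(i) {
    v <- u_norm - sum(u_norm * ahat[i, ]) * ahat[i, ]
    vunit(v)
  }, numeric(3)))
  parts[[ns + 1]] <- segment_atoms(helix_ca, ahat, radial_h, qhat_h,
                                   cb_h, rep("ALA", nh), "A", helix_seq0)
  at <- do.call(rbind, parts)
  at$serial <- seq_len(nrow(at))
  at$element <- infer_element(at$name)
  at$occupancy <- 1; at$b_factor <- 0
  model <- structure_model(at)
  xyz <- coords(model)
  dmin <- min(stats::dist(xyz))
  if (dmin < 1.0)
    stop("geometry clash in toy build: minimum interatomic distance ",
         round(dmin, 2), " A")
  helix_res <- helix_seq0 + k_star - 1L
  barrel_res <- if (m_star <= nr) m_star else NA_integer_  # strand 1 index
  attr(model, "toy") <- list(
    spec = spec,
    helix_seqs = seq(helix_seq0, helix_seq0 + nh - 1L),
    direction = u_norm,
    d0 = d0,
    pair = data.frame(helix_chain = "A", helix_seq = helix_res,
                      barrel_chain = "A", barrel_seq = barrel_res,
                      stringsAsFactors = FALSE))
  model
}

#' Harmonic ground-truth trajectory
#'
#' Frame t = reference + per-residue iid Gaussian displacement (per
#' coordinate sd `sigma` of that residue), the same displacement applied to
#' every atom of the residue, so the per-residue RMSF ground truth is
#' exactly `sigma * sqrt(3)` in the large-sample limit.
#'
#' @param model reference `structure_model`.
#' @param motion a [motion_spec()]; `sigma` scalar or per-residue.
#' @return an `md_trajectory` with a `ground_truth` attribute (per-residue
#'   sigma vector).
#' @export
make_harmonic_trajectory <- function(model, motion = motion_spec()) {
  stopifnot(inherits(model, "structure_model"),
            inherits(motion, "motion_spec"))
  nres <- nrow(model$residues)
  sigma <- rep_len(motion$sigma, nres)
  if (length(motion$sigma) > 1 && length(motion$sigma) != nres)
    stop("sigma vector length must equal residue count (", nres, ")")
  rid <- paste(model$atoms$chain, model$atoms$res_seq)
  res_of_atom <- match(rid, paste(model$residues$chain,
                                  model$residues$res_seq))
  ref <- as.numeric(t(coords(model)))
  nf <- motion$n_frames
  set.seed(motion$seed)
  xyz <- matrix(0, nf, length(ref))
  for (t in seq_len(nf)) {
    disp <- matrix(stats::rnorm(3 * nres, 0, sigma), nres, 3)
    xyz[t, ] <- ref + as.numeric(t(disp[res_of_atom, , drop = FALSE]))
  }
  traj <- md_trajectory(model, xyz, dt = 1)
  attr(traj, "ground_truth") <- list(sigma = sigma)
  traj
}

#' Breathing ground-truth trajectory
#'
#' The helix segment of a [make_toy_protein()] model is rigid-body
#' displaced along the barrel-normal by `A * sin(2*pi*t/period)` plus
#' Gaussian jitter; the barrel stays fixed.  For the matched interface pair
#' the C-alpha distance is exactly `d0 + A*sin(2*pi*t/period) + jitter`, so
#' `D_ave -> d0` and `D_max -> d0 + A`.
#'
#' @param model a `structure_model` built by [make_toy_protein()].
#' @param motion a [motion_spec()] (`breathing_amplitude`,
#'   `breathing_period`, `n_frames`, `jitter_sd`, `seed`).
#' @return an `md_trajectory` with `ground_truth` (d0, A, period,
#'   the matched `pair` data.frame).
#' @export
make_breathing_trajectory <- function(model, motion = motion_spec()) {
  stopifnot(inherits(model, "structure_model"),
            inherits(motion, "motion_spec"))
  toy <- attr(model, "toy")
  if (is.null(toy))
    stop("model must be built by make_toy_protein() (helix segment ",
         "identification is carried as an attribute)")
  at <- model$atoms
  helix_atoms <- which(at$res_seq %in% toy$helix_seqs)
  ref <- coords(model)
  nf <- motion$n_frames
  A <- motion$breathing_amplitude
  set.seed(motion$seed)
  s <- A * sin(2 * pi * (seq_len(nf) - 1) / motion$breathing_period) +
    stats::rnorm(nf, 0, motion$jitter_sd)
  xyz <- matrix(0, nf, 3 * nrow(ref))
  for (t in seq_len(nf)) {
    f <- ref
    f[helix_atoms, ] <- f[helix_atoms, ] +
      matrix(s[t] * toy$direction, length(helix_atoms), 3, byrow = TRUE)
    xyz[t, ] <- as.numeric(t(f))
  }
  traj <- md_trajectory(model, xyz, dt = 1)
  attr(traj, "ground_truth") <- list(d0 = toy$d0, A = A,
                                     period = motion$breathing_period,
                                     pair = toy$pair)
  traj
}

#' Build a free-standing residue fixture
#'
#' Constructs one residue (backbone N, CA, C, O plus side chain from ideal
#' internal coordinates) for use in small synthetic test systems.
#' Supported residues: those with internal-coordinate templates (Ala, Gly,
#' Ser, Cys, Val, Leu, Phe, Tyr).
#'
#' @param res_name 3-letter residue name.
#' @param res_seq,chain residue identity.
#' @param origin position of the CA atom.
#' @param rotation optional 3 x 3 rotation applied about the CA.
#' @return data.frame of atoms; combine with `rbind` and pass to
#'   [structure_model()].
#' @export
build_residue <- function(res_name, res_seq = 1, chain = "A",
                          origin = c(0, 0, 0), rotation = diag(3)) {
  res_name <- toupper(res_name)
  if (!res_name %in% names(.side_chain_zmat))
    stop("no internal-coordinate template for ", res_name,
         "; supported: ", paste(names(.side_chain_zmat), collapse = ", "))
  pos <- list(N = c(-1.45, 0, 0), CA = c(0, 0, 0),
              C = 1.52 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0))
  pos$O <- place_atom(pos$N, pos$CA, pos$C, 1.23, 121, -45)
  if (res_name != "GLY")
    pos$CB <- place_atom(pos$C, pos$N, pos$CA, 1.53, 110.5, -122.6)
  zm <- .side_chain_zmat[[res_name]]
  if (!is.null(zm)) for (e in zm)
    pos[[e[[1]]]] <- place_atom(pos[[e[[2]][1]]], pos[[e[[2]][2]]],
                                pos[[e[[2]][3]]], e[[3]], e[[4]], e[[5]])
  nm <- names(pos)
  xyz <- do.call(rbind, pos) %*% t(rotation)
  xyz <- sweep(xyz, 2, origin, `+`)
  data.frame(serial = seq_along(nm), name = nm,
             res_name = res_name, res_seq = as.integer(res_seq),
             chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, b_factor = 0,
             element = infer_element(nm), stringsAsFactors = FALSE)
}
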