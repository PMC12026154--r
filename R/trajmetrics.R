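# Trajectory-derived structural observables: RMSD series, per-residue RMSF,
# radius of gyration, SASA time series, helix-barrel interface distance and
# essential-dynamics PCA.

traj_selection <- function(traj, selection) {
  sel <- select_atoms(traj$reference, selection)
  cols <- as.numeric(t(outer(sel, 0:2, function(i, k) 3 * (i - 1) + k + 1)))
  list(idx = sel, cols = cols)
}

sel_frame <- function(traj, m, cols) {
  matrix(traj$xyz[m, cols], ncol = 3, byrow = TRUE)
}

#' Per-frame RMSD from a reference frame
#'
#' Each frame is rigidly superposed (Kabsch) on the reference frame over the
#' selection before computing the RMSD.
#'
#' @param traj an `md_trajectory`.
#' @param ref_frame reference frame index (default the first frame).
#' @param selection atom name(s) used, default `"CA"`; `NULL` for all atoms.
#' @param fit superpose before measuring (default TRUE).
#' @return numeric vector of per-frame RMSD, Angstrom.
#' @export
rmsd_series <- function(traj, ref_frame = 1, selection = "CA", fit = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  s <- traj_selection(traj, selection)
  ref <- sel_frame(traj, ref_frame, s$cols)
  vapply(seq_len(n_frames(traj)), function(m) {
    x <- sel_frame(traj, m, s$cols)
    if (fit) kabsch_superpose(x, ref)$rmsd
    else sqrt(mean(rowSums((x - ref)^2)))
  }, numeric(1))
}

#' Per-residue root mean square fluctuation
#'
#' RMSF about the time-average position of each selected atom.  With
#' `fit = TRUE` all frames are first superposed on the average structure
#' (computed after aligning to the first frame, then iterated once).
#'
#' @inheritParams rmsd_series
#' @return object of class `flex_profile`: data.frame with `chain`,
#'   `res_seq`, `res_name`, `rmsf` (Angstrom), and the selection as an
#'   attribute.
#' @export
rmsf_profile <- function(traj, selection = "CA", fit = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  s <- traj_selection(traj, selection)
  nf <- n_frames(traj)
  frames <- lapply(seq_len(nf), function(m) sel_frame(traj, m, s$cols))
  if (fit) {
    ref <- frames[[1]]
    frames <- lapply(frames, function(x) {
      f <- kabsch_superpose(x, ref); apply_transform(x, f)
    })
    avg <- Reduce(`+`, frames) / nf
    frames <- lapply(frames, function(x) {
      f <- kabsch_superpose(x, avg); apply_transform(x, f)
    })
  }
  avg <- Reduce(`+`, frames) / nf
  msf <- Reduce(`+`, lapply(frames, function(x) rowSums((x - avg)^2))) / nf
  at <- traj$reference$atoms[s$idx, ]
  out <- data.frame(chain = at$chain, res_seq = at$res_seq,
                    res_name = at$res_name, rmsf = sqrt(msf),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "selection") <- selection
  class(out) <- c("flex_profile", "data.frame")
  out
}

#' @export
print.flex_profile <- function(x, ...) {
  cat("flex_profile:", nrow(x), "residues, RMSF range [",
      round(min(x$rmsf), 2), ",", round(max(x$rmsf), 2), "] A\n")
  NextMethod()
}

#' @export
plot.flex_profile <- function(x, ...) {
  graphics::plot(x$res_seq, x$rmsf, type = "l", xlab = "Residue",
                 ylab = "RMSF (Å)", ...)
  invisible(x)
}

#' Radius of gyration time series
#'
#' `Rg(t) = sqrt(sum w_i |r_i - rbar|^2 / sum w_i)` with atomic-mass weights
#' by default.
#'
#' @param traj an `md_trajectory`.
#' @param mass_weighted use atomic masses as weights (default) or unit
#'   weights.
#' @param selection atom selection; `NULL` (default) for all atoms.
#' @return numeric vector of per-frame Rg, Angstrom.
#' @export
gyration_series <- function(traj, mass_weighted = TRUE, selection = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  s <- traj_selection(traj, selection)
  w <- if (mass_weighted) {
    m <- .atomic_mass[traj$reference$atoms$element[s$idx]]
    if (any(is.na(m))) stop("no atomic mass for some elements")
    as.numeric(m)
  } else rep(1, length(s$idx))
  w <- w / sum(w)
  vapply(seq_len(n_frames(traj)), function(m) {
    x <- sel_frame(traj, m, s$cols)
    cm <- colSums(x * w)
    sqrt(sum(w * rowSums(sweep(x, 2, cm)^2)))
  }, numeric(1))
}

#' SASA time series
#'
#' Per-frame Shrake-Rupley solvent-accessible surface area of the selection,
#' computed in the whole-protein context.
#'
#' @param traj an `md_trajectory`.
#' @param selection atom names, or `NULL` (default) for total SASA; for a
#'   residue-level series pass `residues` instead.
#' @param residues optional data.frame with `chain`, `res_seq` restricting
#'   the reported area to those residues' atoms.
#' @param params a [hint_params()] (probe radius and lattice size).
#' @return numeric vector of per-frame areas, Angstrom^2.
#' @export
sasa_series <- function(traj, selection = NULL, residues = NULL,
                        params = hint_params()) {
  stopifnot(inherits(traj, "md_trajectory"))
  at <- traj$reference$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(selection)) keep <- at$name %in% selection
  if (!is.null(residues))
    keep <- keep & paste(at$chain, at$res_seq) %in%
      paste(residues$chain, residues$res_seq)
  if (!any(keep)) stop("empty SASA selection")
  vapply(seq_len(n_frames(traj)), function(m) {
    a <- compute_sasa(frame_coords(traj, m), probe_radius = params$probe_radius,
                      n_points = params$sphere_points, elements = at$element)
    sum(a[keep])
  }, numeric(1))
}

#' Helix-barrel interface distance series
#'
#' Aggregated C-alpha pair distance between a helix segment and barrel
#' strands as a function of time, with the trajectory maximum (`D_max`) and
#' average (`D_ave` with SD) reported.
#'
#' @param traj an `md_trajectory`.
#' @param pairs data.frame with columns `helix_chain`, `helix_seq`,
#'   `barrel_chain`, `barrel_seq`: the C-alpha pairs to measure.
#' @param aggregator how to combine pairs per frame: `"mean"` (default) or
#'   `"min"`.
#' @return object of class `helix_barrel_series` with `d` (per-frame,
#'   Angstrom), `D_max`, `D_ave`, `D_sd`, `pairs`.
#' @export
helix_barrel_distance <- function(traj, pairs, aggregator = c("mean", "min")) {
  stopifnot(inherits(traj, "md_trajectory"))
  aggregator <- match.arg(aggregator)
  if (is.null(pairs) || nrow(pairs) == 0) stop("empty pair list")
  at <- traj$reference$atoms
  find_ca <- function(chain, seq) {
    i <- which(at$chain == chain & at$res_seq == seq & at$name == "CA")
    if (!length(i))
      stop("no CA atom for residue ", chain, ":", seq)
    i
  }
  hi <- mapply(find_ca, pairs$helix_chain, pairs$helix_seq)
  bi <- mapply(find_ca, pairs$barrel_chain, pairs$barrel_seq)
  agg <- if (aggregator == "mean") mean else min
  d <- vapply(seq_len(n_frames(traj)), function(m) {
    xyz <- frame_coords(traj, m)
    agg(sqrt(rowSums((xyz[hi, , drop = FALSE] -
                        xyz[bi, , drop = FALSE])^2)))
  }, numeric(1))
  structure(list(d = d, D_max = max(d), D_ave = mean(d),
                 D_sd = stats::sd(d), pairs = pairs,
                 aggregator = aggregator),
            class = "helix_barrel_series")
}

#' @export
print.helix_barrel_series <- function(x, ...) {
  cat(sprintf(
    "helix_barrel_series: %d frames, %d pair(s), D_max = %.2f A, D_ave = %.2f +/- %.2f A\n",
    length(x$d), nrow(x$pairs), x$D_max, x$D_ave,
    ifelse(is.na(x$D_sd), 0, x$D_sd)))
  invisible(x)
}

#' Default helix-barrel C-alpha pairing
#'
#' Pairs each barrel-interface residue with its nearest helix C-alpha in the
#' reference structure.  The interface residue ranges are configuration,
#' not inference: supply the ranges used by the study at hand.
#'
#' @param model reference `structure_model`.
#' @param helix_range data.frame `chain`, `res_seq` of helix residues.
#' @param barrel_range data.frame `chain`, `res_seq` of barrel residues.
#' @return pair data.frame suitable for [helix_barrel_distance()].
#' @export
default_interface_pairs <- function(model, helix_range, barrel_range) {
  at <- model$atoms
  ca <- function(chain, seq) {
    i <- which(at$chain == chain & at$res_seq == seq & at$name == "CA")
    if (!length(i)) stop("no CA for residue ", chain, ":", seq)
    i
  }
  hidx <- mapply(ca, helix_range$chain, helix_range$res_seq)
  xyz <- coords(model)
  out <- lapply(seq_len(nrow(barrel_range)), function(k) {
    b <- ca(barrel_range$chain[k], barrel_range$res_seq[k])
    d2 <- colSums((t(xyz[hidx, , drop = FALSE]) - xyz[b, ])^2)
    j <- which.min(d2)
    data.frame(helix_chain = helix_range$chain[j],
               helix_seq = helix_range$res_seq[j],
               barrel_chain = barrel_range$chain[k],
               barrel_seq = barrel_range$res_seq[k],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Essential-dynamics principal component analysis
#'
#' Eigendecomposition of the 3N x 3N covariance of the selected coordinates
#' over the trajectory, after superposing every frame on the average
#' structure.  The leading components capture large-scale collective
#' motions.
#'
#' @inheritParams rmsd_series
#' @param n_components number of components to report projections for.
#' @param unit `"angstrom"` (default) or `"nm"` for the projections.
#' @return object of class `essential_pca`: `eigenvalues` (descending,
#'   Angstrom^2), `eigenvectors`, `projections` (frames x components),
#'   `ranges` (min/max per component), `explained` (variance fractions).
#' @export
pca_essential <- function(traj, selection = "CA", n_components = 2,
                          fit = TRUE, unit = c("angstrom", "nm")) {
  stopifnot(inherits(traj, "md_trajectory"))
  unit <- match.arg(unit)
  if (n_frames(traj) < 2) stop("PCA needs at least 2 frames")
  s <- traj_selection(traj, selection)
  nf <- n_frames(traj)
  frames <- lapply(seq_len(nf), function(m) sel_frame(traj, m, s$cols))
  if (fit) {
    ref <- frames[[1]]
    frames <- lapply(frames, function(x)
      apply_transform(x, kabsch_superpose(x, ref)))
    avg <- Reduce(`+`, frames) / nf
    frames <- lapply(frames, function(x)
      apply_transform(x, kabsch_superpose(x, avg)))
  }
  X <- do.call(rbind, lapply(frames, function(x) as.numeric(t(x))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc) / nf
  ev <- eigen(cv, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  k <- min(n_components, ncol(Xc))
  proj <- Xc %*% ev$vectors[, seq_len(k), drop = FALSE]
  scale <- if (unit == "nm") 0.1 else 1
  proj <- proj * scale
  ranges <- apply(proj, 2, range)
  dimnames(ranges) <- list(c("min", "max"), paste0("PC", seq_len(k)))
  structure(list(eigenvalues = vals, eigenvectors = ev$vectors,
                 projections = proj, ranges = ranges,
                 explained = vals / sum(vals), unit = unit,
                 selection = selection),
            class = "essential_pca")
}

#' @export
print.essential_pca <- function(x, ...) {
  k <- ncol(x$projections)
  cat("essential_pca:", length(x$eigenvalues), "modes;",
      "explained variance PC1..PC", k, ": ",
      paste(sprintf("%.1f%%", 100 * x$explained[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  cat("projection ranges (", x$unit, "):\n", sep = "")
  print(round(x$ranges, 3))
  invisible(x)
}

#' @export
plot.essential_pca <- function(x, ...) {
  graphics::plot(x$projections[, 1], x$projections[, 2],
                 xlab = paste0("PC1 (", x$unit, ")"),
                 ylab = paste0("PC2 (", x$unit, ")"), pch = 20,
                 col = grDevices::adjustcolor("steelblue", 0.6), ...)
  invisible(x)
}
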