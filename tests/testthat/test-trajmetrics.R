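test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(7)
  x <- matrix(rnorm(45), ncol = 3)
  f <- kabsch_superpose(x, x)
  expect_equal(f$rmsd, 0, tolerance = 1e-12)
  expect_equal(f$rotation, diag(3), tolerance = 1e-9)
  rot <- random_rotation()
  y <- sweep(x %*% t(rot), 2, c(3, -2, 8), `+`)
  f2 <- kabsch_superpose(y, x)
  expect_lt(f2$rmsd, 1e-9)
  expect_equal(det(f2$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "at least 3")
  col <- cbind(1:5, 1:5, 1:5)
  expect_error(kabsch_superpose(col, col), "degenerate|collinear")
})

test_that("Kabsch RMSD matches a brute-force numerical minimisation", {
  set.seed(17)
  x <- matrix(rnorm(12), ncol = 3)
  y <- x
  y[4, ] <- y[4, ] + c(1, 0, 0)
  target <- kabsch_superpose(x, y)$rmsd
  # independent oracle: minimise over rotation (Euler angles) + translation
  obj <- function(p) {
    ca <- cos(p[1]); sa <- sin(p[1])
    cb <- cos(p[2]); sb <- sin(p[2])
    cg <- cos(p[3]); sg <- sin(p[3])
    rz <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cg, -sg, 0, sg, cg), 3, byrow = TRUE)
    xt <- sweep(x %*% t(rz %*% ry %*% rx), 2, p[4:6], `+`)
    sqrt(mean(rowSums((xt - y)^2)))
  }
  best <- Inf
  for (s in 1:8) {
    o <- stats::optim(c(runif(3, -pi, pi), rnorm(3)), obj,
                      method = "BFGS", control = list(maxit = 500))
    best <- min(best, o$value)
  }
  expect_equal(target, best, tolerance = 1e-5)
})

test_that("superposition agrees with an independent implementation", {
  set.seed(29)
  x <- matrix(rnorm(30), ncol = 3)
  y <- x + matrix(rnorm(30, sd = 0.3), ncol = 3)
  ours <- kabsch_superpose(x, y)$rmsd
  theirs <- bio3d::rmsd(as.numeric(t(y)), as.numeric(t(x)), fit = TRUE)
  expect_lt(abs(ours - theirs), 1e-3)   # reference rounds to 3 decimals
})

test_that("RMSD series: rigid motion gives zero, point shifts the closed form", {
  model <- make_toy_protein(small_toy())
  ref <- as.numeric(t(coords(model)))
  rot <- random_rotation()
  rigid <- as.numeric(t(sweep(coords(model) %*% t(rot), 2, c(1, 2, 3), `+`)))
  tr <- md_trajectory(model, rbind(ref, rigid))
  expect_lt(max(rmsd_series(tr, selection = NULL)), 1e-9)
  n_ca <- sum(model$atoms$name == "CA")
  shifted <- ref
  ca1 <- which(model$atoms$name == "CA")[1]
  shifted[3 * (ca1 - 1) + 1] <- shifted[3 * (ca1 - 1) + 1] + 1
  tr2 <- md_trajectory(model, rbind(ref, shifted))
  expect_equal(rmsd_series(tr2, fit = FALSE)[2], 1 / sqrt(n_ca),
               tolerance = 1e-12)
})

test_that("RMSF recovers the harmonic generator sigma at 5% accuracy", {
  model <- make_toy_protein(small_toy())
  nres <- nrow(model$residues)
  sig <- rep(c(0.5, 1.0), length.out = nres)
  tr <- make_harmonic_trajectory(model, motion_spec(sigma = sig,
                                                    n_frames = 2000,
                                                    seed = 42))
  prof <- rmsf_profile(tr, fit = FALSE)
  expect_equal(nrow(prof), nres)
  rel <- abs(prof$rmsf - sig * sqrt(3)) / (sig * sqrt(3))
  expect_lt(max(rel), 0.05)
  # sigma ratio of 2 shows up as an RMSF ratio of 2
  r1 <- mean(prof$rmsf[sig == 1.0]) / mean(prof$rmsf[sig == 0.5])
  expect_equal(r1, 2, tolerance = 0.05)
  # static trajectory: all zero
  tr0 <- make_harmonic_trajectory(model, motion_spec(sigma = 0,
                                                     n_frames = 5, seed = 1))
  expect_equal(max(rmsf_profile(tr0, fit = FALSE)$rmsf), 0)
  expect_error(rmsf_profile(md_trajectory(model, tr$xyz[1, , drop = FALSE])),
               "2 frames")
})

test_that("RMSF agrees with an independent trajectory-analysis implementation", {
  model <- make_toy_protein(small_toy())
  tr <- make_harmonic_trajectory(model, motion_spec(sigma = 0.4,
                                                    n_frames = 200,
                                                    seed = 5))
  prof <- rmsf_profile(tr, fit = FALSE)
  sel <- which(model$atoms$name == "CA")
  cols <- as.numeric(t(outer(sel, 0:2, function(i, k) 3 * (i - 1) + k + 1)))
  theirs <- bio3d::rmsf(tr$xyz[, cols])
  # the reference uses the n-1 variance denominator; ours uses n
  nf <- n_frames(tr)
  expect_equal(prof$rmsf, theirs * sqrt((nf - 1) / nf), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("gyration series has the closed forms and scaling law", {
  cube <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  at <- data.frame(serial = 1:8, name = "CA", res_name = "GLY",
                   res_seq = 1:8, chain = "A", x = cube$x, y = cube$y,
                   z = cube$z, element = "C")
  m <- structure_model(at)
  ref <- as.numeric(t(coords(m)))
  tr <- md_trajectory(m, rbind(ref, 3 * ref))
  rg <- gyration_series(tr, mass_weighted = FALSE)
  expect_equal(rg[1], sqrt(3), tolerance = 1e-12)
  expect_equal(rg[2] / rg[1], 3, tolerance = 1e-12)
  # homoatomic system: mass weighting is a no-op
  expect_equal(gyration_series(tr), rg, tolerance = 1e-12)
  # collapsed to a point
  tr0 <- md_trajectory(m, matrix(rep(c(2, -1, 5), 8), nrow = 1))
  expect_equal(gyration_series(tr0)[1], 0)
})

test_that("SASA series is constant for rigid motion and matches compute_sasa", {
  model <- make_toy_protein(toy_spec(n_strand_res = 3, n_strands = 4,
                                     n_helix_res = 4))
  ref <- as.numeric(t(coords(model)))
  rot <- random_rotation()
  moved <- as.numeric(t(sweep(coords(model) %*% t(rot), 2, c(5, 5, 5), `+`)))
  tr <- md_trajectory(model, rbind(ref, moved))
  s <- sasa_series(tr)
  expect_equal(s[1], s[2], tolerance = 1e-9)
  expect_equal(s[1], sum(compute_sasa(model)), tolerance = 1e-12)
})

test_that("helix-barrel distance: static pairs, aggregation, breathing truth", {
  model <- make_toy_protein(small_toy())
  info <- attr(model, "toy")
  ref <- as.numeric(t(coords(model)))
  tr <- md_trajectory(model, rbind(ref, ref, ref))
  hb <- helix_barrel_distance(tr, info$pair)
  expect_equal(hb$D_max, hb$D_ave)
  expect_equal(hb$D_ave, info$d0, tolerance = 1e-9)
  # two pairs at constant distances average to their mean
  p2 <- rbind(info$pair, info$pair)
  hb2 <- helix_barrel_distance(tr, p2)
  expect_equal(hb2$d, hb$d)
  expect_error(helix_barrel_distance(tr, info$pair[0, ]), "empty")
  bad <- info$pair
  bad$barrel_seq <- 9999
  expect_error(helix_barrel_distance(tr, bad), "9999")
})

test_that("PCA: single collective mode explains everything, centred projections", {
  set.seed(13)
  model <- make_toy_protein(small_toy())
  sel <- which(model$atoms$name == "CA")
  mca <- structure_model(model$atoms[sel, ])
  n3 <- 3 * length(sel)
  x0 <- coords(mca)
  x0c <- sweep(x0, 2, colMeans(x0))
  # collective vector orthogonal to rigid translations and rotations
  basis <- cbind(rep(c(1, 0, 0), length(sel)), rep(c(0, 1, 0), length(sel)),
                 rep(c(0, 0, 1), length(sel)),
                 as.numeric(t(cbind(0, -x0c[, 3], x0c[, 2]))),
                 as.numeric(t(cbind(x0c[, 3], 0, -x0c[, 1]))),
                 as.numeric(t(cbind(-x0c[, 2], x0c[, 1], 0))))
  q <- qr.Q(qr(basis))
  v <- rnorm(n3)
  v <- v - q %*% (t(q) %*% v)
  v <- v / sqrt(sum(v^2))
  amp <- rnorm(400)
  ref <- as.numeric(t(x0))
  frames <- t(vapply(amp, function(a) ref + a * v, numeric(n3)))
  pc <- pca_essential(md_trajectory(mca, frames))
  expect_gte(pc$explained[1], 0.99)
  expect_lt(max(abs(colMeans(pc$projections))), 1e-9)
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))
  expect_true(all(pc$eigenvalues >= 0))
  # nm toggle scales projections by 0.1
  pc_nm <- pca_essential(md_trajectory(mca, frames), unit = "nm")
  expect_equal(pc_nm$projections[, 1], 0.1 * pc$projections[, 1],
               tolerance = 1e-12)
})

test_that("PCA of isotropic noise has a flat leading spectrum", {
  set.seed(3)
  at <- data.frame(serial = 1:10, name = "CA", res_name = "GLY",
                   res_seq = 1:10, chain = "A",
                   x = rnorm(10, sd = 8), y = rnorm(10, sd = 8),
                   z = rnorm(10, sd = 8), element = "C")
  m <- structure_model(at)
  ref <- as.numeric(t(coords(m)))
  frames <- t(replicate(5000, ref + rnorm(30, sd = 0.3)))
  pc <- pca_essential(md_trajectory(m, frames), fit = FALSE)
  expect_lt(pc$eigenvalues[1] / pc$eigenvalues[5], 1.25)
})

test_that("metrics are invariant when a global rigid motion hits every frame", {
  model <- make_toy_protein(small_toy())
  tr <- make_harmonic_trajectory(model, motion_spec(sigma = 0.3,
                                                    n_frames = 40, seed = 8))
  rot <- random_rotation()
  moved <- t(apply(tr$xyz, 1, function(fr) {
    x <- matrix(fr, ncol = 3, byrow = TRUE)
    as.numeric(t(sweep(x %*% t(rot), 2, c(9, -4, 2), `+`)))
  }))
  tr2 <- md_trajectory(model, moved)
  expect_equal(rmsd_series(tr2), rmsd_series(tr), tolerance = 1e-6)
  expect_equal(rmsf_profile(tr2)$rmsf, rmsf_profile(tr)$rmsf,
               tolerance = 1e-6)
  expect_equal(gyration_series(tr2), gyration_series(tr), tolerance = 1e-6)
  p1 <- pca_essential(tr)
  p2 <- pca_essential(tr2)
  expect_equal(p2$eigenvalues[1:5], p1$eigenvalues[1:5], tolerance = 1e-6)
})
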