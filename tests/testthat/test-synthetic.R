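test_that("toy build is deterministic and satisfies structure invariants", {
  m1 <- make_toy_protein()
  m2 <- make_toy_protein()
  expect_identical(coords(m1), coords(m2))
  expect_silent(validate_structure(m1))
  expect_gte(min(stats::dist(coords(m1))), 1.0)
  # every residue has N, CA, C, O; non-Gly have CB
  at <- m1$atoms
  for (r in unique(at$res_seq)) {
    nm <- at$name[at$res_seq == r]
    expect_true(all(c("N", "CA", "C", "O", "CB") %in% nm))
  }
})

test_that("the matched interface pair sits exactly at helix_offset", {
  for (d0 in c(3.5, 4.25, 6)) {
    m <- make_toy_protein(toy_spec(helix_offset = d0))
    info <- attr(m, "toy")
    xyz <- coords(m)
    at <- m$atoms
    h <- xyz[at$res_seq == info$pair$helix_seq & at$name == "CA", ]
    b <- xyz[at$res_seq == info$pair$barrel_seq & at$name == "CA", ]
    expect_equal(sqrt(sum((h - b)^2)), d0, tolerance = 1e-9)
  }
})

test_that("helix centroid sits near helix_offset from the nearest strand", {
  spec <- toy_spec()
  m <- make_toy_protein(spec)
  at <- m$atoms
  xyz <- coords(m)
  info <- attr(m, "toy")
  hcen <- colMeans(xyz[at$res_seq %in% info$helix_seqs & at$name == "CA", ])
  strand_ids <- split(seq_len(spec$n_strands * spec$n_strand_res),
                      rep(seq_len(spec$n_strands), each = spec$n_strand_res))
  cen <- vapply(strand_ids, function(rs)
    colMeans(xyz[at$res_seq %in% rs & at$name == "CA", , drop = FALSE]),
    numeric(3))
  d <- min(apply(cen, 2, function(v) sqrt(sum((hcen - v)^2))))
  expect_equal(d, spec$helix_offset, tolerance = 0.5 / spec$helix_offset)
})

test_that("harmonic generator: zero sigma is static, doubling sigma doubles RMSF", {
  m <- make_toy_protein(small_toy())
  t0 <- make_harmonic_trajectory(m, motion_spec(sigma = 0, n_frames = 4,
                                                seed = 2))
  expect_equal(max(abs(sweep(t0$xyz, 2, t0$xyz[1, ]))), 0)
  tr1 <- make_harmonic_trajectory(m, motion_spec(sigma = 0.4,
                                                 n_frames = 1500, seed = 3))
  tr2 <- make_harmonic_trajectory(m, motion_spec(sigma = 0.8,
                                                 n_frames = 1500, seed = 4))
  r1 <- rmsf_profile(tr1, fit = FALSE)$rmsf
  r2 <- rmsf_profile(tr2, fit = FALSE)$rmsf
  expect_equal(mean(r2 / r1), 2, tolerance = 0.05)
  # same seed reproduces frames exactly; different seed does not
  tr1b <- make_harmonic_trajectory(m, motion_spec(sigma = 0.4,
                                                  n_frames = 1500, seed = 3))
  expect_identical(tr1$xyz, tr1b$xyz)
  tr1c <- make_harmonic_trajectory(m, motion_spec(sigma = 0.4,
                                                  n_frames = 1500, seed = 99))
  expect_false(identical(tr1$xyz, tr1c$xyz))
  # parameter recovery unaffected by the seed beyond tolerance
  r1c <- rmsf_profile(tr1c, fit = FALSE)$rmsf
  expect_equal(mean(r1c), mean(r1), tolerance = 0.05)
})

test_that("breathing generator: amplitude zero keeps the distance at d0", {
  m <- make_toy_protein()
  info <- attr(m, "toy")
  tr <- make_breathing_trajectory(m, motion_spec(breathing_amplitude = 0,
                                                 jitter_sd = 0,
                                                 n_frames = 10, seed = 5))
  hb <- helix_barrel_distance(tr, info$pair)
  expect_equal(hb$d, rep(info$d0, 10), tolerance = 1e-9)
})

test_that("breathing recovery: D_ave near d0, D_max near d0 + A", {
  m <- make_toy_protein()
  info <- attr(m, "toy")
  mo <- motion_spec(breathing_amplitude = 1.65, breathing_period = 100,
                    n_frames = 1000, jitter_sd = 0.05, seed = 6)
  tr <- make_breathing_trajectory(m, mo)
  hb <- helix_barrel_distance(tr, info$pair)
  sem <- hb$D_sd / sqrt(length(hb$d))
  expect_lt(abs(hb$D_ave - info$d0), 3 * sem)
  expect_equal(hb$D_max, info$d0 + 1.65, tolerance = 0.2 / 5.9)
  # undersampled period can only underestimate the peak
  mo2 <- motion_spec(breathing_amplitude = 1.65, breathing_period = 64,
                     n_frames = 20, jitter_sd = 0, seed = 7)
  hb2 <- helix_barrel_distance(make_breathing_trajectory(m, mo2), info$pair)
  expect_lte(hb2$D_max, info$d0 + 1.65 + 1e-9)
})

test_that("generated trajectories round-trip losslessly through PDB text", {
  m <- make_toy_protein(small_toy())
  tr <- make_breathing_trajectory(m, motion_spec(n_frames = 6, seed = 8))
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, tf)
  back <- read_multimodel_trajectory(tf)
  expect_lt(max(abs(back$xyz - tr$xyz)), 1e-3)
})

test_that("breathing generator refuses models without helix bookkeeping", {
  plain <- structure_model(make_toy_protein(small_toy())$atoms)
  expect_error(make_breathing_trajectory(plain, motion_spec()),
               "make_toy_protein")
})

test_that("invalid specifications are rejected", {
  expect_error(toy_spec(n_strands = 0), "not >= 1|>= 1")
  expect_error(toy_spec(helix_offset = -1))
  expect_error(motion_spec(n_frames = 1))
  expect_error(motion_spec(sigma = -0.1))
  m <- make_toy_protein(small_toy())
  expect_error(make_harmonic_trajectory(
    m, motion_spec(sigma = c(0.1, 0.2))), "residue count")
})
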