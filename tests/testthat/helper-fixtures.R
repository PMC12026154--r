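# Shared fixtures and independent oracles.

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# small multi-residue system from the internal-coordinate builder
random_residue_system <- function(n_res = 2,
                                  pool = c("ALA", "GLY", "SER", "CYS",
                                           "LEU", "VAL", "PHE", "TYR")) {
  resn <- sample(pool, n_res, replace = TRUE)
  parts <- lapply(seq_len(n_res), function(k)
    build_residue(resn[k], res_seq = k,
                  origin = stats::runif(3, -1, 1) * 4 + c(7 * (k - 1), 0, 0),
                  rotation = random_rotation()))
  structure_model(do.call(rbind, parts))
}

# two Leu residues with side chains facing each other across a small gap
two_leu_fixture <- function(second = "LEU", gap = 7) {
  l1 <- build_residue("LEU", 1)
  flip <- diag(c(-1, -1, 1))
  l2 <- build_residue(second, 2, origin = c(gap, 0, 0), rotation = flip)
  structure_model(rbind(l1, l2))
}

# Independent brute-force total hydropathic score: triple loop over all
# atom pairs, bond-graph distances via adjacency-matrix powers (a different
# algorithm than the engine's BFS exclusion).
brute_force_hint <- function(assign) {
  model <- assign$model
  p <- assign$params
  xyz <- coords(model)
  n <- nrow(xyz)
  adj <- matrix(FALSE, n, n)
  b <- model$bonds
  for (k in seq_len(nrow(b))) {
    adj[b[k, 1], b[k, 2]] <- TRUE
    adj[b[k, 2], b[k, 1]] <- TRUE
  }
  near <- diag(TRUE, n)
  cur <- adj
  for (d in seq_len(p$exclusion_bond_depth)) {
    near <- near | cur
    cur <- (cur %*% adj) > 0
  }
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r > p$cutoff || near[i, j]) next
    cls <- c(assign$class[i], assign$class[j])
    tsign <- if (all(cls == "acid") || all(cls == "base")) -1 else 1
    total <- total + assign$S[i] * assign$a[i] * assign$S[j] *
      assign$a[j] * exp(-r / p$delta) * tsign
  }
  total
}

# small toy spec for fast trajectory tests
small_toy <- function() toy_spec(n_strand_res = 5, n_strands = 6,
                                 n_helix_res = 7)
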