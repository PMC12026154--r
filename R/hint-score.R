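# Intramolecular hydropathic interaction scoring.
#
# Pairwise score over all non-covalently-linked atom pairs:
#   b_ij = S_i a_i S_j a_j R_ij T_ij,   R_ij = exp(-r_ij / delta)
# with S the per-atom solvent-accessible surface area, a the hydrophobic
# atom constant and T_ij a logic sign that is -1 for like-charged
# (acid-acid, base-base) pairs, so Coulombic repulsion enters the total as
# an unfavourable contribution, and +1 otherwise.  Pairs within bond-graph
# distance <= exclusion_bond_depth or beyond the distance cutoff are
# excluded.  The total is B = sum over admissible pairs (i < j).

.hint_classes <- c("hydrogen-bond", "electrostatic-favorable", "hydrophobic",
                   "electrostatic-unfavorable", "desolvation")

#' Assign hydropathic constants and solvent accessibility to every atom
#'
#' Looks up each atom's hydrophobic constant `a`, polarity class and
#' hydrogen-bond role in the parameter table (neutral-pH ionisation:
#' Asp/Glu side-chain oxygens acid, Lys/Arg nitrogens base, His neutral)
#' and computes per-atom Shrake-Rupley solvent accessibility `S` on the
#' whole model.
#'
#' @param model a `structure_model`, normally after
#'   [add_semi_essential_hydrogens()].
#' @param params a [hint_params()] object.
#' @return object of class `hint_assignment` carrying the model, per-atom
#'   `a`, `S` (Angstrom^2), `class` and `role`.
#' @export
assign_hydropathy <- function(model, params = hint_params()) {
  stopifnot(inherits(model, "structure_model"),
            inherits(params, "hint_params"))
  at <- model$atoms
  tab <- params$table
  key <- paste(tab$res_name, tab$atom_name)
  hit <- match(paste(at$res_name, at$name), key)
  if (anyNA(hit)) {
    missing <- unique(paste0(at$res_name[is.na(hit)], ":",
                             at$name[is.na(hit)]))
    stop("no hydropathic parameters for atom(s): ",
         paste(missing, collapse = ", "))
  }
  S <- compute_sasa(model, probe_radius = params$probe_radius,
                    n_points = params$sphere_points)
  structure(list(model = model, params = params,
                 a = tab$a[hit], S = S,
                 class = tab$class[hit], role = tab$role[hit]),
            class = "hint_assignment")
}

#' @export
print.hint_assignment <- function(x, ...) {
  cat("hint_assignment: ", length(x$a), " atoms, total SASA ",
      round(sum(x$S), 1), " A^2\n", sep = "")
  invisible(x)
}

# Pairs (i, j) within bond-graph distance <= depth, as a 2-column matrix.
excluded_pairs <- function(model, depth = 3) {
  adj <- bond_adjacency(model)
  n <- length(adj)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    seen <- i
    frontier <- i
    for (d in seq_len(depth)) {
      frontier <- unique(unlist(adj[frontier]))
      frontier <- setdiff(frontier, seen)
      if (!length(frontier)) break
      seen <- c(seen, frontier)
    }
    reach <- seen[seen > i]
    if (length(reach)) out[[i]] <- cbind(i, reach)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) matrix(integer(0), ncol = 2) else res
}

# Hydrogen-bond test for candidate pairs: a polar hydrogen bonded to the
# donor lies within hb_dist of the acceptor with donor-H-acceptor angle >=
# hb_angle.  Handles both heavy-heavy (donor, acceptor) pairs and pairs
# where atom i itself is the polar hydrogen.
hbond_flags <- function(assign, pi, pj) {
  model <- assign$model
  at <- model$atoms
  xyz <- coords(model)
  params <- assign$params
  adj <- bond_adjacency(model)
  role <- assign$role
  is_h <- at$element == "H"
  parent <- rep(NA_integer_, nrow(at))
  for (h in which(is_h)) {
    nb <- adj[[h]]
    nb <- nb[at$element[nb] != "H"]
    if (length(nb)) parent[h] <- nb[1]
  }
  polar_h <- is_h & !is.na(parent) &
    at$element[ifelse(is.na(parent), 1L, parent)] %in% c("N", "O", "S") &
    role[ifelse(is.na(parent), 1L, parent)] %in% c("donor", "both")
  donors <- which(role %in% c("donor", "both"))
  children <- lapply(seq_len(nrow(at)), function(i) integer(0))
  for (h in which(polar_h)) children[[parent[h]]] <-
    c(children[[parent[h]]], h)

  geom_ok <- function(d, h, a) {
    if (sqrt(sum((xyz[h, ] - xyz[a, ])^2)) > params$hb_dist) return(FALSE)
    bond_angle(xyz[d, ], xyz[h, ], xyz[a, ]) >= params$hb_angle
  }
  test_one <- function(i, j) {
    # orient so that x is (donor or polar H) and y is acceptor
    for (ord in list(c(i, j), c(j, i))) {
      x <- ord[1]; y <- ord[2]
      if (!(role[y] %in% c("acceptor", "both"))) next
      if (polar_h[x]) {
        if (parent[x] != y && geom_ok(parent[x], x, y)) return(TRUE)
      } else if (role[x] %in% c("donor", "both")) {
        for (h in children[[x]]) if (geom_ok(x, h, y)) return(TRUE)
      }
    }
    FALSE
  }
  mapply(test_one, pi, pj)
}

classify_pairs <- function(assign, pi, pj, r) {
  cls <- assign$class
  ci <- cls[pi]; cj <- cls[pj]
  klass <- rep("electrostatic-favorable", length(pi))
  both_hyd <- ci == "hydrophobic" & cj == "hydrophobic"
  one_hyd <- xor(ci == "hydrophobic", cj == "hydrophobic")
  like_charge <- (ci == "acid" & cj == "acid") | (ci == "base" & cj == "base")
  klass[both_hyd] <- "hydrophobic"
  klass[one_hyd] <- "desolvation"
  klass[like_charge] <- "electrostatic-unfavorable"
  # geometric hydrogen-bond test only where a donor-H...acceptor contact is
  # possible at all: donor-acceptor distance <= hb_dist + X-H bond length
  cand <- which(!both_hyd & !like_charge &
                  r <= assign$params$hb_dist + 1.5)
  if (length(cand)) {
    hb <- hbond_flags(assign, pi[cand], pj[cand])
    klass[cand][hb] <- "hydrogen-bond"
  }
  list(klass = klass, like_charge = like_charge)
}

# All admissible pairs with scores; core of hint_total / pair_score.
score_all_pairs <- function(assign) {
  model <- assign$model
  params <- assign$params
  xyz <- coords(model)
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  keep <- which(upper.tri(d) & d <= params$cutoff, arr.ind = TRUE)
  if (nrow(keep)) {
    excl <- excluded_pairs(model, params$exclusion_bond_depth)
    if (nrow(excl)) {
      bad <- paste(keep[, 1], keep[, 2]) %in% paste(excl[, 1], excl[, 2])
      keep <- keep[!bad, , drop = FALSE]
    }
  }
  pi <- keep[, 1]; pj <- keep[, 2]
  r <- d[keep]
  cl <- classify_pairs(assign, pi, pj, r)
  tsign <- ifelse(cl$like_charge, -1, 1)
  b <- assign$S[pi] * assign$a[pi] * assign$S[pj] * assign$a[pj] *
    exp(-r / params$delta) * tsign
  data.frame(i = pi, j = pj, r = r, b = b, klass = cl$klass,
             stringsAsFactors = FALSE)
}

#' Score a single atom pair
#'
#' @param assign a [assign_hydropathy()] result.
#' @param i,j atom indices into the model's atom table.
#' @return one-row data.frame with `r` (Angstrom), `b` (dimensionless) and
#'   interaction `klass`.  Requesting an excluded pair (covalently linked
#'   within the exclusion depth, or beyond the cutoff) is an error.
#' @export
pair_score <- function(assign, i, j) {
  stopifnot(inherits(assign, "hint_assignment"))
  params <- assign$params
  xyz <- coords(assign$model)
  if (i == j) stop("i and j must differ")
  lo <- min(i, j); hi <- max(i, j)
  r <- sqrt(sum((xyz[lo, ] - xyz[hi, ])^2))
  if (r > params$cutoff)
    stop("pair (", i, ",", j, ") beyond cutoff: r = ", round(r, 2), " A")
  excl <- excluded_pairs(assign$model, params$exclusion_bond_depth)
  if (nrow(excl) && any(excl[, 1] == lo & excl[, 2] == hi))
    stop("pair (", i, ",", j, ") is excluded: within covalent bond depth ",
         params$exclusion_bond_depth)
  cl <- classify_pairs(assign, lo, hi, r)
  b <- assign$S[lo] * assign$a[lo] * assign$S[hi] * assign$a[hi] *
    exp(-r / params$delta) * ifelse(cl$like_charge, -1, 1)
  data.frame(i = lo, j = hi, r = r, b = b, klass = cl$klass,
             stringsAsFactors = FALSE)
}

#' Total intramolecular hydropathic score
#'
#' Scores every admissible atom pair once (i < j) and aggregates the total
#' `B`, its decomposition into hydrogen-bond, electrostatic-favorable,
#' hydrophobic, electrostatic-unfavorable and desolvation components, and
#' per-residue totals (each pair contributes half to each partner residue).
#'
#' @param model a `structure_model`; semi-essential hydrogens are added
#'   automatically if absent.
#' @param params a [hint_params()] object.
#' @param report_threshold only pair records with `|b|` at or above this
#'   value are kept in the `records` table (the totals always include all
#'   pairs).
#' @return object of class `hint_score_table` with elements `total_B`,
#'   `components`, `per_residue`, `records`, `assignment`.
#' @export
hint_total <- function(model, params = hint_params(), report_threshold = 0) {
  stopifnot(inherits(model, "structure_model"))
  if (!any(model$atoms$element == "H"))
    model <- add_semi_essential_hydrogens(model)
  assign <- assign_hydropathy(model, params)
  pairs <- score_all_pairs(assign)
  comp <- vapply(.hint_classes,
                 function(k) sum(pairs$b[pairs$klass == k]), numeric(1))
  at <- model$atoms
  rid <- paste(at$chain, at$res_seq)
  rids <- unique(rid)
  half <- c(pairs$b / 2, pairs$b / 2)
  res_of <- c(match(rid[pairs$i], rids), match(rid[pairs$j], rids))
  kl <- c(pairs$klass, pairs$klass)
  per_res <- data.frame(chain = at$chain[!duplicated(rid)],
                        res_seq = at$res_seq[!duplicated(rid)],
                        res_name = at$res_name[!duplicated(rid)],
                        total = 0, stringsAsFactors = FALSE)
  tot <- tapply(half, factor(res_of, levels = seq_along(rids)), sum)
  per_res$total <- ifelse(is.na(tot), 0, as.numeric(tot))
  for (k in .hint_classes) {
    v <- tapply(half * (kl == k), factor(res_of, levels = seq_along(rids)),
                sum)
    per_res[[k]] <- ifelse(is.na(v), 0, as.numeric(v))
  }
  rec <- pairs[abs(pairs$b) >= report_threshold, , drop = FALSE]
  rec$atom_i <- paste0(at$res_name[rec$i], at$res_seq[rec$i], ":",
                       at$name[rec$i])
  rec$atom_j <- paste0(at$res_name[rec$j], at$res_seq[rec$j], ":",
                       at$name[rec$j])
  structure(list(total_B = sum(pairs$b), components = comp,
                 per_residue = per_res, records = rec,
                 n_pairs = nrow(pairs), assignment = assign),
            class = "hint_score_table")
}

#' @export
print.hint_score_table <- function(x, digits = 2, ...) {
  cat("hint_score_table: B =", format(x$total_B, digits = 6), "over",
      x$n_pairs, "atom pairs\n")
  comp <- round(x$components, digits)
  for (k in names(comp)) cat(sprintf("  %-26s %12.*f\n", k, digits, comp[k]))
  invisible(x)
}

#' @export
summary.hint_score_table <- function(object, n = 10, ...) {
  print(object)
  pr <- object$per_residue
  pr <- pr[order(-abs(pr$total)), ]
  cat("Top residues by |score|:\n")
  print(utils::head(pr, n), row.names = FALSE)
  invisible(object)
}

#' Interaction report for one residue's side chain
#'
#' All scored pairs involving the residue's side-chain atoms, grouped by
#' partner residue with class decomposition, sorted by absolute total -- the
#' per-residue interaction table used to inspect how a mutation site couples
#' to its neighbourhood.
#'
#' @inheritParams hint_total
#' @param chain,res_seq residue to report on.
#' @return object of class `residue_interactions` with the per-partner
#'   summary (`partners`) and the raw pair records (`records`).
#' @export
residue_interactions <- function(model, params = hint_params(), chain,
                                 res_seq) {
  tab <- hint_total(model, params)
  at <- tab$assignment$model$atoms
  idx <- which(at$chain == chain & at$res_seq == res_seq)
  if (!length(idx)) stop("no residue ", res_seq, " in chain ", chain)
  backbone <- c(.backbone_atoms, "OXT", "H", "H1", "H2", "H3", "HA",
                "HA1", "HA2")
  sc <- idx[!(at$name[idx] %in% backbone)]
  rec <- tab$records
  in_i <- rec$i %in% sc
  in_j <- rec$j %in% sc
  rec <- rec[xor(in_i, in_j) | (in_i & in_j), , drop = FALSE]
  both_sc <- rec$i %in% sc & rec$j %in% sc
  partner_idx <- ifelse(rec$i %in% sc & !both_sc, rec$j, rec$i)
  partner <- paste0(at$res_name[partner_idx], at$res_seq[partner_idx])
  self <- both_sc | partner_idx %in% idx
  partner[self] <- paste0(at$res_name[idx[1]], res_seq, " (self)")
  if (nrow(rec)) {
    agg <- stats::aggregate(rec$b, list(partner = partner), sum)
    names(agg)[2] <- "total"
    for (k in .hint_classes)
      agg[[k]] <- vapply(agg$partner, function(p)
        sum(rec$b[partner == p & rec$klass == k]), numeric(1))
    agg <- agg[order(-abs(agg$total)), ]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(partner = character(0), total = numeric(0))
  }
  structure(list(residue = paste0(at$res_name[idx[1]], res_seq),
                 chain = chain, res_seq = res_seq,
                 partners = agg, records = rec),
            class = "residue_interactions")
}

#' @export
print.residue_interactions <- function(x, n = 12, ...) {
  cat("Side-chain interactions of", x$residue, "(chain", x$chain, ")\n")
  if (!nrow(x$partners)) {
    cat("  no side-chain interactions (glycine or fully excluded)\n")
    return(invisible(x))
  }
  print(utils::head(x$partners, n), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Trajectory-averaged hydropathic score
#'
#' Applies [hint_total()] to each frame and reports per-frame totals and
#' component matrices together with their mean and standard deviation
#' across frames.
#'
#' @param traj an `md_trajectory`; each frame is scored on the reference
#'   topology.
#' @param params a [hint_params()] object.
#' @return list with `total` (per-frame B), `components` (frames x class
#'   matrix), `mean`, `sd`.
#' @export
hint_trajectory <- function(traj, params = hint_params()) {
  stopifnot(inherits(traj, "md_trajectory"))
  ref <- traj$reference
  totals <- numeric(n_frames(traj))
  comps <- matrix(0, n_frames(traj), length(.hint_classes),
                  dimnames = list(NULL, .hint_classes))
  for (m in seq_len(n_frames(traj))) {
    tab <- hint_total(set_coords(ref, frame_coords(traj, m)), params)
    totals[m] <- tab$total_B
    comps[m, ] <- tab$components
  }
  list(total = totals, components = comps,
       mean = c(B = mean(totals), colMeans(comps)),
       sd = c(B = stats::sd(totals), apply(comps, 2, stats::sd)))
}
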