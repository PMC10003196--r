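# Independent oracles used against the package implementations.
# These deliberately re-derive each quantity by the most naive route
# (explicit loops, direct summation, numerical search) and share no code
# with the functions they check.

# Terminal-atom table duplicated locally so the oracle does not depend on
# the package's table object.
oracle_terminal <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                        LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                        HIS = c("ND1", "NE2"))

# Exhaustive minimum over all terminal-atom cross pairs, plain loops.
oracle_pair_distance <- function(e, ref_a, ref_b, model = 1L) {
  xyz <- e$coords[, , model]
  pick <- function(ref) {
    sel <- which(e$atoms$chain_id == ref$chain_id &
                   e$atoms$resid == ref$resid &
                   e$atoms$icode == ref$icode)
    resname <- e$atoms$resname[sel[1]]
    sel[e$atoms$atom_name[sel] %in% oracle_terminal[[resname]]]
  }
  best <- Inf
  for (i in pick(ref_a)) for (j in pick(ref_b)) {
    d <- sqrt((xyz[i, 1] - xyz[j, 1])^2 + (xyz[i, 2] - xyz[j, 2])^2 +
                (xyz[i, 3] - xyz[j, 3])^2)
    if (d < best) best <- d
  }
  best
}

# Brute-force re-count of the coordination rule: oxygens within cutoff,
# count in [lo, hi].
oracle_site_qualifies <- function(e, cutoff = 2.5, lo = 4L, hi = 8L,
                                  model = 1L) {
  xyz <- e$coords[, , model]
  ion <- which(e$atoms$atom_name == "CA" & e$atoms$is_hetero)[1]
  cnt <- 0L
  for (j in seq_len(nrow(e$atoms))) {
    if (j == ion || toupper(e$atoms$element[j]) != "O") next
    d <- sqrt(sum((xyz[j, ] - xyz[ion, ])^2))
    if (d <= cutoff) cnt <- cnt + 1L
  }
  list(count = cnt, qualifies = cnt >= lo && cnt <= hi)
}

# Minimum RMSD over rigid transforms by numerical rotation search:
# coarse random-quaternion grid, then Nelder-Mead refinement of the best
# starts.  No SVD anywhere.
oracle_min_rmsd <- function(ref, mov, n_grid = 3000L, n_refine = 5L) {
  A <- sweep(ref, 2, colMeans(ref))
  B <- sweep(mov, 2, colMeans(mov))
  rot_from_quat <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj_q <- function(q) {
    R <- rot_from_quat(q)
    sqrt(mean(rowSums((B %*% t(R) - A)^2)))
  }
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, obj_q)
  best <- Inf
  for (k in order(vals)[seq_len(n_refine)]) {
    o <- optim(qs[k, ], obj_q, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    o2 <- optim(o$par, obj_q, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o2$value)
  }
  best
}

# Residual current by direct discrete summation over explicit indices.
oracle_residual <- function(t, i, pulse_start, pulse_duration, edge_ms = 5) {
  t_end <- pulse_start + pulse_duration
  s_num <- 0; s_n <- 0L; e_num <- 0; e_n <- 0L
  for (k in seq_along(t)) {
    if (t[k] >= pulse_start - 1e-9 && t[k] < pulse_start + edge_ms - 1e-9) {
      s_num <- s_num + i[k]; s_n <- s_n + 1L
    }
    if (t[k] >= t_end - edge_ms - 1e-9 && t[k] < t_end - 1e-9) {
      e_num <- e_num + i[k]; e_n <- e_n + 1L
    }
  }
  (e_num / e_n) / (s_num / s_n)
}

# Random rigid motion applied to every frame of an ensemble.
apply_rigid <- function(e, angle, axis, shift) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  out <- e
  for (m in seq_len(dim(e$coords)[3]))
    out$coords[, , m] <- sweep(e$coords[, , m] %*% t(R), 2, shift, "+")
  out
}

# A random charged-residue pair ensemble with arbitrary (not planted)
# geometry: every terminal atom at an independent random position.
random_pair_ensemble <- function(seed) {
  set.seed(seed)
  acid_res <- sample(c("ASP", "GLU"), 1)
  base_res <- sample(c("LYS", "ARG", "HIS"), 1)
  nm_a <- c("CA", oracle_terminal[[acid_res]])
  nm_b <- c("CA", oracle_terminal[[base_res]])
  atoms <- data.frame(
    chain_id = rep(c("A", "A"), c(length(nm_a), length(nm_b))),
    resid = rep(c(10L, 20L), c(length(nm_a), length(nm_b))),
    icode = "", resname = rep(c(acid_res, base_res),
                              c(length(nm_a), length(nm_b))),
    atom_name = c(nm_a, nm_b),
    element = substr(c(nm_a, nm_b), 1, 1), altloc = "", is_hetero = FALSE,
    stringsAsFactors = FALSE)
  xyz <- matrix(runif(nrow(atoms) * 3, -8, 8), ncol = 3)
  e <- pdb_ensemble(atoms, array(xyz, dim = c(nrow(atoms), 3, 1)))
  list(ensemble = e,
       spec = pair_spec("rnd", residue_ref("A", 10L, resname = acid_res),
                        residue_ref("A", 20L, resname = base_res)),
       ref_a = residue_ref("A", 10L, resname = acid_res),
       ref_b = residue_ref("A", 20L, resname = base_res))
}

# the packaged scenario's alignment plan (internal helper of the package)
scenario_plan_for_tests <- function() gatemap:::scenario_alignment_plan()

# k distinct indices out of n, fixed seed (for planted frame subsets)
with_seed_sample <- function(k, n) {
  set.seed(1234)
  sample.int(n, k)
}

default_bridge_pair <- function(label = "p",
                                acid = residue_ref("A", 294, resname = "GLU"),
                                base = residue_ref("A", 606, resname = "ARG")) {
  pair_spec(label, acid, base)
}
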