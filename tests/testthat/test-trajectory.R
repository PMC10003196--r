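# Kabsch superposition, RMSD series, stability onset and post-onset
# pair-distance statistics.

random_points <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(n * 3, sd = 2), ncol = 3)
}

rigid <- function(x, angle, axis, shift) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(x %*% t(R), 2, shift, "+")
}

test_that("superposing a set onto itself gives zero RMSD and the identity", {
  x <- random_points(10, 1)
  k <- kabsch_superpose(x, x)
  expect_equal(k$rmsd, 0, tolerance = 1e-12)
  expect_equal(k$rotation, diag(3), tolerance = 1e-9)
})

test_that("rigid motions are removed exactly and rotations stay proper", {
  for (s in 1:10) {
    x <- random_points(8, s)
    y <- rigid(x, angle = 37 * pi / 180 + s / 7, axis = c(s, 2, 1),
               shift = c(5, -2, 1))
    k <- kabsch_superpose(x, y)
    expect_lt(k$rmsd, 1e-9)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
    # returned transform really maps mov onto ref
    aligned <- sweep(y %*% k$rotation, 2, k$translation, "+")
    expect_equal(aligned, x, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("RMSD is symmetric and never exceeds the unaligned RMSD", {
  for (s in 1:8) {
    a <- random_points(9, s)
    b <- a + matrix(rnorm(27, sd = 0.5), ncol = 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, kabsch_superpose(b, a)$rmsd,
                 tolerance = 1e-9)
    unaligned <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(kabsch_superpose(a, b)$rmsd, unaligned + 1e-12)
  }
})

test_that("Kabsch minimum matches the numerical rotation-search oracle", {
  set.seed(7)
  for (case in 1:6) {
    a <- random_points(8, 100 + case)
    b <- a + matrix(rnorm(24, sd = 0.3), ncol = 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, oracle_min_rmsd(a, b),
                 tolerance = 1e-3)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(kabsch_superpose(random_points(5, 1), random_points(4, 2)),
               "size mismatch")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
})

test_that("a trajectory of identical frames has an all-zero RMSD series", {
  p <- default_bridge_pair()
  tj <- gen_trajectory(list(list(spec = p, mean_A = 6, sd_A = 0.3)),
                       n_frames = 40, changepoint = 10, rmsd_amplitude = 0,
                       rmsd_noise = 0, seed = 4)
  rs <- rmsd_series(tj)
  expect_equal(max(rs$rmsd_A), 0, tolerance = 1e-9)
  expect_equal(rs$time_ns, (0:39) * 0.2)
})

test_that("the RMSD series is invariant under per-frame rigid motions", {
  p <- default_bridge_pair()
  tj <- gen_trajectory(list(list(spec = p, mean_A = 6, sd_A = 0.3)),
                       n_frames = 30, changepoint = 10, seed = 5)
  rs <- rmsd_series(tj)
  moved <- tj
  set.seed(8)
  for (m in seq_len(30))
    moved$coords[, , m] <- rigid(moved$coords[, , m], runif(1, 0, pi),
                                 rnorm(3), rnorm(3, sd = 20))
  expect_equal(rmsd_series(moved)$rmsd_A, rs$rmsd_A, tolerance = 1e-7)
})

test_that("the series tracks the planted displacement profile", {
  p <- default_bridge_pair()
  tj <- gen_trajectory(list(list(spec = p, mean_A = 6, sd_A = 0.3)),
                       n_frames = 200, changepoint = 60, rmsd_noise = 0,
                       seed = 6)
  rs <- rmsd_series(tj)
  scale <- attr(tj, "ground_truth")$scale
  # proportional to the planted scale: constant ratio over the ramp
  ratio <- rs$rmsd_A[10:60] / scale[10:60]
  expect_lt(stats::sd(ratio) / mean(ratio), 0.05)
  expect_gt(mean(rs$rmsd_A[61:200]), 0.8 * mean(ratio) * max(scale))
})

test_that("stability onset finds flat series immediately and ramps late", {
  flat <- data.frame(frame = 1:100, time_ns = (0:99) * 0.2,
                     rmsd_A = rep(1.5, 100))
  expect_equal(stability_onset(flat, window = 20)$onset_index, 1L)

  rising <- transform(flat, rmsd_A = 0.5 * time_ns)  # slope 0.5 A/ns
  expect_warning(res <- stability_onset(rising, window = 20), "last admissible")
  expect_equal(res$onset_index, 81L)

  expect_error(stability_onset(flat, window = 200), "window")
})

test_that("planted changepoints are recovered within one window", {
  p <- default_bridge_pair()
  for (s in 1:5) {
    tj <- gen_trajectory(list(list(spec = p, mean_A = 6, sd_A = 0.3)),
                         n_frames = 500, changepoint = 150, seed = s)
    on <- stability_onset(rmsd_series(tj))
    expect_lte(abs(on$onset_index - 150), 50)
  }
})

test_that("onset start is non-decreasing as the slope tolerance tightens", {
  p <- default_bridge_pair()
  tj <- gen_trajectory(list(list(spec = p, mean_A = 6, sd_A = 0.3)),
                       n_frames = 300, changepoint = 100, seed = 9)
  rs <- rmsd_series(tj)
  tols <- c(0.5, 0.2, 0.1, 0.05, 0.02)
  onsets <- vapply(tols, function(tol)
    suppressWarnings(stability_onset(rs, slope_tol = tol)$onset_index),
    integer(1))
  expect_true(all(diff(onsets) >= 0))
})

test_that("post-onset distance statistics match a naive recomputation", {
  p <- default_bridge_pair()
  tj <- gen_trajectory(list(list(spec = p, mean_A = 6, sd_A = 0.4,
                                 drift_A = 4)),
                       n_frames = 200, changepoint = 60, seed = 10,
                       source_label = "CaCl2")
  on <- stability_onset(rmsd_series(tj))
  pd <- pair_distance_series(tj, p, on)
  d <- numeric(0)
  for (m in seq_len(200)) d <- c(d, charged_pair_distance(tj, p, m))
  post <- d[on$onset_index:200]
  expect_equal(pd$stats$mean_A, sum(post) / length(post))
  expect_equal(pd$stats$n, length(post))
  expect_identical(pd$stats$condition, "CaCl2")
  expect_equal(pd$series$distance_A, d)
  # fluctuation around the planted post-onset mean
  expect_equal(pd$stats$mean_A, 6, tolerance = 0.2)

  # onset at the last admissible frame restricts to the final window
  pd_tail <- pair_distance_series(tj, p, onset = 200L)
  expect_equal(pd_tail$stats$n, 1L)
  expect_identical(pd_tail$stats$sd_A, 0)
})

test_that("zero-fluctuation trajectories plant the distance exactly", {
  p <- default_bridge_pair()
  tj <- gen_trajectory(list(list(spec = p, mean_A = 7.5, sd_A = 0)),
                       n_frames = 20, changepoint = 5, seed = 11)
  pd <- pair_distance_series(tj, p)
  expect_equal(pd$stats$mean_A, 7.5, tolerance = 1e-9)
  expect_equal(pd$stats$sd_A, 0, tolerance = 1e-9)
})
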