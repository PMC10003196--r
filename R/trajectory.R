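# Trajectory-level analyses: optimal superposition RMSD, stability onset,
# and time-averaged pair distances after stabilisation.

#' Kabsch optimal superposition
#'
#' Closed-form least-squares rigid alignment of two equally-sized point
#' sets: centroid subtraction, SVD of the covariance matrix, and a
#' determinant sign correction so the returned rotation is proper
#' (det = +1, no reflection).  The RMSD is the minimum over all rigid
#' transforms of `mov` onto `ref`.
#'
#' @param ref,mov n x 3 coordinate matrices, n >= 3, not all collinear.
#' @return List with `rotation` (3 x 3), `translation` (length-3), and
#'   `rmsd` (Angstrom); the aligned coordinates are
#'   `mov %*% rotation + translation` (row-vector convention).
#' @export
kabsch_superpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (!identical(dim(ref), dim(mov)))
    stop("size mismatch: ref is ", nrow(ref), " x ", ncol(ref),
         ", mov is ", nrow(mov), " x ", ncol(mov))
  if (ncol(ref) != 3L) stop("coordinate matrices must have 3 columns")
  n <- nrow(ref)
  if (n < 3L) stop("at least 3 points are required")
  cr <- colMeans(ref); cm <- colMeans(mov)
  A <- sweep(ref, 2, cr); B <- sweep(mov, 2, cm)
  H <- crossprod(B, A)                      # covariance, mov -> ref
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)  # maps centred mov rows
  rot <- t(R)                               # row-vector convention
  aligned <- B %*% rot
  rmsd <- sqrt(mean(rowSums((aligned - A)^2)))
  list(rotation = rot, translation = cr - as.vector(cm %*% rot), rmsd = rmsd)
}

# Row indices of the default RMSD selection: alpha carbons of polymer
# residues.
default_rmsd_selection <- function(e) {
  which(e$atoms$atom_name == "CA" & !e$atoms$is_hetero)
}

#' Superposed RMSD series of a trajectory
#'
#' Per-frame Kabsch RMSD against a reference frame over a fixed atom
#' selection (default: alpha carbons of non-hetero residues).
#'
#' @param traj trajectory as `pdb_ensemble` (frames as models).
#' @param frame_interval time between frames, ns (default 0.2).
#' @param selection integer atom indices, or a predicate
#'   `function(atoms) -> logical`; default alpha carbons.
#' @param reference reference frame index (default 1).
#' @return Object of class `rmsd_series`: data.frame `frame`, `time_ns`,
#'   `rmsd_A` with attributes `reference_index` and `frame_interval`.
#' @export
rmsd_series <- function(traj, frame_interval = 0.2, selection = NULL,
                        reference = 1L) {
  stopifnot(frame_interval > 0)
  sel <- if (is.null(selection)) default_rmsd_selection(traj)
  else if (is.function(selection)) which(selection(traj$atoms))
  else as.integer(selection)
  if (length(sel) == 0L) stop("empty RMSD selection")
  nf <- n_models(traj)
  if (nf < 2L) stop("a trajectory needs at least 2 frames")
  ref <- model_coords(traj, reference)[sel, , drop = FALSE]
  vals <- vapply(seq_len(nf), function(m) {
    if (m == reference) return(0)
    kabsch_superpose(ref, model_coords(traj, m)[sel, , drop = FALSE])$rmsd
  }, numeric(1))
  out <- data.frame(frame = seq_len(nf),
                    time_ns = (seq_len(nf) - 1L) * frame_interval,
                    rmsd_A = vals)
  attr(out, "reference_index") <- as.integer(reference)
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Stability onset from an RMSD series
#'
#' The onset is the first frame `i` such that the least-squares slope of
#' the RMSD over the window `[i, i + window - 1]` is within `slope_tol`
#' in absolute value.  If no window is flat enough the last admissible
#' start (`n_frames - window + 1`) is returned with a warning.  Indices
#' are 1-based.
#'
#' @param s an [rmsd_series()] result (or data.frame with `time_ns`,
#'   `rmsd_A`).
#' @param window window length in frames (default 50).
#' @param slope_tol absolute slope tolerance, Angstrom/ns (default 0.05).
#' @return List of class `stability_result`: `onset_index`, `onset_time`,
#'   `window`, `slope_tol`.
#' @export
stability_onset <- function(s, window = 50L, slope_tol = 0.05) {
  n <- nrow(s)
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  stopifnot(window >= 2L, slope_tol >= 0)
  tw <- s$time_ns[seq_len(window)]
  tw <- tw - mean(tw)
  denom <- sum(tw^2)
  onset <- NA_integer_
  for (i in seq_len(n - window + 1L)) {
    y <- s$rmsd_A[i:(i + window - 1L)]
    slope <- sum(tw * (y - mean(y))) / denom
    if (abs(slope) <= slope_tol) { onset <- i; break }
  }
  if (is.na(onset)) {
    onset <- n - window + 1L
    warning("no window with |slope| <= ", slope_tol,
            " A/ns; using last admissible start", call. = FALSE)
  }
  structure(list(onset_index = onset, onset_time = s$time_ns[onset],
                 window = as.integer(window), slope_tol = slope_tol),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> onset frame %d (t = %.2f ns), window %d, |slope| <= %g A/ns\n",
              x$onset_index, x$onset_time, x$window, x$slope_tol))
  invisible(x)
}

#' Per-frame pair-distance series with post-onset statistics
#'
#' Measures [charged_pair_distance()] in every frame and summarises the
#' frames at or after the stability onset, mirroring the convention of
#' averaging interaction distances only over the equilibrated part of a
#' simulation.
#'
#' @param traj trajectory as `pdb_ensemble`.
#' @param p a [pair_spec()].
#' @param onset a [stability_onset()] result, or an integer 1-based frame
#'   index (default 1: use all frames).
#' @param frame_interval ns between frames, for the time column.
#' @return List with `series` (data.frame `frame`, `time_ns`, `distance_A`)
#'   and `stats` (data.frame as [ensemble_distance_stats()], computed over
#'   frames `>= onset`; `condition` is the trajectory's `source_label`).
#' @export
pair_distance_series <- function(traj, p, onset = 1L, frame_interval = 0.2) {
  k <- if (inherits(onset, "stability_result")) onset$onset_index
  else as.integer(onset)
  nf <- n_models(traj)
  stopifnot(k >= 1L, k <= nf)
  d <- vapply(seq_len(nf), function(m) charged_pair_distance(traj, p, m),
              numeric(1))
  post <- d[k:nf]
  list(series = data.frame(frame = seq_len(nf),
                           time_ns = (seq_len(nf) - 1L) * frame_interval,
                           distance_A = d),
       stats = data.frame(pair_label = p$label,
                          condition = traj$source_label,
                          mean_A = mean(post), sd_A = sample_sd(post),
                          n = length(post), stringsAsFactors = FALSE))
}
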