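# Fast-inactivation statistics from whole-cell current traces:
# residual current ratio and single-exponential time constant.

#' Construct a whole-cell current trace
#'
#' @param t time, ms, uniformly sampled (strictly increasing, step
#'   `1000 / sampling_rate`).
#' @param i current, pA (signed; inward currents are negative).
#' @param sampling_rate Hz (default 10000, i.e. 10 kHz digitisation).
#' @param pulse_start start of the voltage pulse, ms.
#' @param pulse_duration pulse length, ms (default 60).
#' @param holding_mV,step_mV potential metadata (defaults 0 and -160).
#' @return Object of class `current_trace`.
#' @export
current_trace <- function(t, i, sampling_rate = 10000, pulse_start = 0,
                          pulse_duration = 60, holding_mV = 0,
                          step_mV = -160) {
  stopifnot(length(t) == length(i), length(t) >= 2L)
  dt <- diff(t)
  step <- 1000 / sampling_rate
  if (any(dt <= 0) || max(abs(dt - step)) > 1e-6 * step)
    stop("t must be uniformly sampled at 1000/sampling_rate ms")
  if (pulse_start < t[1] - 1e-9 ||
      pulse_start + pulse_duration > t[length(t)] + step + 1e-9)
    stop("pulse window extends beyond the trace")
  structure(list(t = as.numeric(t), i = as.numeric(i),
                 sampling_rate = sampling_rate, pulse_start = pulse_start,
                 pulse_duration = pulse_duration, holding_mV = holding_mV,
                 step_mV = step_mV), class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples @ %g kHz, pulse [%g, %g] ms, %g -> %g mV\n",
              length(x$t), x$sampling_rate / 1000, x$pulse_start,
              x$pulse_start + x$pulse_duration, x$holding_mV, x$step_mV))
  invisible(x)
}

#' Read a current trace from a two-column CSV
#'
#' @param path CSV path (or text) with columns `time_ms`, `current_pA`.
#' @param ... metadata passed to [current_trace()].
#' @export
read_trace <- function(path, ...) {
  df <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path))
    utils::read.csv(path) else utils::read.csv(text = path)
  if (!all(c("time_ms", "current_pA") %in% names(df)))
    stop("trace CSV must have columns time_ms, current_pA")
  current_trace(df$time_ms, df$current_pA, ...)
}

# Mean currents over the first and last `edge_ms` of the pulse.
pulse_edge_means <- function(tr, edge_ms) {
  t0 <- tr$pulse_start
  t1 <- tr$pulse_start + tr$pulse_duration
  if (tr$pulse_duration < 2 * edge_ms)
    stop("edge windows overlap: pulse shorter than 2 x edge_ms")
  start_w <- tr$t >= t0 - 1e-9 & tr$t < t0 + edge_ms - 1e-9
  end_w <- tr$t >= t1 - edge_ms - 1e-9 & tr$t < t1 - 1e-9
  if (!any(start_w) || !any(end_w))
    stop("no samples inside an edge window")
  c(start = mean(tr$i[start_w]), end = mean(tr$i[end_w]))
}

#' Residual current of a trace
#'
#' The residual current is the ratio of the mean current over the last
#' `edge_ms` of the pulse to the mean over the first `edge_ms` (window
#' means, computed on signed currents): 1 means no inactivation, values
#' near 0 mean complete fast inactivation.
#'
#' @param tr a [current_trace()].
#' @param edge_ms edge-window length, ms (default 5).
#' @param floor_pA minimum admissible `|i_start_mean|` (default 1 pA);
#'   smaller values make the ratio unstable and raise an error.
#' @return List of class `inactivation_metrics` with `residual`,
#'   `i_start_mean`, `i_end_mean`, `edge_ms`.
#' @export
residual_current <- function(tr, edge_ms = 5, floor_pA = 1) {
  stopifnot(inherits(tr, "current_trace"), edge_ms > 0)
  em <- pulse_edge_means(tr, edge_ms)
  if (abs(em["start"]) < floor_pA)
    stop("unstable-ratio error: |mean current| in the first window is ",
         sprintf("%.3g", abs(em["start"])), " pA (< ", floor_pA, " pA)")
  structure(list(residual = unname(em["end"] / em["start"]),
                 i_start_mean = unname(em["start"]),
                 i_end_mean = unname(em["end"]), edge_ms = edge_ms),
            class = "inactivation_metrics")
}

#' @export
print.inactivation_metrics <- function(x, ...) {
  cat("<inactivation_metrics>\n")
  if (!is.null(x$residual))
    cat(sprintf("  residual = %.4f (Ie %.1f / Is %.1f pA, %g ms windows)\n",
                x$residual, x$i_end_mean, x$i_start_mean, x$edge_ms))
  if (!is.null(x$converged))
    cat(sprintf("  tau = %s ms, converged = %s\n",
                if (is.na(x$tau)) "NA" else sprintf("%.3f", x$tau),
                x$converged))
  invisible(x)
}

#' Fit a single-exponential inactivation time constant
#'
#' Least-squares fit of `i(t) = i_inf + (i0 - i_inf) * exp(-(t - t0)/tau)`
#' over the pulse window on the raw signed currents.  Initialisation:
#' `i_inf` from the end-window mean, `i0` from the start-window mean, and
#' `tau` from a log-linear regression of `|i - i_inf_init|`.  A trace whose
#' end current is not smaller in magnitude than its start current -- within
#' the estimated noise and by at least 1% of the start current -- is treated
#' as non-decaying: no tau is reported and `converged = FALSE`.
#'
#' @param tr a [current_trace()].
#' @param blank_ms capacitive-transient blanking: samples in the first
#'   `blank_ms` of the pulse are excluded from the fit (default 0 -- real
#'   recordings typically need ~0.5 ms, synthetic traces none).
#' @param edge_ms edge-window length used for initialisation (default 5).
#' @return List of class `inactivation_metrics` with `tau` (ms, `NA` when
#'   the fit is rejected), `fit` (`i0`, `i_inf`, `tau`, `rss`), and
#'   `converged` (`TRUE` only for an optimiser success with
#'   `tau` in `(0.1, 10 * pulse_duration)` ms).
#' @export
fit_inactivation_tau <- function(tr, blank_ms = 0, edge_ms = 5) {
  stopifnot(inherits(tr, "current_trace"))
  t0 <- tr$pulse_start
  t1 <- t0 + tr$pulse_duration
  w <- tr$t >= t0 + blank_ms - 1e-9 & tr$t < t1 - 1e-9
  if (sum(w) < 20L) stop("pulse window has fewer than 20 samples")
  tt <- tr$t[w] - t0
  ii <- tr$i[w]
  em <- pulse_edge_means(tr, edge_ms)
  no_fit <- structure(list(tau = NA_real_, fit = NULL, converged = FALSE),
                      class = "inactivation_metrics")

  # Non-decay guard: the end-window mean must be smaller in magnitude than
  # the start-window mean both statistically (noise scale estimated from
  # first differences of the start window) and by a 1% relative floor.
  head_i <- tr$i[tr$t >= t0 - 1e-9 & tr$t < t0 + edge_ms - 1e-9]
  noise_sd <- if (length(head_i) > 2L) stats::sd(diff(head_i)) / sqrt(2) else 0
  n_end <- max(1L, sum(tr$t >= t1 - edge_ms - 1e-9 & tr$t < t1 - 1e-9))
  guard <- max(4 * sqrt(2) * noise_sd / sqrt(n_end),
               0.01 * abs(em["start"])) + 1e-12
  if (abs(em["end"]) >= abs(em["start"]) - guard) return(no_fit)

  # Log-linear tau initialisation on |i - i_inf_init|.
  amp <- abs(ii - em["end"])
  pos <- amp > max(amp) * 1e-3
  tau0 <- if (sum(pos) >= 3L) {
    sl <- stats::coef(stats::lm(log(amp[pos]) ~ tt[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else tr$pulse_duration / 5
  } else tr$pulse_duration / 5
  tau0 <- min(max(tau0, 0.05), 20 * tr$pulse_duration)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      ii ~ i_inf + (i0 - i_inf) * exp(-tt / tau),
      start = list(i0 = unname(em["start"]), i_inf = unname(em["end"]),
                   tau = tau0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(no_fit)
  cf <- stats::coef(fit)
  tau <- unname(cf["tau"])
  ok <- is.finite(tau) && tau > 0.1 && tau < 10 * tr$pulse_duration
  structure(list(tau = if (ok) tau else NA_real_,
                 fit = list(i0 = unname(cf["i0"]), i_inf = unname(cf["i_inf"]),
                            tau = tau, rss = sum(stats::resid(fit)^2)),
                 converged = ok),
            class = "inactivation_metrics")
}

#' Summarise inactivation metrics over a set of traces
#'
#' Convenience wrapper: residual current and tau per trace plus a
#' mean +/- standard-error group summary (tau summarised over converged
#' fits only).
#'
#' @param traces list of [current_trace()] objects (optionally named).
#' @param ... passed to [fit_inactivation_tau()].
#' @return List with `per_trace` (data.frame `trace`, `residual`, `tau`,
#'   `converged`) and `summary` (data.frame of means and standard errors).
#' @export
inactivation_summary <- function(traces, ...) {
  ids <- names(traces) %||% as.character(seq_along(traces))
  per <- do.call(rbind, lapply(seq_along(traces), function(k) {
    r <- residual_current(traces[[k]])
    f <- fit_inactivation_tau(traces[[k]], ...)
    data.frame(trace = ids[k], residual = r$residual, tau = f$tau,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  taus <- per$tau[per$converged]
  list(per_trace = per,
       summary = data.frame(
         n = nrow(per), residual_mean = mean(per$residual),
         residual_sem = sem(per$residual),
         n_converged = length(taus),
         tau_mean = if (length(taus)) mean(taus) else NA_real_,
         tau_sem = sem(taus)))
}
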