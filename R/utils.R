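# Internal helpers shared across modules.

#' gatemap: interdomain distance, coordination-site and inactivation-kinetics analysis
#'
#' See the package README and the methods vignette for the scientific
#' background and a worked example.
#' @keywords internal
"_PACKAGE"

# Run code with a temporarily-set RNG seed; the caller's RNG state is
# restored on exit so generators never perturb user randomness.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Euclidean distance between two 3-vectors.
dist3 <- function(a, b) sqrt(sum((a - b)^2))

# Random unit vector in R^3 (uses current RNG stream).
runif_unit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# Sample standard deviation with the n-1 denominator; 0 when n == 1.
sample_sd <- function(x) if (length(x) <= 1L) 0 else stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
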