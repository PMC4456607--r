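# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`, then
#' restores the previous RNG state, so seeded package functions never clobber
#' the caller's random stream. With `seed = NULL` the expression is evaluated
#' against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Centered running mean with shrinking windows at the vector edges.
# k must be odd so the kernel is symmetric (keeps noiseless signature
# profiles symmetric about their centers).
run_mean <- function(x, k) {
  stopifnot(k >= 1, k %% 2 == 1)
  if (k == 1L) return(x)
  n <- length(x)
  h <- (k - 1L) / 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Smoothed stationary baseline profile: the stochastic stand-in for the
# sequence-dependent naked-DNA unzipping force. Seeded per template so every
# trace of a template (and its naked reference) shares the same features.
baseline_profile <- function(len, mean_pN, sd_pN, corr_bp = 5, seed = NULL) {
  if (sd_pN <= 0) return(rep(mean_pN, len))
  with_seed(seed, {
    pad <- ceiling(3 * corr_bp)
    z <- stats::rnorm(len + 2L * pad)
    kern <- stats::dnorm(seq(-pad, pad), sd = corr_bp)
    kern <- kern / sum(kern)
    sm <- as.numeric(stats::filter(z, kern, sides = 2))
    sm <- sm[(pad + 1L):(pad + len)]
    mean_pN + sd_pN * (sm - mean(sm)) / stats::sd(sm)
  })
}

# Coordinate conversions. Unzipping coordinates run 0..(L-1) in the order the
# fork encounters base pairs; template coordinates are fixed with the TF side
# at low values; dyad-relative coordinates put the origin at the initial dyad.
unzip_to_template <- function(u, template_len, direction) {
  if (direction == "from_tf_side") u else (template_len - 1) - u
}

template_to_unzip <- function(x, template_len, direction) {
  if (direction == "from_tf_side") x else (template_len - 1) - x
}

template_to_rel <- function(x, dyad0) x - dyad0

`%||%` <- function(a, b) if (is.null(a)) b else a
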