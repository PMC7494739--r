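# Internal helpers shared across the package.

#' Round half away from zero
#'
#' Rounding used at the reporting layer for consensus scores and
#' percentages. Unlike [base::round()] (banker's rounding), halves are
#' always rounded away from zero, matching how screening reports are
#' conventionally printed.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(2.675, 2)
#' round_half_up(-9.8283333, 2)
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-block seed derivation: one root seed plus a block
# label gives an independent substream, so adding a generator block never
# perturbs another block's draws.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  as.integer((h + (seed %% m) * 69069) %% m)
}

# Run an expression under a named substream without disturbing the
# caller's RNG state.
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  expr
}

stop_fields <- function(ok, field, msg) {
  if (!ok) stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

# Draw from a normal(mean, sd) truncated to [0, Inf) by inverse-CDF;
# exact and vectorised, no rejection loop.
rtruncnorm0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean = mean, sd = sd)
  u <- lo + (1 - lo) * stats::runif(n)
  q <- stats::qnorm(u, mean = mean, sd = sd)
  pmax(q, 0) # guard against tiny negative values from rounding at u ~ lo
}
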