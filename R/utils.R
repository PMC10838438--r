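#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed and a stage label
#'
#' Stable fan-out so each pipeline stage gets an independent, reproducible
#' stream. Uses a small polynomial rolling hash of the label, folded into
#' [0, 2^31 - 2].
#' @noRd
derive_seed <- function(master_seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(master_seed) * 2654435 + h) %% 2147480009)
}

#' log(mean(exp(x))) without overflow
#' @noRd
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Centered moving average with edge shrinkage
#' @noRd
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  half <- floor(width / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Truncated standard normal draws on [-3, 3]
#' @noRd
rnorm_trunc3 <- function(n) {
  x <- stats::rnorm(n)
  bad <- abs(x) > 3
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad))
    bad <- abs(x) > 3
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
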