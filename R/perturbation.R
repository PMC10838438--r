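#' Jitter measures from a pulse sequence
#'
#' Cycle-to-cycle period perturbation quotients over the periods
#' \eqn{T_i}:
#' * `local`: mean absolute difference of consecutive periods over the
#'   mean period;
#' * `local_absolute`: the same numerator in seconds;
#' * `rap`: relative average perturbation, each period against the
#'   3-point moving average;
#' * `ppq5`: 5-point period perturbation quotient;
#' * `ddp`: mean absolute difference of consecutive period differences
#'   over the mean period (identically `3 * rap`).
#'
#' Requires at least 3 periods (5 for `ppq5`); measures that cannot be
#' computed are `NA`.
#'
#' @param p A `pulse_sequence` from [extract_pulses()].
#' @return Named list `local`, `local_absolute`, `rap`, `ppq5`, `ddp`
#'   (fractions except `local_absolute` in seconds).
#' @export
jitter_metrics <- function(p) {
  T_ <- p$periods
  out <- list(local = NA_real_, local_absolute = NA_real_, rap = NA_real_,
              ppq5 = NA_real_, ddp = NA_real_)
  n <- length(T_)
  if (isTRUE(p$missing) || n < 3L) return(out)
  mT <- mean(T_)
  out$local_absolute <- mean(abs(diff(T_)))
  out$local <- out$local_absolute / mT
  dev3 <- abs(T_[2:(n - 1)] - (T_[1:(n - 2)] + T_[2:(n - 1)] + T_[3:n]) / 3)
  out$rap <- mean(dev3) / mT
  out$ddp <- mean(abs(diff(diff(T_)))) / mT
  if (n >= 5L) {
    i <- 3:(n - 2)
    m5 <- (T_[i - 2] + T_[i - 1] + T_[i] + T_[i + 1] + T_[i + 2]) / 5
    out$ppq5 <- mean(abs(T_[i] - m5)) / mT
  }
  out
}

#' Shimmer measures from a pulse sequence
#'
#' Cycle-to-cycle amplitude perturbation quotients over the per-cycle
#' peak amplitudes \eqn{A_i}:
#' * `local`: mean absolute difference of consecutive amplitudes over the
#'   mean amplitude;
#' * `local_db`: mean absolute base-10 log amplitude ratio of consecutive
#'   cycles, times 20 (dB);
#' * `apq3`, `apq5`, `apq11`: N-point amplitude perturbation quotients;
#' * `dda`: mean absolute difference of consecutive amplitude differences
#'   over the mean amplitude (identically `3 * apq3`).
#'
#' `apq11` requires at least 11 amplitudes; the others at least 3 (5 for
#' `apq5`).
#'
#' @param p A `pulse_sequence`.
#' @return Named list `local`, `local_db`, `apq3`, `apq5`, `apq11`, `dda`.
#' @export
shimmer_metrics <- function(p) {
  A <- p$amplitudes
  out <- list(local = NA_real_, local_db = NA_real_, apq3 = NA_real_,
              apq5 = NA_real_, apq11 = NA_real_, dda = NA_real_)
  n <- length(A)
  if (isTRUE(p$missing) || n < 3L) return(out)
  mA <- mean(A)
  out$local <- mean(abs(diff(A))) / mA
  out$local_db <- mean(abs(20 * log10(A[-1] / A[-n])))
  apq <- function(k) {
    if (n < k) return(NA_real_)
    half <- (k - 1L) %/% 2L
    i <- (half + 1L):(n - half)
    mk <- vapply(i, function(j) mean(A[(j - half):(j + half)]), numeric(1))
    mean(abs(A[i] - mk)) / mA
  }
  out$apq3 <- apq(3L)
  out$apq5 <- apq(5L)
  out$apq11 <- apq(11L)
  out$dda <- mean(abs(diff(diff(A)))) / mA
  out
}
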