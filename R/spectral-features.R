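#' Harmonicity measures
#'
#' Per voiced frame, `r` is the normalized autocorrelation at the pitch
#' lag (as refined by the tracker). The frame harmonics-to-noise ratio is
#' \eqn{10\log_{10}(r/(1-r))}, capped at \eqn{\pm 60} dB. Summaries:
#' `hnr_mean`/`hnr_sd` over voiced frames, `ac_mean` the mean `r`,
#' `cc_mean` the mean normalized cross-correlation of successive cycles,
#' and `nhr_mean` the mean noise-to-harmonics ratio \eqn{(1-r)/r}.
#'
#' @param rec An `audio_recording`.
#' @param f0_contour Output of [track_f0()].
#' @return Named list `hnr_mean`, `hnr_sd`, `ac_mean`, `cc_mean`,
#'   `nhr_mean`; all `NA` when no frame is voiced.
#' @export
harmonicity_metrics <- function(rec, f0_contour = track_f0(rec)) {
  out <- list(hnr_mean = NA_real_, hnr_sd = NA_real_, ac_mean = NA_real_,
              cc_mean = NA_real_, nhr_mean = NA_real_)
  v <- f0_contour$voiced
  if (!any(v)) return(out)
  r <- pmin(pmax(f0_contour$r[v], 1e-6), 1 - 1e-6)
  hnr <- pmin(pmax(10 * log10(r / (1 - r)), -60), 60)
  out$hnr_mean <- mean(hnr)
  out$hnr_sd <- if (sum(v) > 1L) stats::sd(hnr) else 0
  out$ac_mean <- mean(r)
  out$nhr_mean <- mean((1 - r) / r)
  # cross-correlation of successive cycles within each voiced frame
  fs <- rec$sample_rate_hz
  x <- rec$samples
  cc <- vapply(which(v), function(k) {
    f0 <- f0_contour$f0[k]
    L <- round(fs / f0)
    c0 <- round(f0_contour$time[k] * fs)
    i1 <- (c0 - L + 1L):c0
    i2 <- (c0 + 1L):(c0 + L)
    if (i1[1] < 1L || i2[length(i2)] > length(x)) return(NA_real_)
    a <- x[i1]; b <- x[i2]
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  out$cc_mean <- mean(cc, na.rm = TRUE)
  if (is.nan(out$cc_mean)) out$cc_mean <- NA_real_
  out
}

#' Intensity distribution statistics
#'
#' Per-frame RMS level in dB relative to full scale over speech-active
#' frames (energy-based activity detection, threshold relative to the
#' 95th-percentile frame level so the active set is invariant under
#' amplitude scaling).
#'
#' @param rec An `audio_recording`.
#' @param frame_s Frame length in seconds.
#' @return Named list `mean`, `median`, `min`, `max`, `range`, `variance`,
#'   `sd` in dB (dB^2 for `variance`); all `NA` for an all-silent input.
#' @export
intensity_metrics <- function(rec, frame_s = 0.01) {
  out <- list(mean = NA_real_, median = NA_real_, min = NA_real_,
              max = NA_real_, range = NA_real_, variance = NA_real_,
              sd = NA_real_)
  if (max(abs(rec$samples)) < 1e-12) return(out)
  v <- vad_frames(rec, frame_s = frame_s)
  db <- v$frame_db
  act <- if (v$indeterminate) rep(TRUE, length(db)) else v$active
  db <- db[act]
  if (!length(db)) return(out)
  list(mean = mean(db), median = stats::median(db), min = min(db),
       max = max(db), range = max(db) - min(db),
       variance = if (length(db) > 1L) stats::var(db) else 0,
       sd = if (length(db) > 1L) stats::sd(db) else 0)
}

#' Zero-crossing rate statistics
#'
#' Per frame, the number of sign changes divided by the frame sample
#' count (a per-sample crossing fraction; multiply by the sample rate for
#' crossings per second). Returns the mean and variance over frames.
#'
#' @param rec An `audio_recording`.
#' @param frame_s Frame length in seconds.
#' @return Named list `mean`, `variance`.
#' @export
zcr_metrics <- function(rec, frame_s = 0.025) {
  fs <- rec$sample_rate_hz
  w <- max(2L, round(frame_s * fs))
  n_frames <- floor(length(rec$samples) / w)
  if (n_frames < 1L) {
    x <- rec$samples
    zc <- sum(diff(x >= 0) != 0) / length(x)
    return(list(mean = zc, variance = 0))
  }
  m <- matrix(rec$samples[seq_len(n_frames * w)], nrow = w)
  pos <- m >= 0
  zc <- colSums(pos[-1, , drop = FALSE] != pos[-w, , drop = FALSE]) / w
  list(mean = mean(zc),
       variance = if (n_frames > 1L) stats::var(zc) else 0)
}
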