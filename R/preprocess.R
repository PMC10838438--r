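#' @useDynLib bulbarvoice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Short-time Fourier analysis frame plan: window length in samples (even),
# 50% overlap Hann.
stft_plan <- function(sample_rate_hz, window_s = 0.025) {
  n_win <- round(window_s * sample_rate_hz)
  if (n_win %% 2L == 1L) n_win <- n_win + 1L
  list(n_win = n_win, hop = n_win %/% 2L,
       window = 0.5 - 0.5 * cos(2 * pi * seq_len(n_win) / n_win), # periodic Hann
       freq = (seq_len(n_win) - 1L) / n_win * sample_rate_hz)
}

#' Estimate a noise magnitude profile from a noise-only segment
#'
#' Averages short-time magnitude spectra (Hann windows of `window_s`, 50%
#' overlap) over the given segment. The segment must be at least 0.25 s
#' long so the profile averages over enough analysis windows.
#'
#' @param rec An `audio_recording`.
#' @param segment Numeric `c(start_s, end_s)` of a noise-only interval;
#'   defaults to the first 0.25 s of the recording.
#' @param window_s Analysis window length in seconds.
#' @return An object of class `noise_profile`.
#' @export
estimate_noise_profile <- function(rec, segment = NULL, window_s = 0.025) {
  stopifnot(inherits(rec, "audio_recording"))
  fs <- rec$sample_rate_hz
  if (is.null(segment)) segment <- c(0, min(0.25, duration_s(rec)))
  if (segment[1] < 0 || segment[2] > duration_s(rec) + 1e-9)
    stop("estimate_noise_profile: segment outside recording")
  src_dur <- segment[2] - segment[1]
  if (src_dur < 0.25 - 1e-9)
    stop("estimate_noise_profile: noise segment must be at least 0.25 s (got ",
         sprintf("%.3f", src_dur), " s)")
  plan <- stft_plan(fs, window_s)
  i0 <- floor(segment[1] * fs) + 1L
  i1 <- min(length(rec$samples), floor(segment[2] * fs))
  x <- rec$samples[i0:i1]
  starts <- seq(1L, length(x) - plan$n_win + 1L, by = plan$hop)
  mags <- vapply(starts, function(s) {
    Mod(stats::fft(x[s:(s + plan$n_win - 1L)] * plan$window))
  }, numeric(plan$n_win))
  structure(
    list(magnitude = rowMeans(mags), window_s = window_s,
         sample_rate_hz = fs, source_duration_s = src_dur,
         freq = plan$freq),
    class = "noise_profile"
  )
}

#' Spectral-subtraction noise reduction
#'
#' Boll-style short-time magnitude subtraction: Hann windows of `window_s`
#' with 50% overlap, noise magnitude spectrum smoothed with a moving
#' average of `smoothing_hz` bandwidth, subtraction restricted to the
#' `band_hz` suppression range, a spectral floor preventing negative
#' magnitudes, phase reused from the input, and overlap-add
#' reconstruction. Output length equals input length.
#'
#' @param rec An `audio_recording`.
#' @param profile A `noise_profile` from [estimate_noise_profile()] with
#'   matching sample rate and window length.
#' @param band_hz Suppression range, default 80 Hz to 10 kHz.
#' @param smoothing_hz Bandwidth of the noise-spectrum moving average (Hz).
#' @param oversubtraction Multiple of the noise magnitude subtracted.
#' @param floor_coef Spectral floor as a fraction of the noise magnitude.
#' @param window_s Configured analysis window length (s); the profile must
#'   have been estimated with the same window.
#' @return A noise-reduced `audio_recording`.
#' @export
spectral_subtract <- function(rec, profile, band_hz = c(80, 10000),
                              smoothing_hz = 40, oversubtraction = 2,
                              floor_coef = 0.02, window_s = 0.025) {
  stopifnot(inherits(rec, "audio_recording"), inherits(profile, "noise_profile"))
  if (profile$sample_rate_hz != rec$sample_rate_hz)
    stop("spectral_subtract: sample rate mismatch between recording and profile")
  if (abs(profile$window_s - window_s) > 1e-12)
    stop("spectral_subtract: profile window length (", profile$window_s,
         " s) does not match the configured analysis window (", window_s, " s)")
  fs <- rec$sample_rate_hz
  plan <- stft_plan(fs, window_s)
  if (length(profile$magnitude) != plan$n_win)
    stop("spectral_subtract: profile window length does not match analysis window")
  # smooth the noise spectrum over ~smoothing_hz of bandwidth
  bin_hz <- fs / plan$n_win
  width <- max(1L, round(smoothing_hz / bin_hz))
  noise_mag <- moving_average(profile$magnitude, width)
  in_band <- (plan$freq >= band_hz[1] & plan$freq <= band_hz[2]) |
    (plan$freq >= fs - band_hz[2] & plan$freq <= fs - band_hz[1])
  n <- length(rec$samples)
  pad <- plan$hop
  xp <- c(numeric(pad), rec$samples, numeric(plan$n_win))
  starts <- seq(1L, length(xp) - plan$n_win + 1L, by = plan$hop)
  y <- numeric(length(xp))
  wsum <- numeric(length(xp))
  for (s in starts) {
    idx <- s:(s + plan$n_win - 1L)
    X <- stats::fft(xp[idx] * plan$window)
    mag <- Mod(X)
    sub <- mag
    sub[in_band] <- pmax(mag[in_band] - oversubtraction * noise_mag[in_band],
                         floor_coef * noise_mag[in_band])
    Y <- sub * exp(1i * Arg(X))
    y[idx] <- y[idx] + Re(stats::fft(Y, inverse = TRUE)) / plan$n_win
    wsum[idx] <- wsum[idx] + plan$window
  }
  out <- y[(pad + 1L):(pad + n)] / pmax(wsum[(pad + 1L):(pad + n)], 1e-8)
  out <- pmin(pmax(out, -1), 1)
  audio_recording(out, fs, rec$subject_id, rec$bit_depth)
}

# Frame power in dB for 10 ms frames, plus the energy-based voice-activity
# split: active frames are those within 25 dB of the 95th-percentile frame
# level. Returns NULL-free list(frame_db, active, silent, indeterminate).
vad_frames <- function(rec, frame_s = 0.01, rel_threshold_db = 25) {
  fs <- rec$sample_rate_hz
  w <- max(1L, round(frame_s * fs))
  n_frames <- floor(length(rec$samples) / w)
  if (n_frames < 2L)
    return(list(frame_db = numeric(0), active = logical(0),
                silent = logical(0), indeterminate = TRUE))
  m <- matrix(rec$samples[seq_len(n_frames * w)], nrow = w)
  p <- colMeans(m^2)
  frame_db <- 10 * log10(pmax(p, 1e-30))
  thr <- stats::quantile(frame_db, 0.95, names = FALSE) - rel_threshold_db
  active <- frame_db > thr
  silent <- !active
  indeterminate <- !any(silent) || !any(active)
  if (indeterminate && stats::sd(frame_db) > 1e-9) {
    # fall back to a bimodal two-means split of the frame levels; only
    # trusted when the two modes are clearly separated
    km <- suppressWarnings(stats::kmeans(frame_db, centers = 2, nstart = 3))
    lo <- which.min(km$centers)
    if (abs(diff(range(km$centers))) > 6) {
      silent <- km$cluster == lo
      active <- !silent
      indeterminate <- FALSE
    }
  }
  list(frame_db = frame_db, active = active, silent = silent,
       indeterminate = indeterminate)
}

#' Estimate the signal-to-noise ratio of a recording
#'
#' Energy-based voice-activity detection on 10 ms frames (threshold 25 dB
#' below the 95th-percentile frame level, with a bimodal fallback split
#' when that rule leaves no silent frames); SNR is
#' \eqn{10\log_{10}} (mean active-frame power / mean silent-frame power),
#' capped at +60 dB. When no speech/silence split can be found the result
#' is `NA` with attribute `reason = "indeterminate"`.
#'
#' @param rec An `audio_recording`.
#' @return SNR in dB (possibly `NA` flagged indeterminate).
#' @export
compute_snr <- function(rec) {
  v <- vad_frames(rec)
  if (v$indeterminate) {
    out <- NA_real_
    attr(out, "reason") <- "indeterminate"
    return(out)
  }
  w <- max(1L, round(0.01 * rec$sample_rate_hz))
  n_frames <- length(v$frame_db)
  m <- matrix(rec$samples[seq_len(n_frames * w)], nrow = w)
  p <- colMeans(m^2)
  p_active <- mean(p[v$active])
  p_silent <- mean(p[v$silent])
  if (p_silent <= 0) return(60)
  min(10 * log10(p_active / p_silent), 60)
}

#' Fraction of clipped samples
#'
#' A sample is counted as clipped when its magnitude reaches 99.9% of full
#' scale.
#'
#' @param rec An `audio_recording`.
#' @return Fraction in `[0, 1]`.
#' @export
detect_clipping <- function(rec) {
  mean(abs(rec$samples) >= 0.999)
}

#' Quality-control decision rule
#'
#' The pure decision underlying [qc_gate()]: a recording passes iff
#' `snr_db > snr_min_db` (strictly, so the boundary fails) and
#' `clipping_fraction < clip_max` (strictly). An `NA` SNR counts as a
#' failure with reason `"SNR indeterminate"`.
#'
#' @param snr_db Estimated SNR in dB (may be `NA`).
#' @param clipping_fraction Fraction of clipped samples.
#' @param snr_min_db,clip_max Thresholds.
#' @return Character vector of failure reasons (empty = pass).
#' @export
qc_decision <- function(snr_db, clipping_fraction, snr_min_db = 30,
                        clip_max = 0.01) {
  reasons <- character(0)
  if (is.na(snr_db)) {
    reasons <- c(reasons, "SNR indeterminate")
  } else if (!(snr_db > snr_min_db)) {
    reasons <- c(reasons, "SNR")
  }
  if (!(clipping_fraction < clip_max)) reasons <- c(reasons, "clipping")
  reasons
}

#' Quality-control gate for a recording
#'
#' A recording passes iff its estimated SNR exceeds `snr_min_db` (strictly)
#' and its clipped-sample fraction is below `clip_max` (strictly). The
#' defaults are the screening thresholds for laboratory passage readings:
#' SNR > 30 dB and clipping < 1% of samples. Failures are reported, never
#' raised.
#'
#' @param rec An `audio_recording`.
#' @param snr_min_db SNR threshold in dB (boundary fails).
#' @param clip_max Clipping-fraction threshold (boundary fails).
#' @return An object of class `qc_report`: `snr_db`, `clipping_fraction`,
#'   `passed`, `reasons`.
#' @export
qc_gate <- function(rec, snr_min_db = 30, clip_max = 0.01) {
  snr <- compute_snr(rec)
  clip <- detect_clipping(rec)
  reasons <- qc_decision(snr, clip, snr_min_db, clip_max)
  structure(
    list(subject_id = rec$subject_id, snr_db = as.numeric(snr),
         clipping_fraction = clip, passed = length(reasons) == 0L,
         reasons = reasons),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: SNR %.1f dB, clipping %.3f%% -> %s%s\n",
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              x$snr_db, 100 * x$clipping_fraction,
              if (x$passed) "PASS" else "FAIL",
              if (length(x$reasons)) paste0(" (", paste(x$reasons, collapse = ", "), ")") else ""))
  invisible(x)
}
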