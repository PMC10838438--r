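#' Track the fundamental frequency contour
#'
#' Autocorrelation-based pitch tracking: 40 ms analysis frames at a 10 ms
#' hop; per frame the normalized autocorrelation is evaluated (via FFT)
#' over lags in the `f_range_hz` search range, the best peak is refined by
#' parabolic interpolation, and a small octave cost favours the shorter
#' lag when two octaves correlate equally well. A frame is voiced when its
#' refined autocorrelation peak reaches `voicing_threshold` and the frame
#' has non-negligible energy.
#'
#' @param rec An `audio_recording`.
#' @param f_range_hz Pitch search range in Hz.
#' @param frame_s Analysis window length (s).
#' @param hop_s Hop between frames (s).
#' @param voicing_threshold Minimum normalized autocorrelation for voicing.
#' @return A data.frame with columns `time` (frame centre, s), `f0`
#'   (Hz, `NA` when unvoiced), `voiced`, `r` (autocorrelation peak).
#' @export
track_f0 <- function(rec, f_range_hz = c(75, 500), frame_s = 0.04,
                     hop_s = 0.01, voicing_threshold = 0.45) {
  stopifnot(inherits(rec, "audio_recording"))
  fs <- rec$sample_rate_hz
  w <- round(frame_s * fs)
  hop <- max(1L, round(hop_s * fs))
  x <- rec$samples
  lag_min <- max(2L, floor(fs / f_range_hz[2]))
  lag_max <- min(w - 2L, ceiling(fs / f_range_hz[1]))
  starts <- seq(1L, max(1L, length(x) - w + 1L), by = hop)
  nfft <- 2^ceiling(log2(2L * w))
  rms_all <- vapply(starts, function(s) sqrt(mean(x[s:(s + w - 1L)]^2)),
                    numeric(1))
  rms_gate <- max(rms_all) * 1e-3 + 1e-12
  res <- lapply(seq_along(starts), function(k) {
    s <- starts[k]
    fr <- x[s:(s + w - 1L)]
    t_mid <- (s - 1L + w / 2) / fs
    if (rms_all[k] < rms_gate)
      return(c(t_mid, NA, 0, 0))
    fr <- fr - mean(fr)
    ac <- Re(stats::fft(Mod(stats::fft(c(fr, numeric(nfft - w))))^2,
                        inverse = TRUE))[1:(lag_max + 2L)] / nfft
    # normalized ACF with exact per-lag energy terms (rectangular window)
    cs <- cumsum(fr^2)
    lags <- lag_min:lag_max
    e0 <- cs[w - lags]                 # energy of x[1 .. w-L]
    e1 <- cs[w] - cs[lags]             # energy of x[L+1 .. w]
    r <- ac[lags + 1L] / sqrt(pmax(e0 * e1, 1e-30))
    score <- r - 0.01 * log2(lags / lag_min)
    i <- which.max(score)
    L <- lags[i]
    # subharmonic correction: prefer half the lag when it correlates
    # nearly as well (guards against octave-down errors under jitter)
    repeat {
      L2 <- round(L / 2)
      i2 <- L2 - lag_min + 1L
      if (L2 < lag_min || i2 < 1L || r[i2] <= 0.75 * r[i]) break
      i <- i2; L <- lags[i]
    }
    # parabolic refinement of both location and peak value
    if (i > 1L && i < length(lags)) {
      y1 <- r[i - 1L]; y2 <- r[i]; y3 <- r[i + 1L]
      denom <- y1 - 2 * y2 + y3
      delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
      delta <- max(min(delta, 0.5), -0.5)
      r_pk <- y2 - 0.25 * (y1 - y3) * delta
    } else {
      delta <- 0; r_pk <- r[i]
    }
    f0 <- fs / (L + delta)
    voiced <- r_pk >= voicing_threshold && f0 >= f_range_hz[1] &&
      f0 <= f_range_hz[2]
    c(t_mid, if (voiced) f0 else NA, as.numeric(voiced), min(r_pk, 1))
  })
  m <- do.call(rbind, res)
  data.frame(time = m[, 1], f0 = m[, 2], voiced = m[, 3] > 0.5, r = m[, 4])
}

#' Extract glottal pulse marks from a recording
#'
#' Places cycle marks at amplitude-envelope peaks spaced by the local
#' pitch period predicted from the F0 contour, refining each mark to
#' sub-sample precision by parabolic interpolation of the smoothed
#' envelope. Per-cycle amplitudes are waveform peak magnitudes near each
#' mark.
#'
#' @param rec An `audio_recording`.
#' @param f0_contour Output of [track_f0()]; at least 3 voiced frames.
#' @return An object of class `pulse_sequence`: `times` (s, strictly
#'   increasing), `periods` (s, length `length(times) - 1`), `amplitudes`
#'   (> 0, one per pulse). When fewer than 3 pulses can be placed the
#'   result carries `missing = TRUE`.
#' @export
extract_pulses <- function(rec, f0_contour = track_f0(rec)) {
  fs <- rec$sample_rate_hz
  x <- rec$samples
  voiced <- which(f0_contour$voiced)
  empty <- structure(list(times = numeric(0), periods = numeric(0),
                          amplitudes = numeric(0), missing = TRUE),
                     class = "pulse_sequence")
  if (length(voiced) < 3L) return(empty)
  # smooth amplitude envelope: analytic-signal magnitude, low-passed
  nfft <- 2^ceiling(log2(length(x)))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  h <- numeric(nfft); h[1] <- 1
  h[2:(nfft / 2)] <- 2; h[nfft / 2 + 1] <- 1
  env <- Mod(stats::fft(X * h, inverse = TRUE) / nfft)[seq_along(x)]
  # keep the envelope's f0-rate modulation, suppress formant ringing
  f0_med <- stats::median(f0_contour$f0[voiced], na.rm = TRUE)
  cutoff <- min(600, 1.4 * f0_med)
  bf <- signal::butter(2, min(0.99, cutoff / (fs / 2)))
  env <- as.numeric(signal::filtfilt(bf, env))
  # median-smoothed contour guards the period prediction against isolated
  # octave errors in single frames
  f0_v <- f0_contour$f0[voiced]
  if (length(f0_v) >= 5L) f0_v <- stats::runmed(f0_v, 5)
  period_at <- function(t) {
    f <- stats::approx(f0_contour$time[voiced], f0_v, xout = t, rule = 2)$y
    1 / f
  }
  refine <- function(i) {
    if (i <= 1L || i >= length(env)) return(as.numeric(i))
    y1 <- env[i - 1L]; y2 <- env[i]; y3 <- env[i + 1L]
    denom <- y1 - 2 * y2 + y3
    d <- if (abs(denom) > 1e-15) 0.5 * (y1 - y3) / denom else 0
    i + max(min(d, 0.5), -0.5)
  }
  t_lo <- f0_contour$time[voiced[1]] - 0.02
  t_hi <- f0_contour$time[voiced[length(voiced)]] + 0.02
  i_lo <- max(1L, floor(t_lo * fs)); i_hi <- min(length(x), ceiling(t_hi * fs))
  seed_i <- i_lo - 1L + which.max(env[i_lo:i_hi])
  env_gate <- 0.1 * env[seed_i]
  step <- function(from_i, dir) {
    marks <- integer(0)
    cur <- from_i
    repeat {
      T_samp <- period_at(cur / fs) * fs
      ctr <- cur + dir * T_samp
      w0 <- max(i_lo, round(ctr - 0.3 * T_samp))
      w1 <- min(i_hi, round(ctr + 0.3 * T_samp))
      if (w0 >= w1) break
      nxt <- w0 - 1L + which.max(env[w0:w1])
      if (env[nxt] < env_gate) break
      if (dir > 0 && nxt <= cur) break
      if (dir < 0 && nxt >= cur) break
      marks <- c(marks, nxt)
      cur <- nxt
    }
    marks
  }
  right <- step(seed_i, +1)
  left <- step(seed_i, -1)
  marks <- sort(unique(c(rev(left), seed_i, right)))
  if (length(marks) < 3L) return(empty)
  times <- vapply(marks, refine, numeric(1)) / fs
  half <- round(stats::median(diff(marks)) / 4)
  amps <- vapply(marks, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    a <- abs(x[lo:hi])
    j <- which.max(a)
    y2 <- a[j]
    # parabolic refinement of the peak value removes sampling-phase ripple
    if (j > 1L && j < length(a)) {
      y1 <- a[j - 1L]; y3 <- a[j + 1L]
      denom <- y1 - 2 * y2 + y3
      if (abs(denom) > 1e-15) {
        d <- max(min(0.5 * (y1 - y3) / denom, 0.5), -0.5)
        y2 <- y2 - 0.25 * (y1 - y3) * d
      }
    }
    y2
  }, numeric(1))
  keep <- amps > 0
  times <- times[keep]; amps <- amps[keep]
  if (length(times) < 3L) return(empty)
  structure(list(times = times, periods = diff(times), amplitudes = amps,
                 missing = FALSE),
            class = "pulse_sequence")
}
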