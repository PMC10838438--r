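#' Specification for a synthetic vowel-like voice
#'
#' Describes a sustained, vowel-like phonation: an impulse-excited
#' two-formant resonator driven by a glottal pulse train with controllable
#' cycle-to-cycle period perturbation (jitter), amplitude perturbation
#' (shimmer), additive noise, and scheduled silences. Perturbations are
#' i.i.d. Gaussian per cycle, truncated at three standard deviations, which
#' matches the perturbation-quotient definitions the extractor implements.
#'
#' @param f0_hz Target fundamental frequency (Hz).
#' @param duration_s Duration in seconds (> 0).
#' @param jitter_pct Cycle-to-cycle period perturbation, percent of the mean
#'   period (>= 0).
#' @param shimmer_pct Cycle-to-cycle amplitude perturbation, percent of the
#'   mean amplitude (>= 0).
#' @param noise_snr_db Additive white-noise SNR in dB; `NULL` for clean.
#' @param pause_schedule List of `c(onset_s, length_s)` silences; must lie
#'   within `[0, duration_s]` and not overlap.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param seed Integer seed; synthesis is deterministic given the spec.
#' @return An object of class `voice_spec`.
#' @export
voice_spec <- function(f0_hz = 150, duration_s = 1, jitter_pct = 0,
                       shimmer_pct = 0, noise_snr_db = NULL,
                       pause_schedule = list(), sample_rate_hz = 44100L,
                       seed = 1L) {
  if (duration_s <= 0) stop("voice_spec: duration_s must be > 0")
  if (jitter_pct < 0 || shimmer_pct < 0)
    stop("voice_spec: jitter_pct and shimmer_pct must be >= 0")
  if (f0_hz <= 0) stop("voice_spec: f0_hz must be > 0")
  if (length(pause_schedule)) {
    ivs <- do.call(rbind, lapply(pause_schedule, function(p) {
      if (length(p) != 2L) stop("voice_spec: each pause is c(onset_s, length_s)")
      c(p[1], p[1] + p[2])
    }))
    if (any(ivs[, 1] < 0) || any(ivs[, 2] > duration_s))
      stop("voice_spec: pause outside [0, duration_s]")
    o <- order(ivs[, 1])
    if (nrow(ivs) > 1L && any(ivs[o, 1][-1] < ivs[o, 2][-nrow(ivs)]))
      stop("voice_spec: pauses overlap")
  }
  structure(
    list(f0_hz = f0_hz, duration_s = duration_s, jitter_pct = jitter_pct,
         shimmer_pct = shimmer_pct, noise_snr_db = noise_snr_db,
         pause_schedule = pause_schedule,
         sample_rate_hz = as.integer(sample_rate_hz), seed = as.integer(seed)),
    class = "voice_spec"
  )
}

# Cascade of two-pole resonators approximating an open-vowel vocal tract.
resonator_cascade <- function(x, fs, formants = c(700, 1200),
                              bandwidths = c(90, 120)) {
  for (k in seq_along(formants)) {
    r <- exp(-pi * bandwidths[k] / fs)
    th <- 2 * pi * formants[k] / fs
    x <- stats::filter(x, filter = c(2 * r * cos(th), -r^2),
                       method = "recursive")
  }
  as.numeric(x)
}

#' Synthesize a vowel-like voice from a specification
#'
#' Builds a glottal pulse train with the requested mean period, perturbs
#' each cycle's period and amplitude per `jitter_pct`/`shimmer_pct`, excites
#' a two-formant resonator (~700/1200 Hz) so harmonicity and intensity
#' features behave speech-like, inserts scheduled silences, and optionally
#' adds white noise at a target SNR. Pulses are placed with sub-sample
#' timing (a narrow Gaussian pulse evaluated at its real-valued centre) so
#' that period quantization does not masquerade as jitter. Peak amplitude
#' is normalized to 0.9.
#'
#' @param spec A [voice_spec()].
#' @return An `audio_recording`; deterministic for a fixed spec.
#' @export
#' @examples
#' rec <- synthesize_voice(voice_spec(f0_hz = 150, duration_s = 0.5))
#' duration_s(rec)
synthesize_voice <- function(spec) {
  stopifnot(inherits(spec, "voice_spec"))
  fs <- spec$sample_rate_hz
  n <- round(spec$duration_s * fs)
  with_seed(spec$seed, {
    t0 <- 1 / spec$f0_hz
    n_pulses_max <- ceiling(spec$duration_s / t0) + 8L
    periods <- t0 * (1 + spec$jitter_pct / 100 * rnorm_trunc3(n_pulses_max))
    amps <- 1 + spec$shimmer_pct / 100 * rnorm_trunc3(n_pulses_max)
    amps <- pmax(amps, 0.05)
    times <- t0 / 2 + cumsum(c(0, periods))
    keep <- times < spec$duration_s - t0 / 4
    times <- times[keep]
    amps <- amps[seq_along(times)]
    # narrow Gaussian glottal pulse at real-valued centres
    sigma <- 2e-4
    half_w <- ceiling(4 * sigma * fs)
    x <- numeric(n)
    for (k in seq_along(times)) {
      c_idx <- times[k] * fs + 1
      idx <- max(1L, floor(c_idx - half_w)):min(n, ceiling(c_idx + half_w))
      tt <- (idx - c_idx) / fs
      x[idx] <- x[idx] + amps[k] * exp(-0.5 * (tt / sigma)^2)
    }
    x <- resonator_cascade(x, fs)
    for (p in spec$pause_schedule) {
      i0 <- max(1L, floor(p[1] * fs) + 1L)
      i1 <- min(n, floor((p[1] + p[2]) * fs))
      if (i1 >= i0) x[i0:i1] <- 0
    }
    x <- 0.9 * x / max(abs(x))
    if (!is.null(spec$noise_snr_db)) {
      p_sig <- mean(x^2)
      p_noise <- p_sig / 10^(spec$noise_snr_db / 10)
      x <- x + stats::rnorm(n, sd = sqrt(p_noise))
      x <- x / max(1, max(abs(x)))
    }
    audio_recording(x, fs, subject_id = "synthetic", bit_depth = 16L)
  })
}

#' Corrupt a recording with additive noise and/or clipping
#'
#' Stresses the downstream quality-control gates. Noise is white Gaussian
#' scaled so signal-power / noise-power equals `noise_snr_db`; clipping
#' saturates the loudest samples until the stated fraction sits at full
#' scale. The clean and noise components are attached as attributes
#' `"clean"` and `"noise"` so tests can measure the realized power ratio
#' directly. With both options absent the input is returned unchanged.
#'
#' @param rec An `audio_recording`.
#' @param noise_snr_db Target SNR in dB, or `NULL` for no added noise.
#' @param clip_fraction Fraction of samples to saturate in `[0, 1]`, or
#'   `NULL` for none.
#' @param seed Integer seed for the noise draw.
#' @return A corrupted `audio_recording`.
#' @export
corrupt_audio <- function(rec, noise_snr_db = NULL, clip_fraction = NULL,
                          seed = 1L) {
  stopifnot(inherits(rec, "audio_recording"))
  if (!is.null(clip_fraction) &&
      (clip_fraction < 0 || clip_fraction > 1))
    stop("corrupt_audio: clip_fraction must be in [0, 1]")
  if (is.null(noise_snr_db) && is.null(clip_fraction)) return(rec)
  x <- rec$samples
  clean <- x
  noise <- numeric(length(x))
  if (!is.null(noise_snr_db)) {
    p_sig <- mean(x^2)
    p_noise <- p_sig / 10^(noise_snr_db / 10)
    noise <- with_seed(seed, stats::rnorm(length(x), sd = sqrt(p_noise)))
    x <- x + noise
    sc <- max(1, max(abs(x)))
    x <- x / sc; clean <- clean / sc; noise <- noise / sc
  }
  if (!is.null(clip_fraction) && clip_fraction > 0) {
    thr <- stats::quantile(abs(x), 1 - clip_fraction, names = FALSE)
    x <- pmin(pmax(x / thr, -1), 1)
  }
  out <- audio_recording(x, rec$sample_rate_hz, rec$subject_id, rec$bit_depth)
  attr(out, "clean") <- clean
  attr(out, "noise") <- noise
  out
}
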