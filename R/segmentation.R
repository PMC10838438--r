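#' Segment a recording into speech and pause intervals
#'
#' Energy-based segmentation on 10 ms frames: sub-threshold runs of at
#' least `min_pause_s` become pauses; shorter dips are absorbed into the
#' surrounding speech. Speech and pause segments tile `[0, duration)`
#' without overlap. Syllable nuclei are local maxima of the smoothed
#' intensity contour within speech segments with at least
#' `nucleus_prominence_db` of prominence.
#'
#' @param rec An `audio_recording`.
#' @param min_pause_s Minimum pause length in seconds.
#' @param frame_s Analysis frame length in seconds.
#' @param nucleus_prominence_db Minimum intensity-peak prominence (dB) for
#'   a syllable nucleus.
#' @return An object of class `segmentation_result`: data.frames
#'   `speech` and `pauses` with columns `start`, `end` (half-open, s),
#'   `nuclei` (times, s), `duration` (s), `frame_s`.
#' @export
segment_speech_pauses <- function(rec, min_pause_s = 0.15, frame_s = 0.01,
                                  nucleus_prominence_db = 2) {
  dur <- duration_s(rec)
  v <- vad_frames(rec, frame_s = frame_s)
  n_frames <- length(v$frame_db)
  empty <- function() {
    structure(list(speech = data.frame(start = numeric(0), end = numeric(0)),
                   pauses = data.frame(start = 0, end = dur),
                   nuclei = numeric(0), duration = dur, frame_s = frame_s),
              class = "segmentation_result")
  }
  if (n_frames < 1L || max(abs(rec$samples)) < 1e-12) return(empty())
  # indeterminate split on a non-silent input means unbroken activity
  speech_frame <- if (v$indeterminate) rep(TRUE, n_frames) else v$active
  if (!any(speech_frame)) return(empty())
  min_run <- max(1L, round(min_pause_s / frame_s))
  r <- rle(speech_frame)
  # absorb sub-minimum silence runs into speech
  r$values[!r$values & r$lengths < min_run] <- TRUE
  speech_frame <- inverse.rle(r)
  r <- rle(speech_frame)
  ends_f <- cumsum(r$lengths)
  starts_f <- ends_f - r$lengths
  seg_start <- starts_f * frame_s
  seg_end <- ends_f * frame_s
  seg_end[length(seg_end)] <- dur # last segment absorbs the partial frame
  speech <- data.frame(start = seg_start[r$values], end = seg_end[r$values])
  pauses <- data.frame(start = seg_start[!r$values], end = seg_end[!r$values])
  # syllable nuclei: prominent peaks of the smoothed intensity contour
  db <- moving_average(v$frame_db, 3L)
  t_frame <- (seq_len(n_frames) - 0.5) * frame_s
  nuclei <- numeric(0)
  for (si in seq_len(nrow(speech))) {
    idx <- which(t_frame >= speech$start[si] & t_frame < speech$end[si])
    if (length(idx) < 3L) {
      if (length(idx) >= 1L) nuclei <- c(nuclei, t_frame[idx[which.max(db[idx])]])
      next
    }
    y <- db[idx]
    pk <- which(diff(sign(diff(y))) < 0) + 1L
    if (!length(pk)) {
      nuclei <- c(nuclei, t_frame[idx[which.max(y)]])
      next
    }
    for (p in pk) {
      # prominence: drop to the higher of the two flanking minima before a
      # taller point is reached (segment-bounded)
      left <- y[seq_len(p - 1L)]
      right <- y[(p + 1L):length(y)]
      taller_l <- which(left >= y[p])
      base_l <- if (length(taller_l)) min(left[(max(taller_l)):(p - 1L)]) else min(left)
      taller_r <- which(right >= y[p])
      base_r <- if (length(taller_r)) min(right[seq_len(min(taller_r))]) else min(right)
      prom <- y[p] - max(base_l, base_r)
      if (prom >= nucleus_prominence_db) nuclei <- c(nuclei, t_frame[idx[p]])
    }
  }
  structure(list(speech = speech, pauses = pauses, nuclei = sort(nuclei),
                 duration = dur, frame_s = frame_s),
            class = "segmentation_result")
}

#' Timing and rate features from a segmentation
#'
#' The 21 timing/rate features: total duration, speech and pause time,
#' phonation ratio (speech time / total), pause rate (pauses per second),
#' pause counts overall and by length class (short 0.15-0.5 s, medium
#' 0.5-1.0 s, long > 1.0 s), pause duration statistics, speech-segment
#' count and duration statistics, speech rate (syllables per second of
#' total time), articulation rate (syllables per second of speech time),
#' syllable count, and the mean and variance of word-unit durations
#' (speech-chunk durations standing in for words).
#'
#' @param seg A `segmentation_result`.
#' @param total_duration_s Total duration (s); defaults to the
#'   segmentation's duration.
#' @return Named list of the 21 timing/rate features; rates are `NA` when
#'   there is no speech time.
#' @export
timing_rate_metrics <- function(seg, total_duration_s = seg$duration) {
  pd <- seg$pauses$end - seg$pauses$start
  sdur <- seg$speech$end - seg$speech$start
  speech_time <- sum(sdur)
  pause_time <- sum(pd)
  n_syll <- length(seg$nuclei)
  var0 <- function(x) if (length(x) > 1L) stats::var(x) else 0
  list(
    total_duration = total_duration_s,
    speech_time = speech_time,
    pause_time = pause_time,
    phonation_ratio = speech_time / total_duration_s,
    pause_rate = length(pd) / total_duration_s,
    n_pauses = length(pd),
    n_pauses_short = sum(pd < 0.5),
    n_pauses_medium = sum(pd >= 0.5 & pd < 1.0),
    n_pauses_long = sum(pd >= 1.0),
    pause_mean_dur = if (length(pd)) mean(pd) else 0,
    pause_var_dur = var0(pd),
    pause_max_dur = if (length(pd)) max(pd) else 0,
    n_speech_segments = length(sdur),
    speech_seg_mean_dur = if (length(sdur)) mean(sdur) else 0,
    speech_seg_var_dur = var0(sdur),
    speech_seg_max_dur = if (length(sdur)) max(sdur) else 0,
    speech_rate = if (speech_time > 0) n_syll / total_duration_s else NA_real_,
    articulation_rate = if (speech_time > 0) n_syll / speech_time else NA_real_,
    syllable_count = as.numeric(n_syll),
    word_dur_mean = if (length(sdur)) mean(sdur) else NA_real_,
    word_dur_var = if (length(sdur)) var0(sdur) else NA_real_
  )
}
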