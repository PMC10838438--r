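#' Fundamental-frequency distribution statistics
#'
#' Summaries of the voiced part of an F0 contour.
#'
#' @param f0_contour Output of [track_f0()].
#' @return Named list `mean`, `median`, `min`, `max`, `range`, `variance`,
#'   `sd` in Hz (Hz^2 for `variance`); all `NA` with no voiced frames.
#' @export
f0_statistics <- function(f0_contour) {
  f0 <- f0_contour$f0[f0_contour$voiced]
  f0 <- f0[is.finite(f0)]
  if (!length(f0))
    return(list(mean = NA_real_, median = NA_real_, min = NA_real_,
                max = NA_real_, range = NA_real_, variance = NA_real_,
                sd = NA_real_))
  list(mean = mean(f0), median = stats::median(f0), min = min(f0),
       max = max(f0), range = max(f0) - min(f0),
       variance = if (length(f0) > 1L) stats::var(f0) else 0,
       sd = if (length(f0) > 1L) stats::sd(f0) else 0)
}

#' Extract the full 53-feature acoustic set from a recording
#'
#' Runs the pitch tracker, pulse extractor, perturbation, harmonicity,
#' intensity, zero-crossing and timing/rate extractors and assembles the
#' manifest-ordered feature vector. Features whose prerequisites are
#' unavailable (e.g. phonatory measures of an unvoiced recording) are
#' returned as `NA` and flagged in the `missing` attribute. Extraction is
#' deterministic.
#'
#' @param rec A QC-passed `audio_recording`.
#' @param manifest Feature manifest data.frame (see [feature_manifest()]).
#' @return Named numeric vector of length `nrow(manifest)` in manifest
#'   order, with a logical `missing` attribute.
#' @export
#' @examples
#' rec <- synthesize_voice(voice_spec(duration_s = 0.6))
#' fv <- extract_features(rec)
#' length(fv)  # 53
extract_features <- function(rec, manifest = feature_manifest()) {
  stopifnot(inherits(rec, "audio_recording"))
  f0c <- track_f0(rec)
  pulses <- extract_pulses(rec, f0c)
  jit <- jitter_metrics(pulses)
  shi <- shimmer_metrics(pulses)
  har <- harmonicity_metrics(rec, f0c)
  f0s <- f0_statistics(f0c)
  int <- intensity_metrics(rec)
  zcr <- zcr_metrics(rec)
  seg <- segment_speech_pauses(rec)
  tim <- timing_rate_metrics(seg)
  vals <- c(
    jitter_local = jit$local, jitter_local_absolute = jit$local_absolute,
    jitter_rap = jit$rap, jitter_ppq5 = jit$ppq5, jitter_ddp = jit$ddp,
    shimmer_local = shi$local, shimmer_local_db = shi$local_db,
    shimmer_apq3 = shi$apq3, shimmer_apq5 = shi$apq5,
    shimmer_apq11 = shi$apq11, shimmer_dda = shi$dda,
    hnr_mean = har$hnr_mean, hnr_sd = har$hnr_sd, ac_mean = har$ac_mean,
    cc_mean = har$cc_mean, nhr_mean = har$nhr_mean,
    f0_mean = f0s$mean, f0_median = f0s$median, f0_min = f0s$min,
    f0_max = f0s$max, f0_range = f0s$range, f0_var = f0s$variance,
    f0_sd = f0s$sd,
    int_mean = int$mean, int_median = int$median, int_min = int$min,
    int_max = int$max, int_range = int$range, int_var = int$variance,
    int_sd = int$sd,
    zcr_mean = zcr$mean, zcr_var = zcr$variance,
    total_duration = tim$total_duration, speech_time = tim$speech_time,
    pause_time = tim$pause_time, phonation_ratio = tim$phonation_ratio,
    pause_rate = tim$pause_rate, n_pauses = tim$n_pauses,
    n_pauses_short = tim$n_pauses_short,
    n_pauses_medium = tim$n_pauses_medium,
    n_pauses_long = tim$n_pauses_long,
    pause_mean_dur = tim$pause_mean_dur, pause_var_dur = tim$pause_var_dur,
    pause_max_dur = tim$pause_max_dur,
    n_speech_segments = tim$n_speech_segments,
    speech_seg_mean_dur = tim$speech_seg_mean_dur,
    speech_seg_var_dur = tim$speech_seg_var_dur,
    speech_seg_max_dur = tim$speech_seg_max_dur,
    speech_rate = tim$speech_rate, articulation_rate = tim$articulation_rate,
    syllable_count = tim$syllable_count,
    word_dur_mean = tim$word_dur_mean, word_dur_var = tim$word_dur_var
  )
  nm <- feature_names(manifest)
  miss_nm <- setdiff(nm, names(vals))
  if (length(miss_nm))
    stop("extract_features: manifest names not produced by extractors: ",
         paste(miss_nm, collapse = ", "))
  out <- vals[nm]
  attr(out, "missing") <- !is.finite(out)
  out
}

#' Extract features for several recordings into a cohort table
#'
#' @param recs List of `audio_recording` objects.
#' @param metadata Optional data.frame keyed by `subject_id` with columns
#'   such as `group`, `frs_bulb`, `sex` to join onto the feature rows.
#' @param manifest Feature manifest data.frame.
#' @return A data.frame with `subject_id` plus manifest feature columns
#'   (and metadata columns when supplied).
#' @export
extract_feature_table <- function(recs, metadata = NULL,
                                  manifest = feature_manifest()) {
  rows <- lapply(recs, function(r) {
    fv <- extract_features(r, manifest)
    cbind(data.frame(subject_id = r$subject_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(metadata)) {
    stopifnot("subject_id" %in% names(metadata))
    tab <- merge(metadata, tab, by = "subject_id", sort = FALSE)
  }
  tab
}
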