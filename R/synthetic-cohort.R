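#' Configuration for a synthetic feature-level cohort
#'
#' Describes a two-group cohort (controls and ALS) at the feature level:
#' group sizes, the FRS-bulbar score distribution of the ALS group, sex
#' composition, per-feature standardized group differences, and the
#' within-category feature correlation. The default configuration mirrors
#' the reference study cohort: 119 ALS (47 female) vs 22 controls
#' (12 female), FRS-bulbar median 11 with IQR 3, and the FRS missing in
#' 26/119 of ALS rows.
#'
#' Effect sign convention: a positive standardized difference means the
#' less-impaired group has the higher value.
#'
#' @param n_control,n_als Group sizes (each >= 2).
#' @param frs_median,frs_iqr Targets for the ALS FRS-bulbar distribution
#'   (scores 0-12, higher = less impaired).
#' @param sex_female_fraction Named numeric `c(control = ..., als = ...)`
#'   fractions of female participants.
#' @param frs_missing_fraction Fraction of ALS rows with missing FRS.
#' @param effect_map Named list/vector: feature name -> standardized mean
#'   difference between groups (positive = less-impaired higher).
#' @param rho Within-category feature correlation, `0 <= rho < 1`.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 22, n_als = 119, frs_median = 11,
                          frs_iqr = 3,
                          sex_female_fraction = c(control = 12 / 22,
                                                  als = 47 / 119),
                          frs_missing_fraction = 26 / 119,
                          effect_map = list(), rho = 0.5, seed = 1L) {
  if (n_control < 2 || n_als < 2) stop("cohort_config: group sizes must be >= 2")
  if (rho < 0 || rho >= 1) stop("cohort_config: rho must be in [0, 1)")
  effects <- unlist(effect_map)
  if (length(effects) && any(!is.finite(effects)))
    stop("cohort_config: effect sizes must be finite")
  valid <- feature_names()
  if (length(effects) && !all(names(effects) %in% valid))
    stop("cohort_config: unknown feature name(s) in effect_map: ",
         paste(setdiff(names(effects), valid), collapse = ", "),
         "\nValid names: ", paste(valid, collapse = ", "))
  structure(
    list(n_control = as.integer(n_control), n_als = as.integer(n_als),
         frs_median = frs_median, frs_iqr = frs_iqr,
         sex_female_fraction = sex_female_fraction,
         frs_missing_fraction = frs_missing_fraction,
         effect_map = as.list(effects), rho = rho, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' A realistic ALS-vs-control standardized effect pattern
#'
#' Standardized group differences (positive = less-impaired group higher)
#' mimicking the pattern reported for bulbar ALS connected speech: slowed
#' speech and articulation rate, longer and more frequent pauses, longer
#' word units, reduced loudness and F0 range, and raised perturbation
#' (jitter/shimmer) in the impaired group. Magnitudes are capped at 1.5.
#'
#' @return Named numeric vector of standardized mean differences.
#' @export
als_effect_map <- function() {
  c(speech_rate = 1.5, articulation_rate = 1.2, word_dur_mean = -1.3,
    pause_time = -1.2, n_pauses = -1.0, pause_mean_dur = -1.0,
    phonation_ratio = 1.0, int_mean = 0.8, int_median = 0.8,
    f0_range = 0.8, shimmer_local = -0.8, shimmer_apq11 = -0.6,
    jitter_local = -0.6)
}

# Draw n samples from a k-dimensional equicorrelated normal (unit
# variances, correlation rho).
rmvn_block <- function(n, k, rho) {
  if (k == 1L) return(matrix(stats::rnorm(n), ncol = 1))
  sigma <- matrix(rho, k, k); diag(sigma) <- 1
  MASS::mvrnorm(n, mu = rep(0, k), Sigma = sigma)
}

#' Generate a feature-level synthetic cohort
#'
#' Features are drawn from a multivariate normal with unit variances,
#' correlation `rho` within each manifest category and zero across
#' categories. ALS rows are shifted against the effect map: less-severe
#' ALS rows (FRS >= 11, the ALS-E stratum) receive 0.8 of the configured
#' standardized difference and more-severe rows (ALS-L) 1.2 of it, so
#' that severity strata are separable in proportion to the configured
#' effects while the overall control-ALS difference matches the map.
#' FRS-bulbar scores are integers in 0-12 drawn to match the configured
#' median/IQR, with the configured fraction missing; sex is assigned by
#' the per-group female fractions. Deterministic per seed.
#'
#' @param cfg A [cohort_config()].
#' @param manifest Feature manifest data.frame.
#' @return A data.frame: `subject_id`, `group` (`control`/`ALS`),
#'   `frs_bulb` (NA for controls and for missing), `sex` (`F`/`M`), then
#'   the 53 manifest feature columns.
#' @export
#' @examples
#' tab <- generate_cohort(cohort_config(n_control = 5, n_als = 8, seed = 2))
#' dim(tab)
generate_cohort <- function(cfg, manifest = feature_manifest()) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_control + cfg$n_als
  with_seed(cfg$seed, {
    group <- c(rep("control", cfg$n_control), rep("ALS", cfg$n_als))
    sex <- character(n)
    sex[group == "control"] <- ifelse(
      stats::runif(cfg$n_control) < cfg$sex_female_fraction[["control"]], "F", "M")
    sex[group == "ALS"] <- ifelse(
      stats::runif(cfg$n_als) < cfg$sex_female_fraction[["als"]], "F", "M")
    # FRS-bulbar: rounded normal matched to the target median/IQR
    frs <- rep(NA_real_, n)
    mu <- cfg$frs_median - 0.2
    sdv <- cfg$frs_iqr / 1.349
    frs_als <- pmin(12, pmax(0, round(stats::rnorm(cfg$n_als, mu, sdv))))
    n_miss <- round(cfg$frs_missing_fraction * cfg$n_als)
    if (n_miss > 0) frs_als[sample.int(cfg$n_als, n_miss)] <- NA
    frs[group == "ALS"] <- frs_als
    # impairment weight: control 0; ALS-E 0.8, ALS-L 1.2, unknown FRS 1.0
    g <- numeric(n)
    is_als <- group == "ALS"
    g[is_als] <- ifelse(is.na(frs[is_als]), 1.0,
                        ifelse(frs[is_als] >= 11, 0.8, 1.2))
    # block-correlated standard normal features
    feats <- matrix(0, n, nrow(manifest),
                    dimnames = list(NULL, manifest$name))
    for (cat in unique(manifest$category)) {
      idx <- which(manifest$category == cat)
      feats[, idx] <- rmvn_block(n, length(idx), cfg$rho)
    }
    for (f in names(cfg$effect_map)) {
      feats[, f] <- feats[, f] - cfg$effect_map[[f]] * g
    }
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = group, frs_bulb = frs, sex = sex,
      feats, stringsAsFactors = FALSE, check.names = FALSE
    )
  })
}

#' Generate a small audio-level cohort
#'
#' For integration tests: synthesizes one vowel-like recording per
#' subject from a template [voice_spec()], with the impaired (ALS) group's
#' spec modified by the audio effect analogues (multiplied jitter and
#' shimmer, lengthened pauses, reduced noise SNR). Per-subject F0 varies
#' by ~5% around the template.
#'
#' @param cfg A [cohort_config()] (keep the group sizes small).
#' @param template A [voice_spec()] used for every subject.
#' @param audio_effects List with any of `jitter_mult`, `shimmer_mult`,
#'   `pause_mult` (multiplies pause lengths), `noise_snr_delta_db`
#'   (subtracted from the template SNR) applied to the ALS group.
#' @return A list with one element per subject:
#'   `list(rec, subject_id, group)`.
#' @export
generate_audio_cohort <- function(cfg, template = voice_spec(),
                                  audio_effects = list()) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(template, "voice_spec"))
  jm <- audio_effects$jitter_mult %||% 1
  sm <- audio_effects$shimmer_mult %||% 1
  pm <- audio_effects$pause_mult %||% 1
  nd <- audio_effects$noise_snr_delta_db %||% 0
  n <- cfg$n_control + cfg$n_als
  group <- c(rep("control", cfg$n_control), rep("ALS", cfg$n_als))
  lapply(seq_len(n), function(i) {
    s <- derive_seed(cfg$seed, paste0("audio", i))
    f0_i <- with_seed(s, template$f0_hz * stats::runif(1, 0.95, 1.05))
    impaired <- group[i] == "ALS"
    pauses <- template$pause_schedule
    if (impaired && pm != 1 && length(pauses)) {
      pauses <- lapply(pauses, function(p) {
        len <- min(p[2] * pm, template$duration_s - p[1])
        c(p[1], len)
      })
    }
    spec <- voice_spec(
      f0_hz = f0_i, duration_s = template$duration_s,
      jitter_pct = template$jitter_pct * (if (impaired) jm else 1),
      shimmer_pct = template$shimmer_pct * (if (impaired) sm else 1),
      noise_snr_db = if (is.null(template$noise_snr_db)) NULL else
        template$noise_snr_db - (if (impaired) nd else 0),
      pause_schedule = pauses,
      sample_rate_hz = template$sample_rate_hz, seed = s
    )
    rec <- synthesize_voice(spec)
    rec$subject_id <- sprintf("A%03d", i)
    list(rec = rec, subject_id = rec$subject_id, group = group[i])
  })
}

#' Write / read a cohort table as CSV
#'
#' Columns: `subject_id`, `group`, `frs_bulb`, `sex`, then the manifest
#' feature columns in manifest order.
#'
#' @param table A cohort data.frame as produced by [generate_cohort()].
#' @param path Output path.
#' @return `path` invisibly (`write_cohort_csv`); the table
#'   (`read_cohort_csv`).
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
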