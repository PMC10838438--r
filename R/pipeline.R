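#' Pipeline configuration
#'
#' End-to-end run settings. Defaults reproduce the reference analysis
#' conditions: QC thresholds SNR > 30 dB and clipping < 1%; spectral
#' subtraction with a 0.025 s window, 80 Hz-10 kHz suppression range,
#' 40 Hz smoothing and at least 0.25 s of noise sample; ten repeated
#' 50/50 splits with a Laplace(0.5) coefficient prior.
#'
#' @param input_mode `"audio"` (WAV directory + metadata CSV) or
#'   `"features"` (cohort feature CSV).
#' @param audio_dir Directory of mono WAV files (audio mode).
#' @param metadata_csv CSV with `subject_id`, `group`, `frs_bulb`, `sex`
#'   (audio mode).
#' @param feature_csv Cohort CSV as written by [write_cohort_csv()]
#'   (features mode).
#' @param snr_min_db,clip_max QC thresholds.
#' @param nr_window_s,nr_band_hz,nr_smoothing_hz,nr_min_noise_s Noise
#'   reduction settings.
#' @param manifest_path Optional path to an alternative feature manifest.
#' @param model A [model_config()].
#' @param n_reps Number of repeated splits per contrast.
#' @param seed Master seed; fans out to per-stage seeds.
#' @param out_dir Output directory for [export_report()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("features", "audio"),
                            audio_dir = NULL, metadata_csv = NULL,
                            feature_csv = NULL, snr_min_db = 30,
                            clip_max = 0.01, nr_window_s = 0.025,
                            nr_band_hz = c(80, 10000), nr_smoothing_hz = 40,
                            nr_min_noise_s = 0.25, manifest_path = NULL,
                            model = model_config(), n_reps = 10L,
                            seed = 1L, out_dir = "bulbarvoice_out") {
  input_mode <- match.arg(input_mode)
  structure(
    list(input_mode = input_mode, audio_dir = audio_dir,
         metadata_csv = metadata_csv, feature_csv = feature_csv,
         snr_min_db = snr_min_db, clip_max = clip_max,
         nr_window_s = nr_window_s, nr_band_hz = nr_band_hz,
         nr_smoothing_hz = nr_smoothing_hz, nr_min_noise_s = nr_min_noise_s,
         manifest_path = manifest_path, model = model,
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147480009
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Audio mode: read WAVs, estimate a noise profile from the first
#' `nr_min_noise_s` of each recording, apply spectral subtraction, gate
#' on SNR and clipping (recording pre- and post-reduction SNR), extract
#' the 53-feature set from passing recordings, and join the metadata.
#' Features mode: read a prepared cohort CSV. Either way the cohort is
#' then stratified by FRS-bulbar and the three binary contrasts are run
#' under the repeated-split protocol (only control-vs-ALS, with a
#' warning, when no FRS column is available), followed by the
#' sex-interaction WAIC comparison when sex is available.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `run_report`: `qc` (per-recording reports
#'   and kept/discarded counts), `cohort`, `comparisons` (list of
#'   `comparison_result`), `interaction`, `provenance`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  manifest <- feature_manifest(cfg$manifest_path)
  qc <- list(reports = list(), kept = integer(0), discarded = integer(0))
  if (cfg$input_mode == "audio") {
    paths <- sort(list.files(cfg$audio_dir, pattern = "\\.wav$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(paths)) stop("run_pipeline: no WAV files in ", cfg$audio_dir)
    meta <- utils::read.csv(cfg$metadata_csv, stringsAsFactors = FALSE)
    kept <- list()
    for (p in paths) {
      rec <- read_wav(p)
      prof <- estimate_noise_profile(rec, c(0, min(cfg$nr_min_noise_s,
                                                   duration_s(rec))),
                                     window_s = cfg$nr_window_s)
      den <- spectral_subtract(rec, prof, band_hz = cfg$nr_band_hz,
                               smoothing_hz = cfg$nr_smoothing_hz,
                               window_s = cfg$nr_window_s)
      rep_pre <- compute_snr(rec)
      gate <- qc_gate(den, snr_min_db = cfg$snr_min_db, clip_max = cfg$clip_max)
      gate$snr_pre_db <- as.numeric(rep_pre)
      qc$reports[[rec$subject_id]] <- gate
      if (gate$passed) kept[[length(kept) + 1L]] <- den
    }
    qc$kept <- length(kept)
    qc$discarded <- length(paths) - length(kept)
    if (!length(kept))
      stop("run_pipeline: no recordings passed quality control (",
           qc$discarded, " discarded)")
    cohort <- extract_feature_table(kept, metadata = meta, manifest = manifest)
  } else {
    cohort <- read_cohort_csv(cfg$feature_csv)
    qc$kept <- nrow(cohort)
  }
  has_frs <- "frs_bulb" %in% names(cohort) && any(!is.na(cohort$frs_bulb))
  if (has_frs) cohort <- stratify_cohort(cohort)
  contrasts <- if (has_frs) contrast_names() else "control_vs_als"
  if (!has_frs)
    warning("run_pipeline: no FRS-bulbar scores; running control_vs_als only")
  model <- cfg$model
  model$seed <- derive_seed(cfg$seed, "model")
  comparisons <- lapply(contrasts, function(ct) {
    run_binary_comparison(cohort, ct, cfg = model, n_reps = cfg$n_reps,
                          manifest = manifest)
  })
  names(comparisons) <- contrasts
  interaction <- NULL
  if ("sex" %in% names(cohort) && !any(is.na(cohort$sex))) {
    imodel <- cfg$model
    imodel$seed <- derive_seed(cfg$seed, "interaction")
    interaction <- compare_interaction_models(cohort, imodel,
                                              contrast = contrasts[1],
                                              n_reps = cfg$n_reps,
                                              manifest = manifest)
  }
  structure(
    list(qc = qc, cohort = cohort, comparisons = comparisons,
         interaction = interaction,
         provenance = list(seed = cfg$seed, config_hash = config_hash(cfg),
                           package_version =
                             as.character(utils::packageVersion("bulbarvoice")))),
    class = "run_report"
  )
}

# Empirical ROC curve points (monotone nondecreasing FPR/TPR).
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  labels <- as.logical(labels)[o]
  tpr <- c(0, cumsum(labels) / max(1, sum(labels)))
  fpr <- c(0, cumsum(!labels) / max(1, sum(!labels)))
  data.frame(fpr = fpr, tpr = tpr)
}

#' Export a run report to files
#'
#' Writes into `outdir`: `features.csv` (the cohort table),
#' `roc_points_<contrast>_<fold>.csv`, `coefficients.csv` (features x
#' contrasts median coefficients), `qc.jsonl` (one JSON object per
#' recording) and `report.json` (AUROC summaries, interaction verdict,
#' provenance). Fails before any partial write when the directory cannot
#' be created.
#'
#' @param report A `run_report`.
#' @param outdir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
export_report <- function(report, outdir) {
  stopifnot(inherits(report, "run_report"))
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("export_report: cannot create ", outdir)
  written <- character(0)
  w <- function(p) { written <<- c(written, p); p }
  utils::write.csv(report$cohort, w(file.path(outdir, "features.csv")),
                   row.names = FALSE)
  coef_tab <- do.call(cbind, lapply(report$comparisons, function(cr)
    cr$median_coefficients))
  colnames(coef_tab) <- names(report$comparisons)
  utils::write.csv(data.frame(feature = rownames(coef_tab), coef_tab,
                              check.names = FALSE),
                   w(file.path(outdir, "coefficients.csv")),
                   row.names = FALSE)
  for (ct in names(report$comparisons)) {
    cr <- report$comparisons[[ct]]
    for (k in seq_along(cr$folds)) {
      f <- cr$folds[[k]]
      utils::write.csv(roc_points(f$scores, f$labels),
                       w(file.path(outdir,
                                   sprintf("roc_points_%s_%02d.csv", ct, k))),
                       row.names = FALSE)
    }
  }
  qcl <- vapply(report$qc$reports, function(r) {
    jsonlite::toJSON(list(subject_id = r$subject_id, snr_db = r$snr_db,
                          clipping_fraction = r$clipping_fraction,
                          passed = r$passed, reasons = r$reasons),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(qcl, w(file.path(outdir, "qc.jsonl")))
  summary <- list(
    qc = list(kept = report$qc$kept, discarded = report$qc$discarded),
    comparisons = lapply(report$comparisons, function(cr) list(
      contrast = cr$contrast, n = cr$n,
      fold_aurocs = as.numeric(cr$fold_aurocs),
      auroc_mean = cr$auroc_mean, auroc_sd = cr$auroc_sd,
      coefficients = as.list(cr$median_coefficients)
    )),
    interaction = if (!is.null(report$interaction)) list(
      verdict = report$interaction$verdict,
      folds = report$interaction$folds
    ),
    provenance = report$provenance
  )
  jsonlite::write_json(summary, w(file.path(outdir, "report.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(written)
}
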