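#' Names of the three binary contrasts
#'
#' `control_vs_als` (controls vs all ALS), `control_vs_alse` (controls vs
#' early ALS) and `alse_vs_alsl` (early vs late ALS). In every contrast
#' class 1 is the less-impaired group, so positive coefficients mean the
#' less-impaired group has the higher feature value.
#'
#' @return Character vector of contrast names.
#' @export
contrast_names <- function() c("control_vs_als", "control_vs_alse", "alse_vs_alsl")

# Subset a stratified cohort for one contrast; returns rows and the 0/1
# response (1 = less impaired).
contrast_subset <- function(table, contrast, manifest = feature_manifest()) {
  if (!"severity" %in% names(table)) table <- stratify_cohort(table)
  sev <- table$severity
  sel <- switch(
    contrast,
    control_vs_als = table$group %in% c("control", "ALS"),
    control_vs_alse = (sev %in% c("control", "ALS-E")),
    alse_vs_alsl = (sev %in% c("ALS-E", "ALS-L")),
    stop("unknown contrast: ", contrast)
  )
  sel[is.na(sel)] <- FALSE
  sub <- table[sel, , drop = FALSE]
  y <- switch(
    contrast,
    control_vs_als = as.numeric(sub$group == "control"),
    control_vs_alse = as.numeric(sub$severity == "control"),
    alse_vs_alsl = as.numeric(sub$severity == "ALS-E")
  )
  list(table = sub, y = y,
       X = as.matrix(sub[, feature_names(manifest), drop = FALSE]))
}

#' Run one binary comparison under the repeated-split protocol
#'
#' For each of `n_reps` stratified pseudorandom 50/50 splits: impute
#' missing features with training-half medians, standardize by training
#' mean/SD, fit the Bayesian LASSO logistic model on the training half,
#' score the held-out half, and compute the AUROC. Per-fold
#' posterior-median coefficients are aggregated across folds by the
#' median. Test rows never influence the imputation medians, the scaler,
#' or the posterior.
#'
#' @param table A cohort data.frame (will be stratified if needed).
#' @param contrast One of [contrast_names()].
#' @param cfg A [model_config()].
#' @param n_reps Number of repeated splits.
#' @param manifest Feature manifest data.frame.
#' @return An object of class `comparison_result`: `contrast`,
#'   `fold_aurocs`, `auroc_mean`, `auroc_sd`, `coefficients` (features x
#'   folds matrix of posterior medians), `median_coefficients`, `folds`
#'   (per-fold audit records), `n`.
#' @export
run_binary_comparison <- function(table, contrast = "control_vs_als",
                                  cfg = model_config(), n_reps = 10L,
                                  manifest = feature_manifest()) {
  cs <- contrast_subset(table, contrast, manifest)
  if (length(unique(cs$y)) < 2L)
    stop("run_binary_comparison: both contrast classes must be present")
  splits <- make_splits(cs$y, n_reps = n_reps,
                        seed = derive_seed(cfg$seed, contrast))
  nm <- feature_names(manifest)
  coefs <- matrix(NA_real_, length(nm), n_reps,
                  dimnames = list(nm, paste0("fold", seq_len(n_reps))))
  aurocs <- rep(NA_real_, n_reps)
  folds <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    sp <- splits[[k]]
    imp <- impute_train_medians(cs$X[sp$train, , drop = FALSE],
                                cs$X[sp$test, , drop = FALSE])
    std <- standardize_features(imp$train, imp$test)
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(cfg$seed, paste0(contrast, "_fit", k))
    fit <- fit_lasso_logistic(std$train, cs$y[sp$train], fold_cfg)
    scores <- predict_probability(fit, std$test)
    aurocs[k] <- compute_auroc(scores, cs$y[sp$test])
    med <- apply(fit$beta, 2, stats::median)
    coefs[names(med), k] <- med
    folds[[k]] <- list(
      train = sp$train, test = sp$test, split_seed = sp$seed,
      medians = imp$medians, center = std$center, scale = std$scale,
      dropped = std$dropped, converged = fit$converged,
      scores = scores, labels = cs$y[sp$test]
    )
  }
  ok <- !vapply(folds, function(f) isFALSE(f$converged), logical(1))
  structure(
    list(contrast = contrast, fold_aurocs = aurocs,
         auroc_mean = mean(aurocs[ok], na.rm = TRUE),
         auroc_sd = stats::sd(aurocs[ok], na.rm = TRUE),
         coefficients = coefs,
         median_coefficients = aggregate_coefficients(coefs),
         folds = folds, n = nrow(cs$table)),
    class = "comparison_result"
  )
}

#' Aggregate per-fold coefficients by the median
#'
#' The median across folds of each feature's posterior-median
#' coefficient. With class 1 coded as the less-impaired group, positive
#' aggregated coefficients indicate features on which the less-impaired
#' group scores higher.
#'
#' @param coefs Features x folds matrix of per-fold posterior medians (or
#'   a `comparison_result`).
#' @return Named numeric vector of per-feature median coefficients.
#' @export
aggregate_coefficients <- function(coefs) {
  if (inherits(coefs, "comparison_result")) coefs <- coefs$coefficients
  coefs <- as.matrix(coefs)
  if (ncol(coefs) < 1L) stop("aggregate_coefficients: need >= 1 fold")
  apply(coefs, 1, stats::median, na.rm = TRUE)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s (n = %d): AUROC %.3f +/- %.3f over %d folds\n",
              x$contrast, x$n, x$auroc_mean, x$auroc_sd,
              sum(!is.na(x$fold_aurocs))))
  top <- sort(abs(x$median_coefficients), decreasing = TRUE)[1:5]
  cat("  top |median coefficients|:",
      paste(sprintf("%s=%.2f", names(top),
                    x$median_coefficients[names(top)]), collapse = ", "), "\n")
  invisible(x)
}
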