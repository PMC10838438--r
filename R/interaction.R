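#' Build a sex-interaction design matrix
#'
#' Appends to a standardized feature design a sex main effect (0 =
#' female, 1 = male) and, for each feature in the interaction subset
#' (F0 and HNR features by default), a multiplicative `sex x feature`
#' column. Both the interaction and the no-interaction model share the
#' sex main effect, so a model comparison isolates the interactions.
#'
#' @param X Standardized numeric feature matrix with column names.
#' @param sex Sex per row: `"F"`/`"M"`, or 0/1 (female = 0).
#' @param subset Feature names receiving interactions; defaults to
#'   [interaction_feature_subset()] intersected with `colnames(X)`.
#' @return List `base` (X + sex main effect), `interaction` (base +
#'   product columns), `subset`, `interaction_names`.
#' @export
build_interaction_design <- function(X, sex,
                                     subset = NULL) {
  X <- as.matrix(X)
  if (is.null(subset)) subset <- intersect(interaction_feature_subset(),
                                           colnames(X))
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.character(sex)
    if (!all(sex %in% c("F", "M")))
      stop("build_interaction_design: sex values must be 'F' or 'M'")
    sex <- as.numeric(sex == "M")
  }
  if (any(is.na(sex)) || !all(sex %in% c(0, 1)))
    stop("build_interaction_design: sex must be known (0/1) for every row")
  stopifnot(length(sex) == nrow(X), all(subset %in% colnames(X)))
  base <- cbind(X, sex = sex)
  inter <- X[, subset, drop = FALSE] * sex
  colnames(inter) <- paste0("sex_x_", subset)
  list(base = base, interaction = cbind(base, inter), subset = subset,
       interaction_names = colnames(inter))
}

#' Watanabe-Akaike information criterion from a posterior fit
#'
#' WAIC = \eqn{-2(\mathrm{lppd} - p_{\mathrm{waic}})}, where the log
#' pointwise predictive density sums \eqn{\log} mean posterior likelihood
#' per observation and the effective parameter count sums the pointwise
#' posterior variances of the log-likelihood. The standard error scales
#' the pointwise spread by \eqn{\sqrt{n}}. Lower WAIC means better
#' estimated out-of-sample fit.
#'
#' @param fit A `posterior_fit` (its `loglik` matrix is draws x
#'   observations), or such a matrix directly.
#' @return List `waic`, `p_waic`, `lppd`, `pointwise` (per-observation
#'   \eqn{-2 \cdot} elpd contributions), `se`.
#' @export
compute_waic <- function(fit) {
  ll <- if (inherits(fit, "posterior_fit")) fit$loglik else as.matrix(fit)
  if (nrow(ll) < 2L) stop("compute_waic: need at least 2 posterior draws")
  lppd_i <- apply(ll, 2, log_mean_exp)
  p_i <- apply(ll, 2, stats::var)
  pointwise <- -2 * (lppd_i - p_i)
  n <- ncol(ll)
  list(waic = sum(pointwise), p_waic = sum(p_i), lppd = sum(lppd_i),
       pointwise = pointwise, se = sqrt(n * stats::var(pointwise)))
}

#' Compare two fits by WAIC with a substantiality rule
#'
#' The more complex model is preferred only when its WAIC is lower by
#' more than twice the standard error of the pointwise WAIC difference;
#' otherwise the simpler model is retained (ties therefore default to
#' the simpler model).
#'
#' @param fit_simple,fit_complex `posterior_fit`s on the same
#'   observations.
#' @return List `waic_simple`, `waic_complex`, `delta` (simple minus
#'   complex; positive favours the complex model), `se`, `decision`
#'   (`"retain simpler"` or `"prefer complex"`).
#' @export
waic_compare <- function(fit_simple, fit_complex) {
  w1 <- compute_waic(fit_simple)
  w2 <- compute_waic(fit_complex)
  if (length(w1$pointwise) != length(w2$pointwise))
    stop("waic_compare: fits cover different observation sets")
  d_i <- w1$pointwise - w2$pointwise
  delta <- sum(d_i)
  se <- sqrt(length(d_i) * stats::var(d_i))
  list(waic_simple = w1$waic, waic_complex = w2$waic, delta = delta,
       se = se,
       decision = if (delta > 2 * se && delta > 0) "prefer complex"
                  else "retain simpler")
}

#' Compare sex-interaction and no-interaction models across folds
#'
#' For each training half of the repeated-split protocol, fits the
#' classifier with and without `sex x feature` interaction columns
#' (both models share the sex main effect; interaction coefficients get
#' the same Laplace prior) and compares them by WAIC with the
#' substantiality rule. The overall verdict is the majority of per-fold
#' decisions.
#'
#' @param table Cohort data.frame with a `sex` column and features.
#' @param cfg A [model_config()].
#' @param contrast Which binary contrast to fit; see [contrast_names()].
#' @param n_reps Number of repeated splits.
#' @param subset Feature names receiving interactions (default: F0 + HNR
#'   manifest subsets).
#' @param manifest Feature manifest data.frame.
#' @return An object of class `interaction_comparison`: per-fold
#'   data.frame `folds` (`waic_base`, `waic_inter`, `delta`, `se`,
#'   `decision`) and `verdict`.
#' @export
compare_interaction_models <- function(table, cfg = model_config(),
                                       contrast = "control_vs_als",
                                       n_reps = 10L, subset = NULL,
                                       manifest = feature_manifest()) {
  if (!"sex" %in% names(table) || any(is.na(table$sex)))
    stop("compare_interaction_models: sex must be available for all rows")
  cs <- contrast_subset(table, contrast, manifest)
  splits <- make_splits(cs$y, n_reps = n_reps,
                        seed = derive_seed(cfg$seed, paste0("inter_", contrast)))
  rows <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    tr <- splits[[k]]$train
    imp <- impute_train_medians(cs$X[tr, , drop = FALSE],
                                cs$X[tr, , drop = FALSE])
    std <- standardize_features(imp$train, imp$test)
    des <- build_interaction_design(std$train, cs$table$sex[tr],
                                    subset = subset)
    cfg_b <- cfg; cfg_b$seed <- derive_seed(cfg$seed, paste0("base", k))
    cfg_i <- cfg; cfg_i$seed <- derive_seed(cfg$seed, paste0("inter", k))
    fit_b <- fit_lasso_logistic(des$base, cs$y[tr], cfg_b)
    fit_i <- fit_lasso_logistic(des$interaction, cs$y[tr], cfg_i)
    cmpr <- waic_compare(fit_b, fit_i)
    rows[[k]] <- data.frame(
      fold = k, waic_base = cmpr$waic_simple, waic_inter = cmpr$waic_complex,
      delta = cmpr$delta, se = cmpr$se,
      decision = if (cmpr$decision == "prefer complex") "prefer interaction"
                 else "retain simpler",
      stringsAsFactors = FALSE
    )
  }
  folds <- do.call(rbind, rows)
  n_prefer <- sum(folds$decision == "prefer interaction")
  structure(
    list(folds = folds,
         verdict = if (n_prefer > n_reps / 2) "prefer interaction"
                   else "retain simpler"),
    class = "interaction_comparison"
  )
}

#' @export
print.interaction_comparison <- function(x, ...) {
  n_prefer <- sum(x$folds$decision == "prefer interaction")
  cat(sprintf("<interaction_comparison> verdict: %s (%d/%d folds prefer interaction)\n",
              x$verdict, n_prefer, nrow(x$folds)))
  invisible(x)
}
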