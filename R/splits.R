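#' Assign bulbar severity strata to a cohort table
#'
#' ALS rows are stratified by the FRS-bulbar score: `ALS-E` (early, FRS
#' >= 11 of 12) or `ALS-L` (late, FRS < 11). Controls are labelled
#' `control` regardless of FRS. ALS rows with missing FRS get `NA`
#' severity: they are excluded from severity contrasts but retained for
#' the control-vs-all-ALS comparison.
#'
#' @param table A cohort data.frame with columns `group` and `frs_bulb`.
#' @param cutoff Severity cutoff (FRS >= cutoff is early).
#' @return The table with an added `severity` column.
#' @export
stratify_cohort <- function(table, cutoff = 11) {
  stopifnot("group" %in% names(table))
  # absent FRS column = all scores missing (degraded mode)
  frs <- if ("frs_bulb" %in% names(table)) table$frs_bulb else
    rep(NA_real_, nrow(table))
  bad <- !is.na(frs) & (frs < 0 | frs > 12)
  if (any(bad))
    stop("stratify_cohort: FRS-bulbar outside [0, 12] in rows ",
         paste(which(bad), collapse = ", "))
  sev <- rep(NA_character_, nrow(table))
  is_ctrl <- table$group == "control"
  sev[is_ctrl] <- "control"
  is_als <- !is_ctrl
  sev[is_als & !is.na(frs) & frs >= cutoff] <- "ALS-E"
  sev[is_als & !is.na(frs) & frs < cutoff] <- "ALS-L"
  table$severity <- sev
  table
}

#' Repeated stratified 50/50 split plans
#'
#' Builds `n_reps` class-stratified pseudorandom partitions of the
#' subjects into disjoint, exhaustive train/test halves
#' (|train| = |test| +/- 1 at the default fraction). Each repetition
#' uses a seed derived from the master seed, so plans are reproducible.
#'
#' @param labels Class label per subject (any two-level vector).
#' @param n_reps Number of repetitions.
#' @param train_fraction Fraction of subjects in the training half.
#' @param seed Master seed.
#' @return List of split plans: `list(rep, train, test, seed)` with
#'   integer index vectors.
#' @export
make_splits <- function(labels, n_reps = 10L, train_fraction = 0.5,
                        seed = 1L) {
  labels <- as.character(labels)
  classes <- unique(labels)
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("make_splits: class '", names(sizes)[which.min(sizes)],
         "' too small to appear in both halves")
  n <- length(labels)
  target <- round(n * train_fraction)
  lapply(seq_len(n_reps), function(r) {
    rep_seed <- derive_seed(seed, paste0("split", r))
    with_seed(rep_seed, {
      train <- integer(0)
      # per-class floor allocation, then largest remainders up to the target
      alloc <- vapply(classes, function(cl) floor(sizes[[cl]] * train_fraction),
                      numeric(1))
      rem <- vapply(classes, function(cl) sizes[[cl]] * train_fraction,
                    numeric(1)) - alloc
      short <- target - sum(alloc)
      if (short > 0) {
        bump <- order(rem, decreasing = TRUE)[seq_len(short)]
        alloc[bump] <- alloc[bump] + 1
      }
      alloc <- pmin(pmax(alloc, 1), vapply(classes, function(cl) sizes[[cl]] - 1L,
                                           numeric(1)))
      for (ci in seq_along(classes)) {
        idx <- which(labels == classes[ci])
        train <- c(train, sample(idx, alloc[ci]))
      }
      train <- sort(train)
      list(rep = r, train = train, test = setdiff(seq_len(n), train),
           seed = rep_seed)
    })
  })
}

#' Standardize features by training statistics
#'
#' Columns are centred and scaled by the training mean and standard
#' deviation; the test half is transformed with the same constants.
#' Zero-variance training columns are dropped from both halves and
#' recorded in the scaler.
#'
#' @param train,test Numeric matrices or data.frames of feature columns.
#' @return List `train`, `test` (matrices), `center`, `scale`, `dropped`.
#' @export
standardize_features <- function(train, test) {
  train <- as.matrix(train); test <- as.matrix(test)
  stopifnot(nrow(train) >= 2L, ncol(train) == ncol(test))
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  dropped <- colnames(train)[!is.finite(scl) | scl < 1e-12]
  keep <- setdiff(colnames(train), dropped)
  train <- sweep(sweep(train[, keep, drop = FALSE], 2, ctr[keep]), 2,
                 scl[keep], `/`)
  test <- sweep(sweep(test[, keep, drop = FALSE], 2, ctr[keep]), 2,
                scl[keep], `/`)
  list(train = train, test = test, center = ctr[keep], scale = scl[keep],
       dropped = dropped)
}

# Train-median imputation: medians computed on the training half only.
impute_train_medians <- function(train, test) {
  train <- as.matrix(train); test <- as.matrix(test)
  med <- apply(train, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0 # all-missing training column
  for (j in seq_len(ncol(train))) {
    train[is.na(train[, j]), j] <- med[j]
    test[is.na(test[, j]), j] <- med[j]
  }
  list(train = train, test = test, medians = med)
}
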