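test_that("AUROC equals exhaustive pair counting on random small instances", {
  pair_oracle <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(11, {
    for (i in 1:200) {
      n <- sample(4:20, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
      expect_identical(compute_auroc(scores, labels),
                       pair_oracle(scores, labels))
    }
  })
})

test_that("AUROC handles canonical cases", {
  expect_equal(compute_auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(compute_auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auroc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  und <- compute_auroc(1:4, rep(1, 4))
  expect_true(is.na(und))
  expect_equal(attr(und, "reason"), "single class")
})

test_that("AUROC agrees with pROC on a larger instance", {
  withr::with_seed(3, {
    scores <- runif(60)
    labels <- rbinom(60, 1, 0.5)
  })
  ours <- compute_auroc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("severity stratification applies the FRS cutoff", {
  tab <- data.frame(group = c("ALS", "ALS", "ALS", "control"),
                    frs_bulb = c(11, 10, NA, NA))
  out <- stratify_cohort(tab)
  expect_identical(out$severity, c("ALS-E", "ALS-L", NA, "control"))
  expect_error(stratify_cohort(data.frame(group = "ALS", frs_bulb = 13)),
               "\\[0, 12\\]")
})

test_that("missing-FRS rows join only the all-ALS contrast", {
  tab <- demo_cohort()
  n_missing <- sum(tab$group == "ALS" & is.na(tab$frs_bulb))
  expect_gt(n_missing, 0)
  cs_all <- bulbarvoice:::contrast_subset(tab, "control_vs_als")
  cs_sev <- bulbarvoice:::contrast_subset(tab, "alse_vs_alsl")
  cs_e <- bulbarvoice:::contrast_subset(tab, "control_vs_alse")
  expect_equal(nrow(cs_all$table), nrow(tab))
  expect_equal(nrow(cs_sev$table), sum(!is.na(tab$severity) &
                                         tab$severity != "control"))
  expect_false(any(is.na(cs_e$table$severity)))
})

test_that("split plans are stratified, disjoint, exhaustive and reproducible", {
  labels <- rep(c("a", "b"), c(24, 22))
  plans <- make_splits(labels, n_reps = 10, seed = 5)
  expect_length(plans, 10)
  for (p in plans) {
    expect_length(intersect(p$train, p$test), 0)
    expect_setequal(c(p$train, p$test), 1:46)
    expect_lte(abs(length(p$train) - length(p$test)), 1)
    expect_true(all(table(labels[p$train]) >= 1))
    expect_true(all(table(labels[p$test]) >= 1))
  }
  expect_identical(plans, make_splits(labels, n_reps = 10, seed = 5))
  # pseudorandom: repetitions differ
  expect_gt(length(unique(vapply(plans, function(p)
    paste(p$train, collapse = ","), character(1)))), 1)
  expect_error(make_splits(c("a", rep("b", 9)), seed = 1), "too small")
})

test_that("standardization uses training constants only", {
  withr::with_seed(2, {
    tr <- matrix(rnorm(40, 5, 2), 20, 2, dimnames = list(NULL, c("u", "v")))
    te <- tr + 3
  })
  std <- standardize_features(tr, te)
  expect_equal(unname(colMeans(std$train)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(std$train, 2, var)), c(1, 1), tolerance = 1e-10)
  # test = train + c => transformed test mean = c / train sd
  expect_equal(unname(colMeans(std$test)), unname(3 / std$scale),
               tolerance = 1e-10)
  # constant training column is dropped and recorded
  tr2 <- cbind(tr, w = 1)
  te2 <- cbind(te, w = rnorm(20))
  std2 <- standardize_features(tr2, te2)
  expect_identical(std2$dropped, "w")
  expect_false("w" %in% colnames(std2$train))
})

test_that("posterior matches an independent sampler (JAGS) on shared data", {
  skip_if_not_installed("rjags")
  set.seed(2)
  n <- 150; p <- 6
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rbinom(n, 1, plogis(X %*% c(1.5, -1, 0, 0, 0, 0)))
  fit <- fit_lasso_logistic(X, y, model_config(seed = 3))
  mine <- c(median(fit$alpha), apply(fit$beta, 2, median))
  msd <- c(sd(fit$alpha), apply(fit$beta, 2, sd))
  model_str <- "model {
    for (i in 1:n) { y[i] ~ dbern(ilogit(alpha + inprod(X[i,], beta[]))) }
    alpha ~ dnorm(0, 1)
    for (j in 1:p) { beta[j] ~ ddexp(0, 2) }
  }"
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(X = X, y = y, n = n, p = p),
                          n.chains = 3, n.adapt = 1000, quiet = TRUE)
  s <- rjags::coda.samples(jm, c("alpha", "beta"), n.iter = 4000)
  jag <- apply(as.matrix(s), 2, median)
  jsd <- apply(as.matrix(s), 2, sd)
  expect_lt(max(abs(mine - jag)), 0.05)
  expect_lt(max(abs(msd - jsd)), 0.05)
})

test_that("split R-hat agrees with coda's diagnostic on well-mixed chains", {
  skip_if_not_installed("coda")
  withr::with_seed(8, {
    chains <- lapply(1:4, function(i) rnorm(1000))
  })
  ours <- bulbarvoice:::split_rhat(chains)
  cl <- coda::mcmc.list(lapply(chains, coda::mcmc))
  ref <- coda::gelman.diag(cl, autoburnin = FALSE)$psrf[1, 1]
  expect_lt(abs(ours - 1), 0.02)
  expect_lt(abs(ref - 1), 0.02)
})

test_that("predict_probability follows the posterior algebra", {
  fit <- structure(list(alpha = c(0, 0), beta = matrix(c(1, -1), 2, 1,
                          dimnames = list(NULL, "x1")),
                        feature_names = "x1"), class = "posterior_fit")
  # sigma(1) + sigma(-1) = 1 symmetry
  expect_equal(predict_probability(fit, matrix(1, 1, 1,
                                               dimnames = list(NULL, "x1"))),
               0.5)
  fit0 <- structure(list(alpha = c(0, 0), beta = matrix(0, 2, 1,
                           dimnames = list(NULL, "x1")),
                         feature_names = "x1"), class = "posterior_fit")
  expect_equal(predict_probability(fit0, matrix(c(-3, 5), 2, 1,
                                                dimnames = list(NULL, "x1"))),
               c(0.5, 0.5))
  # monotone in x when all draws positive
  fitp <- structure(list(alpha = c(0, 0), beta = matrix(c(0.5, 1.5), 2, 1,
                           dimnames = list(NULL, "x1")),
                         feature_names = "x1"), class = "posterior_fit")
  pr <- predict_probability(fitp, matrix(c(0, 1, 2), 3, 1,
                                         dimnames = list(NULL, "x1")))
  expect_true(all(diff(pr) > 0))
  expect_error(predict_probability(fitp, matrix(0, 1, 2)), "match")
})

test_that("null labels give near-chance AUROC and near-zero coefficients", {
  withr::with_seed(9, {
    n <- 200; p <- 8
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
    y <- rep(c(0, 1), n / 2)
  })
  fit <- fit_lasso_logistic(X, y, model_config(seed = 4, chains = 2L,
                                               warmup = 500L, draws = 500L))
  med <- apply(fit$beta, 2, median)
  expect_true(all(abs(med) < 0.3))
  expect_lt(abs(median(fit$alpha)), 0.3)
})
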