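# Statistical battery: partial rank correlation, dependent-correlation z,
# ROC/AUC, classification metrics, regression comparison, spectral
# baselines.

test_that("partial Spearman correlation hits its closed-form poles", {
  z <- rnorm(8)
  x <- 1:8
  expect_equal(spearman_partial(x, 2 * x + 3, z)$rho, 1, tolerance = 1e-12)
  expect_equal(spearman_partial(x, rev(x), z)$rho, -1, tolerance = 1e-12)
  expect_error(spearman_partial(x, rep(1, 8), z), "non-constant")
  expect_error(spearman_partial(x, x, rep(2, 8)), "constant")
  expect_error(spearman_partial(1:3, 1:3, 1:3), "at least 4")
})

test_that("partial Spearman matches a rank-residual oracle on random triples", {
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10); z <- rnorm(10)
    got <- spearman_partial(x, y, z)
    # oracle: partial correlation = correlation of rank-regression residuals
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    ex <- resid(lm(rx ~ rz)); ey <- resid(lm(ry ~ rz))
    expect_equal(got$rho, cor(ex, ey), tolerance = 1e-10)
    # p from the t approximation on n - 3 df
    tt <- got$rho * sqrt(7 / (1 - got$rho^2))
    expect_equal(got$p, 2 * pt(-abs(tt), 7), tolerance = 1e-12)
  }
})

test_that("dependent-correlation z is zero for identical predictors and matches the formula", {
  set.seed(42)
  y <- rnorm(20); x <- rnorm(20)
  expect_equal(compare_dependent_correlations(x, x, y)$z, 0)
  expect_error(compare_dependent_correlations(1:5, 5:1, rnorm(5)),
               "at least 10")

  for (i in 1:10) {
    x1 <- rnorm(15); x2 <- rnorm(15); y <- rnorm(15)
    got <- compare_dependent_correlations(x1, x2, y, method = "pearson")
    # independent evaluation of the overlapping-correlation z construction
    r1 <- cor(x1, y); r2 <- cor(x2, y); r12 <- cor(x1, x2)
    rb <- (r1^2 + r2^2) / 2
    f <- min((1 - r12) / (2 * (1 - rb)), 1)
    h <- (1 - f * rb) / (1 - rb)
    z_oracle <- (atanh(r1) - atanh(r2)) *
      sqrt((15 - 3) / (2 * (1 - r12) * h))
    expect_equal(got$z, z_oracle, tolerance = 1e-8)
  }
})

test_that("AUC equals brute-force pairwise counting, with tie and flip symmetry", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(c(0.8, 0.4, 0.6, 0.2),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")

  set.seed(43)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    scores <- sample(round(runif(n), 2))  # deliberate ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    auc <- roc_auc(scores, labels)$auc
    pos <- scores[labels]; neg <- scores[!labels]
    brute <- mean(outer(pos, neg, function(a, b) {
      (a > b) + 0.5 * (a == b)
    }))
    expect_equal(auc, brute, tolerance = 1e-12)
    expect_equal(roc_auc(scores, !labels)$auc, 1 - auc, tolerance = 1e-12)
  }
})

test_that("classification metrics and the exact rank-sum p behave as expected", {
  m <- classification_metrics(
    predicted = c("impaired", "impaired", "normal", "impaired"),
    truth = c("impaired", "impaired", "normal", "normal"),
    scores = c(0.1, 0.2, 0.9, 0.4))
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 50)
  expect_equal(m$accuracy, 75)
  expect_equal(sum(m$confusion), 4)

  all_right <- classification_metrics(
    c("impaired", "normal"), c("impaired", "normal"), c(0.1, 0.9))
  expect_equal(all_right$accuracy, 100)

  sep <- classification_metrics(
    predicted = rep(c("normal", "impaired"), each = 3),
    truth = rep(c("normal", "impaired"), each = 3),
    scores = c(0.9, 0.85, 0.8, 0.1, 0.15, 0.2))
  expect_equal(sep$ranksum_p, 0.1, tolerance = 1e-12)

  expect_error(classification_metrics("normal", c("normal", "impaired"),
                                      0.5), "equal length")
})

test_that("linear vs quadratic regression separates curvature and matches an R2 oracle", {
  idx <- c(-2, -1, 0, 1, 2)
  sq <- suppressWarnings(  # exact fit makes summary() grumble
    regression_linear_quadratic(idx, idx^2))
  expect_equal(sq$r2_quadratic, 1, tolerance = 1e-12)
  expect_equal(sq$r2_linear, 0, tolerance = 1e-12)

  lin <- suppressWarnings(  # near-perfect fit makes summary() grumble
    regression_linear_quadratic(1:20, 3 + 0.5 * (1:20) + rnorm(20, sd = 1e-8)))
  expect_lt(abs(coef(lin$fit_quadratic)[3]), 1e-6)

  set.seed(44)
  x <- rnorm(20); y <- rnorm(20)
  got <- regression_linear_quadratic(x, y)
  sse <- sum(resid(lm(y ~ x))^2); sst <- sum((y - mean(y))^2)
  expect_equal(got$r2_linear, 1 - sse / sst, tolerance = 1e-10)
  expect_gte(got$r2_quadratic, got$r2_linear - 1e-12)
})

test_that("Welch band powers put a 10 Hz tone in alpha and sign the alpha/theta ratio", {
  fs <- 500
  coh <- tiny_cohort(n_subjects = 4, duration = 8, seed = 6)
  ds <- cohort_dataset(coh)
  # overwrite one channel with pure tones to probe the baseline features
  mk_ds <- function(freq) {
    recs <- ds$recordings
    for (id in names(recs)) {
      recs[[id]]$samples[1, ] <- tone(freq, fs, recs[[id]]$duration) +
        0.01 * rnorm(ncol(recs[[id]]$samples))
    }
    leapd_dataset(ds$subjects, recs)
  }
  base10 <- spectral_baselines(mk_ds(10))
  ch1 <- base10$channel[1]
  row10 <- base10[base10$channel == ch1, ]
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  # recompute the per-subject features directly for one subject
  w <- welch_psd(tone(10, fs, 8), fs)
  powers <- vapply(bands, function(b) {
    lim <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                beta = c(13, 30), gamma = c(31, 100))[[b]]
    leapd:::band_power_from_psd(w$freq, w$psd, lim[1], lim[2])
  }, numeric(1))
  expect_equal(names(which.max(powers)), "alpha")
  expect_gt(log(powers["alpha"]) - log(powers["theta"]), 0)
  w6 <- welch_psd(tone(6, fs, 8), fs)
  p_a <- leapd:::band_power_from_psd(w6$freq, w6$psd, 8, 13)
  p_t <- leapd:::band_power_from_psd(w6$freq, w6$psd, 4, 8)
  expect_lt(log(p_a) - log(p_t), 0)
  # the baselines table carries one row per channel x feature
  expect_setequal(unique(row10$feature), c(bands, "alpha_theta_log_ratio"))
})

test_that("metrics are permutation equivariant", {
  set.seed(45)
  scores <- runif(20)
  labels <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  labels[1:2] <- c(TRUE, FALSE)
  perm <- sample(20)
  expect_equal(roc_auc(scores, labels)$auc,
               roc_auc(scores[perm], labels[perm])$auc, tolerance = 1e-12)
  x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
  expect_equal(spearman_partial(x, y, z)$rho,
               spearman_partial(x[perm], y[perm], z[perm])$rho,
               tolerance = 1e-12)
})
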