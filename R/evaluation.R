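# Evaluation battery: age-controlled rank correlation, dependent-correlation
# comparison, ROC/AUC, classification metrics with rank-sum separation,
# linear vs quadratic regression, cross-validation schemes, randomization
# tests, robustness sweeps, and classical spectral baselines.

#' Spearman partial correlation controlling one covariate
#'
#' Rank-transforms all three variables (mid-ranks for ties) and computes
#' the first-order partial Pearson correlation of the ranks,
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with a
#' t-approximation p-value on n - 3 degrees of freedom. Used throughout to
#' correlate the bounded index with cognitive scores while controlling for
#' age.
#'
#' @param x,y Numeric vectors, length >= 4.
#' @param covariate Numeric covariate (age), non-constant.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_partial <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n) {
    stop_leapd("x, y and covariate must have equal length")
  }
  if (n < 4L) stop_leapd("need at least 4 observations, got %d", n)
  for (v in list(x = x, y = y, covariate = covariate)) {
    check_finite_numeric(v, "input")
  }
  if (sd(x) == 0 || sd(y) == 0) stop_leapd("x and y must be non-constant")
  if (sd(covariate) == 0) stop_leapd("covariate is constant")
  rx <- midranks(x); ry <- midranks(y); rz <- midranks(covariate)
  r_xy <- cor(rx, ry); r_xz <- cor(rx, rz); r_yz <- cor(ry, rz)
  den <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
  if (den == 0) stop_leapd("degenerate covariate correlation")
  rho <- (r_xy - r_xz * r_yz) / den
  rho <- max(-1, min(1, rho))
  df <- n - 3L
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * pt(-abs(tstat), df), n = n)
}

#' Compare two dependent overlapping correlations
#'
#' z statistic for the difference between `cor(x1, y)` and `cor(x2, y)`
#' measured on the same subjects, accounting for `cor(x1, x2)`
#' (Meng-Rosenthal-Rubin construction on Fisher-transformed values). With
#' `method = "spearman"` (default) all vectors are rank-transformed first.
#'
#' @param x1,x2 Competing predictors.
#' @param y Common criterion.
#' @param method `"spearman"` or `"pearson"`.
#' @return List with `z` and two-sided `p`.
#' @export
compare_dependent_correlations <- function(x1, x2, y,
                                           method = c("spearman",
                                                      "pearson")) {
  method <- match.arg(method)
  n <- length(y)
  if (length(x1) != n || length(x2) != n) stop_leapd("length mismatch")
  if (n < 10L) stop_leapd("need at least 10 observations, got %d", n)
  if (method == "spearman") {
    x1 <- midranks(x1); x2 <- midranks(x2); y <- midranks(y)
  }
  r1 <- cor(x1, y); r2 <- cor(x2, y); rx <- cor(x1, x2)
  if (any(abs(c(r1, r2)) >= 1)) {
    stop_leapd("degenerate correlation |r| = 1")
  }
  if (r1 == r2) return(list(z = 0, p = 1))
  if (abs(rx) >= 1) stop_leapd("predictors are perfectly correlated")
  z1 <- atanh(r1); z2 <- atanh(r2)
  rbar <- (r1^2 + r2^2) / 2
  f <- min((1 - rx) / (2 * (1 - rbar)), 1)
  h <- (1 - f * rbar) / (1 - rbar)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - rx) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' ROC curve and AUC
#'
#' AUC is `P(score_pos > score_neg) + 0.5 P(tie)` over all positive-negative
#' pairs, computed via mid-ranks (exact under ties).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Logical (TRUE = positive) or two-level vector with
#'   `positive` naming the positive level.
#' @param positive Positive level when `labels` is not logical.
#' @return List with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  check_finite_numeric(scores, "scores")
  if (!is.logical(labels)) {
    if (is.null(positive)) stop_leapd("positive level required for non-logical labels")
    labels <- labels == positive
  }
  if (length(labels) != length(scores)) stop_leapd("length mismatch")
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) stop_leapd("both classes must be present")
  r <- midranks(scores)
  auc <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores[!labels] >= t) / nn, numeric(1)),
    tpr = vapply(thr, function(t) sum(scores[labels] >= t) / np, numeric(1))
  )
  list(auc = auc, curve = curve)
}

#' Classification metrics with rank-sum separation
#'
#' Confusion table and accuracy / sensitivity / specificity in percent,
#' with the impaired class as the detection target (sensitivity = fraction
#' of impaired subjects detected), plus a two-sided Wilcoxon rank-sum test
#' comparing the index between the true groups (exact for small untied
#' samples, normal approximation otherwise).
#'
#' @param predicted,truth Vectors of `"normal"` / `"impaired"` labels.
#' @param scores Combined indices backing the predictions.
#' @return List: `confusion` (2x2), `accuracy`, `sensitivity`,
#'   `specificity` (percent), `ranksum_p`.
#' @export
classification_metrics <- function(predicted, truth, scores) {
  n <- length(truth)
  if (length(predicted) != n || length(scores) != n) {
    stop_leapd("predicted, truth and scores must have equal length")
  }
  lv <- c("impaired", "normal")
  if (!all(predicted %in% lv) || !all(truth %in% lv)) {
    stop_leapd("labels must be 'normal' or 'impaired'")
  }
  if (length(unique(truth)) < 2L) stop_leapd("both classes must be present in truth")
  confusion <- table(factor(predicted, lv), factor(truth, lv),
                     dnn = c("predicted", "truth"))
  tp <- confusion["impaired", "impaired"]; fn <- confusion["normal", "impaired"]
  tn <- confusion["normal", "normal"];    fp <- confusion["impaired", "normal"]
  w <- suppressWarnings(
    wilcox.test(scores[truth == "impaired"], scores[truth == "normal"])
  )
  list(confusion = confusion,
       accuracy = 100 * (tp + tn) / n,
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       ranksum_p = w$p.value)
}

#' Linear and quadratic regression of score on index
#'
#' Ordinary least squares for `score ~ index` and
#' `score ~ index + index^2`, with a likelihood-ratio test (chi-squared,
#' 1 df) for the nested comparison.
#'
#' @param index Combined indices.
#' @param score Cognitive scores.
#' @return List: `fit_linear`, `fit_quadratic` (lm objects), `r2_linear`,
#'   `r2_quadratic`, `lr_p`.
#' @export
regression_linear_quadratic <- function(index, score) {
  n <- length(index)
  if (length(score) != n) stop_leapd("length mismatch")
  if (n < 4L) stop_leapd("need at least 4 observations")
  if (sd(index) == 0) stop_leapd("degenerate design: constant index")
  d <- data.frame(index = index, score = score)
  fl <- lm(score ~ index, data = d)
  fq <- lm(score ~ index + I(index^2), data = d)
  lr <- as.numeric(2 * (logLik(fq) - logLik(fl)))
  list(fit_linear = fl, fit_quadratic = fq,
       r2_linear = summary(fl)$r.squared,
       r2_quadratic = summary(fq)$r.squared,
       lr_p = pchisq(max(lr, 0), df = 1, lower.tail = FALSE))
}

#' Cross-validation scheme
#'
#' @param kind `"loocv"` or `"kfold"`.
#' @param k Number of folds (kfold only, >= 2).
#' @param repeats Number of independently shuffled repeats (kfold; default
#'   1).
#' @param shuffle_seed Seed for fold shuffling (default 1).
#' @return A `cv_scheme` list.
#' @export
cv_scheme <- function(kind = c("loocv", "kfold"), k = 10, repeats = 1,
                      shuffle_seed = 1) {
  kind <- match.arg(kind)
  if (kind == "kfold") {
    check_scalar(k, "k", 2, Inf)
    check_scalar(repeats, "repeats", 1, Inf)
  }
  structure(list(kind = kind, k = as.integer(k),
                 repeats = as.integer(repeats),
                 shuffle_seed = as.integer(shuffle_seed)),
            class = "cv_scheme")
}

# Fold assignment: a list of test-index vectors partitioning 1..n.  With
# strata, members of each class are shuffled and dealt round-robin so every
# fold's per-class counts differ by at most one.
make_folds <- function(n, scheme, seed_offset = 0, strata = NULL) {
  if (scheme$kind == "loocv") return(as.list(seq_len(n)))
  k <- scheme$k
  withr::with_seed(derive_seed(scheme$shuffle_seed, seed_offset), {
    fold_of <- integer(n)
    if (is.null(strata)) {
      fold_of[sample(n)] <- rep(seq_len(k), length.out = n)
    } else {
      for (cls in unique(strata)) {
        ix <- which(strata == cls)
        fold_of[sample(ix)] <- rep(seq_len(k), length.out = length(ix))
      }
    }
    split(seq_len(n), fold_of)
  })
}

# Build the pooled out-of-fold report given indices + subject metadata.
evaluation_report <- function(indices, subjects, groups, score_name,
                              threshold) {
  scores <- subjects[[score_name]][match(names(indices), subjects$id)]
  ages <- subjects$age[match(names(indices), subjects$id)]
  truth <- unname(groups[names(indices)])
  sp <- spearman_partial(indices, scores, ages)
  roc <- roc_auc(indices, truth == "normal")
  predicted <- ifelse(indices > threshold, "normal", "impaired")
  cm <- classification_metrics(predicted, truth, indices)
  reg <- regression_linear_quadratic(indices, scores)
  structure(
    list(rho = sp$rho, rho_p = sp$p, auc = roc$auc, roc_curve = roc$curve,
         accuracy = cm$accuracy, sensitivity = cm$sensitivity,
         specificity = cm$specificity, confusion = cm$confusion,
         ranksum_p = cm$ranksum_p,
         r2_linear = reg$r2_linear, r2_quadratic = reg$r2_quadratic,
         lr_p = reg$lr_p,
         per_subject = data.frame(id = names(indices), index = indices,
                                  score = scores, age = ages, group = truth,
                                  predicted = predicted,
                                  row.names = NULL)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<evaluation: n=%d  rho=%.3f (p=%.2g)  AUC=%.3f  acc=%.1f%%  ",
    "sens=%.1f%%  spec=%.1f%%  R2 lin/quad=%.2f/%.2f>\n"),
    nrow(x$per_subject), x$rho, x$rho_p, x$auc, x$accuracy, x$sensitivity,
    x$specificity, x$r2_linear, x$r2_quadratic))
  invisible(x)
}

# Out-of-fold indices for one full pass over the data (internal; operates
# on a shared feature cache so folds only refit label-dependent pieces).
oof_indices <- function(features, subjects, score_name, grouping, settings,
                        scheme, seed_offset = 0, strata = NULL,
                        rows = seq_along(features$subject_ids),
                        groups_vec = NULL) {
  n <- length(rows)
  folds <- make_folds(n, scheme, seed_offset, strata)
  if (!is.null(groups_vec)) {
    # a fold whose training half loses a whole class is flagged and re-drawn
    for (attempt in seq_len(20L)) {
      ok <- all(vapply(folds, function(f) {
        length(unique(groups_vec[-f])) == 2L
      }, logical(1)))
      if (ok) break
      message("fold left a single class in training; re-drawing folds")
      folds <- make_folds(n, scheme, seed_offset + attempt * 1009L, strata)
    }
  }
  out <- rep(NA_real_, n)
  for (fold in folds) {
    train_rows <- rows[-fold]
    model <- fit_leapd_features(features, subjects, score_name, grouping,
                                settings, train_rows)
    for (j in fold) {
      out[j] <- score_subject_features(model, features, rows[j])
    }
  }
  names(out) <- features$subject_ids[rows]
  out
}

#' Cross-validated evaluation
#'
#' For each fold the entire training protocol (configuration search,
#' subspace fits, electrode selection) is re-run on the training subjects
#' only; held-out subjects are scored with the fold's model and the pooled
#' out-of-fold indices feed the full report. k-fold schemes repeat with
#' independently seeded shuffles and report mean and sd across repeats.
#'
#' @param ds A [leapd_dataset()].
#' @param settings A [leapd_settings()].
#' @param scheme A [cv_scheme()].
#' @param score_name Cognitive score column (default `"moca"`).
#' @param grouping Class-assignment rule (default MoCA < 26).
#' @param features Optional precomputed [compute_lpc_features()] cache.
#' @param balanced If TRUE, subsample the majority class (seeded by the
#'   scheme's `shuffle_seed`) so both classes have equal size before
#'   cross-validating, and stratify fold assignment by class.
#' @return An `evaluation_report`; for repeated k-fold, the report of the
#'   first repeat with a `repeats` data.frame (rho/auc/accuracy per repeat)
#'   and `summary` (mean, sd) attached.
#' @export
cross_validate <- function(ds, settings = leapd_settings(),
                           scheme = cv_scheme("loocv"),
                           score_name = "moca",
                           grouping = list(rule = "fixed_cutoff",
                                           cutoff = 26),
                           features = NULL, balanced = FALSE) {
  problems <- validate_dataset(ds)
  if (length(problems) > 0L) {
    stop_leapd("invalid dataset: %s", paste(problems, collapse = "; "))
  }
  if (is.null(features)) {
    features <- compute_lpc_features(ds, settings$grid,
                                     line_freq = settings$line_freq)
  }
  groups_all <- assign_groups(ds$subjects, score_name, grouping$rule,
                              cutoff = grouping$cutoff %||% 26)
  rows <- seq_along(features$subject_ids)
  strata <- NULL
  if (balanced) {
    grp <- unname(groups_all[features$subject_ids])
    n_min <- min(table(grp))
    rows <- withr::with_seed(derive_seed(scheme$shuffle_seed, 991), {
      sort(unlist(lapply(split(seq_along(grp), grp),
                         function(ix) sample(ix, n_min)),
                  use.names = FALSE))
    })
    strata <- grp[rows]
  } else if (scheme$kind == "kfold") {
    strata <- unname(groups_all[features$subject_ids])[rows]
  }
  reps <- if (scheme$kind == "loocv") 1L else scheme$repeats
  rep_rows <- vector("list", reps)
  report <- NULL
  for (r in seq_len(reps)) {
    oof <- oof_indices(features, ds$subjects, score_name, grouping, settings,
                       scheme, seed_offset = r, strata = strata, rows = rows,
                       groups_vec = unname(groups_all[features$subject_ids])[rows])
    rep_report <- evaluation_report(oof, ds$subjects, groups_all, score_name,
                                    settings$threshold)
    if (r == 1L) report <- rep_report
    rep_rows[[r]] <- data.frame(repeat_ = r, rho = rep_report$rho,
                                auc = rep_report$auc,
                                accuracy = rep_report$accuracy,
                                sensitivity = rep_report$sensitivity,
                                specificity = rep_report$specificity)
  }
  rep_df <- do.call(rbind, rep_rows)
  report$repeats <- rep_df
  report$summary <- data.frame(
    metric = c("rho", "auc", "accuracy", "sensitivity", "specificity"),
    mean = vapply(rep_df[, -1L], mean, numeric(1)),
    sd = vapply(rep_df[, -1L], sd, numeric(1)),
    row.names = NULL
  )
  report
}

#' Randomization (label-shuffling) test
#'
#' Permutes the cognitive score column across subjects (recordings fixed),
#' reruns the entire pipeline -- class assignment, configuration search,
#' electrode selection, cross-validation -- on the shuffled data, and
#' reports rho / AUC / accuracy per shuffle. With informative labels
#' destroyed, performance should collapse to chance; this is the overfitting
#' control.
#'
#' @param ds A [leapd_dataset()].
#' @param settings A [leapd_settings()].
#' @param scheme A [cv_scheme()].
#' @param n_shuffles Number of shuffles (>= 1).
#' @param seed Seed for the permutations.
#' @param score_name,grouping As in [cross_validate()].
#' @param features Optional precomputed feature cache.
#' @return data.frame with one row per shuffle: `shuffle`, `rho`, `rho_p`,
#'   `auc`, `accuracy`.
#' @export
randomization_test <- function(ds, settings = leapd_settings(),
                               scheme = cv_scheme("loocv"),
                               n_shuffles = 1, seed = 1,
                               score_name = "moca",
                               grouping = list(rule = "fixed_cutoff",
                                               cutoff = 26),
                               features = NULL) {
  check_scalar(n_shuffles, "n_shuffles", 1, Inf)
  if (is.null(features)) {
    features <- compute_lpc_features(ds, settings$grid,
                                     line_freq = settings$line_freq)
  }
  rows <- lapply(seq_len(n_shuffles), function(s) {
    shuffled <- ds$subjects
    perm <- withr::with_seed(derive_seed(seed, s),
                             sample(nrow(shuffled)))
    shuffled[[score_name]] <- shuffled[[score_name]][perm]
    ds_s <- leapd_dataset(shuffled, ds$recordings)
    rep <- cross_validate(ds_s, settings, scheme, score_name, grouping,
                          features = features)
    data.frame(shuffle = s, rho = rep$rho, rho_p = rep$rho_p, auc = rep$auc,
               accuracy = rep$accuracy)
  })
  do.call(rbind, rows)
}

#' Robustness sweep
#'
#' Re-runs the cross-validated evaluation while varying either the number
#' of fused electrodes or the retained leading fraction of every recording
#' (the data-truncation experiment). For the fraction axis the whole
#' pipeline -- conditioning, encoding, search, fitting -- operates on the
#' truncated recordings.
#'
#' @param ds A [leapd_dataset()].
#' @param settings A [leapd_settings()].
#' @param axis `"n_electrodes"` or `"fraction"`.
#' @param values Axis values (electrode counts, or fractions in (0, 1]).
#' @param scheme A [cv_scheme()].
#' @param score_name,grouping As in [cross_validate()].
#' @return data.frame with one row per value: `value`, `rho`, `auc`,
#'   `accuracy`, and for the fraction axis `retained_seconds` (mean
#'   retained recording length).
#' @export
robustness_sweep <- function(ds, settings = leapd_settings(),
                             axis = c("n_electrodes", "fraction"),
                             values,
                             scheme = cv_scheme("loocv"),
                             score_name = "moca",
                             grouping = list(rule = "fixed_cutoff",
                                             cutoff = 26)) {
  axis <- match.arg(axis)
  mean_dur <- mean(vapply(ds$recordings, function(r) r$duration, numeric(1)))
  if (axis == "n_electrodes") {
    features <- compute_lpc_features(ds, settings$grid,
                                     line_freq = settings$line_freq)
    rows <- lapply(values, function(v) {
      s <- settings
      s$n_electrodes <- as.integer(v)
      rep <- cross_validate(ds, s, scheme, score_name, grouping,
                            features = features)
      data.frame(value = v, rho = rep$rho, auc = rep$auc,
                 accuracy = rep$accuracy, retained_seconds = mean_dur)
    })
  } else {
    rows <- lapply(values, function(v) {
      features <- compute_lpc_features(ds, settings$grid, fraction = v,
                                       line_freq = settings$line_freq)
      rep <- cross_validate(ds, settings, scheme, score_name, grouping,
                            features = features)
      data.frame(value = v, rho = rep$rho, auc = rep$auc,
                 accuracy = rep$accuracy, retained_seconds = mean_dur * v)
    })
  }
  do.call(rbind, rows)
}

CANONICAL_BANDS <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                        beta = c(13, 30), gamma = c(31, 100))

#' Classical spectral baselines
#'
#' Welch relative band power per canonical band (delta 1-4, theta 4-8,
#' alpha 8-13, beta 13-30, gamma 31-100 Hz) per channel, the alpha/theta
#' log-spectral ratio, the age-controlled Spearman correlation of each
#' feature with the cognitive score, and each feature's AUC for the group
#' labels.
#'
#' @param ds A [leapd_dataset()].
#' @param score_name Cognitive score column (default `"moca"`).
#' @param grouping Class-assignment rule (default MoCA < 26).
#' @return data.frame: `channel`, `feature`, `rho`, `p`, `auc`.
#' @export
spectral_baselines <- function(ds, score_name = "moca",
                               grouping = list(rule = "fixed_cutoff",
                                               cutoff = 26)) {
  ids <- ds$subjects$id
  channels <- ds$recordings[[ids[1L]]]$channel_labels
  scores <- ds$subjects[[score_name]]
  ages <- ds$subjects$age
  groups <- assign_groups(ds$subjects, score_name, grouping$rule,
                          cutoff = grouping$cutoff %||% 26)
  truth_normal <- unname(groups[ids]) == "normal"
  out <- list()
  for (ch in channels) {
    feats <- matrix(NA_real_, nrow = length(ids),
                    ncol = length(CANONICAL_BANDS) + 1L)
    colnames(feats) <- c(names(CANONICAL_BANDS), "alpha_theta_log_ratio")
    for (si in seq_along(ids)) {
      rec <- ds$recordings[[ids[si]]]
      w <- welch_psd(get_channel(rec, ch), rec$sample_rate)
      total <- band_power_from_psd(w$freq, w$psd, 1,
                                   min(100, rec$sample_rate / 2 - 1e-9))
      powers <- vapply(CANONICAL_BANDS, function(b) {
        band_power_from_psd(w$freq, w$psd, b[1],
                            min(b[2], rec$sample_rate / 2 - 1e-9))
      }, numeric(1))
      feats[si, seq_along(powers)] <- powers / total
      feats[si, "alpha_theta_log_ratio"] <-
        log(powers[["alpha"]]) - log(powers[["theta"]])
    }
    for (fname in colnames(feats)) {
      sp <- tryCatch(spearman_partial(feats[, fname], scores, ages),
                     error = function(e) list(rho = NA_real_, p = NA_real_))
      auc <- tryCatch(roc_auc(feats[, fname], truth_normal)$auc,
                      error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        channel = ch, feature = fname, rho = sp$rho, p = sp$p, auc = auc)
    }
  }
  do.call(rbind, out)
}
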