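# Training protocol: class assignment from cognitive scores, per-electrode
# search over band/order/subspace-dimension configurations, electrode
# selection by training correlation, and subject scoring.
#
# LPC feature vectors depend only on (recording, channel, band, order) --
# never on class labels -- so they are computed once per dataset and reused
# across cross-validation folds; everything label-dependent (subspace fits,
# config selection, electrode ranking) is refitted inside each fold.

#' Assign subjects to cognitive classes
#'
#' `fixed_cutoff`: score < cutoff is impaired (the MoCA convention with
#' cutoff 26). `median_cut`: score below the cohort median is impaired,
#' used for continuous scores without an established cutoff.
#'
#' @param subjects data.frame with an `id` column and the score column.
#' @param score_name Name of the score column.
#' @param rule `"fixed_cutoff"` or `"median_cut"`.
#' @param cutoff Cutoff for `fixed_cutoff` (default 26, the MoCA
#'   impairment threshold).
#' @return Named character vector, id -> `"normal"` / `"impaired"`.
#' @export
assign_groups <- function(subjects, score_name = "moca",
                          rule = c("fixed_cutoff", "median_cut"),
                          cutoff = 26) {
  rule <- match.arg(rule)
  if (!score_name %in% names(subjects)) {
    stop_leapd("score column '%s' not found", score_name)
  }
  s <- subjects[[score_name]]
  if (any(is.na(s))) stop_leapd("missing %s score(s)", score_name)
  thr <- if (rule == "fixed_cutoff") cutoff else median(s)
  out <- ifelse(s < thr, "impaired", "normal")
  if (length(unique(out)) < 2L) {
    stop_leapd("grouping by %s (%s) leaves one class empty", score_name, rule)
  }
  names(out) <- subjects$id
  out
}

#' Single-electrode model configuration
#'
#' @param channel Channel label.
#' @param f_lo,f_hi Analysis band edges in Hz.
#' @param order LPC order.
#' @param k_normal,k_impaired Affine-subspace dimensions per class.
#' @return A `channel_config` list.
#' @export
channel_config <- function(channel, f_lo, f_hi, order,
                           k_normal = 3, k_impaired = 3) {
  structure(list(channel = channel, band = band(f_lo, f_hi),
                 order = as.integer(order),
                 k_normal = as.integer(k_normal),
                 k_impaired = as.integer(k_impaired)),
            class = "channel_config")
}

#' Default hyperparameter search grid
#'
#' Band edges span low-frequency through broad ranges
#' (`f_lo` 1-8 Hz, `f_hi` 10-50 Hz with `f_hi > f_lo + 4`), LPC orders
#' 6-20, subspace dimensions 1-5.
#'
#' @return data.frame with columns `f_lo`, `f_hi`, `order`, `k_normal`,
#'   `k_impaired`.
#' @export
default_grid <- function() {
  g <- expand.grid(f_lo = c(1, 2, 4, 6, 8), f_hi = c(10, 13, 20, 30, 50),
                   order = c(6, 10, 14, 20), k = c(1, 3, 5))
  g <- g[g$f_hi > g$f_lo + 4, ]
  data.frame(f_lo = g$f_lo, f_hi = g$f_hi, order = g$order,
             k_normal = g$k, k_impaired = g$k)
}

#' Reduced search grid
#'
#' A 8-configuration grid (4 bands x 2 orders, k = 3) covering the
#' theta-alpha and beta ranges; the grid used by the package's own
#' end-to-end validation runs, where the full grid's extra resolution does
#' not change the outcome but multiplies the cost.
#'
#' @return data.frame as in [default_grid()].
#' @export
reduced_grid <- function() {
  g <- expand.grid(f_lo = c(2, 6), f_hi = c(13, 30), order = c(6, 10))
  data.frame(f_lo = g$f_lo, f_hi = g$f_hi, order = g$order,
             k_normal = 3, k_impaired = 3)
}

#' Training settings
#'
#' @param grid Search grid, as from [default_grid()] or [reduced_grid()].
#' @param n_electrodes Number of electrodes fused into the combined index
#'   (default 8).
#' @param threshold Classification threshold on the combined index
#'   (default 0.5, the symmetry point).
#' @param line_freq Notch frequency in Hz, `NULL` to disable (default 60).
#' @param criterion Config-scoring criterion: `"partial_spearman"`
#'   (age-controlled rank correlation between single-channel index and the
#'   cognitive score; default) or `"auc"`.
#' @return A `leapd_settings` list.
#' @export
leapd_settings <- function(grid = default_grid(), n_electrodes = 8,
                           threshold = 0.5, line_freq = 60,
                           criterion = c("partial_spearman", "auc")) {
  criterion <- match.arg(criterion)
  check_scalar(threshold, "threshold", 0, 1)
  if (threshold <= 0 || threshold >= 1) {
    stop_leapd("threshold must lie strictly inside (0, 1)")
  }
  structure(list(grid = grid, n_electrodes = as.integer(n_electrodes),
                 threshold = threshold, line_freq = line_freq,
                 criterion = criterion),
            class = "leapd_settings")
}

feature_key <- function(f_lo, f_hi, order) {
  sprintf("%g-%g|p%d", f_lo, f_hi, order)
}

#' Precompute LPC feature vectors for a dataset
#'
#' Conditions every (subject, channel, band) combination once (notch,
#' zero-phase band-pass, unit-power normalization), estimates the
#' autocorrelation up to the largest order the grid requests for that band,
#' and stores the Levinson-Durbin coefficients for each requested order.
#' Purely unsupervised, so the cache can safely be shared across
#' cross-validation folds.
#'
#' @param ds A [leapd_dataset()].
#' @param grid Search grid (see [default_grid()]).
#' @param fraction Leading fraction of each recording to use, in (0, 1]
#'   (default 1).
#' @param line_freq Notch frequency or `NULL` (default 60).
#' @return A `leapd_features` object (internal layout: per-channel,
#'   per-configuration subject x order coefficient matrices).
#' @export
compute_lpc_features <- function(ds, grid, fraction = 1, line_freq = 60) {
  ids <- ds$subjects$id
  channels <- ds$recordings[[ids[1L]]]$channel_labels
  sample_rate <- ds$recordings[[ids[1L]]]$sample_rate
  bands <- unique(grid[, c("f_lo", "f_hi")])
  feat <- lapply(channels, function(ch) list())
  names(feat) <- channels
  for (bi in seq_len(nrow(bands))) {
    f_lo <- bands$f_lo[bi]; f_hi <- bands$f_hi[bi]
    orders <- sort(unique(grid$order[grid$f_lo == f_lo & grid$f_hi == f_hi]))
    for (ch in channels) {
      for (p in orders) {
        feat[[ch]][[feature_key(f_lo, f_hi, p)]] <-
          matrix(NA_real_, nrow = length(ids), ncol = p,
                 dimnames = list(ids, NULL))
      }
    }
  }
  for (si in seq_along(ids)) {
    rec <- ds$recordings[[ids[si]]]
    for (ch in channels) {
      x <- get_channel(rec, ch)
      if (fraction < 1) x <- truncate_fraction(x, fraction)
      # the notch does not depend on the band: apply it once per channel
      if (!is.null(line_freq)) x <- notch_line(x, sample_rate, line_freq)
      for (bi in seq_len(nrow(bands))) {
        f_lo <- bands$f_lo[bi]; f_hi <- bands$f_hi[bi]
        orders <- sort(unique(grid$order[grid$f_lo == f_lo &
                                           grid$f_hi == f_hi]))
        y <- normalize_unit_power(
          bandpass_zero_phase(x, sample_rate, band(f_lo, f_hi)))
        r <- autocorr_biased(y, max(orders))
        for (p in orders) {
          feat[[ch]][[feature_key(f_lo, f_hi, p)]][si, ] <-
            levinson_durbin(r, p)$coefficients
        }
      }
    }
  }
  structure(list(subject_ids = ids, channels = channels,
                 sample_rate = sample_rate, fraction = fraction,
                 line_freq = line_freq, feat = feat),
            class = "leapd_features")
}

# Order grid rows for deterministic tie-breaking: lower LPC order first,
# then lower f_lo, then the remaining knobs.
order_grid <- function(grid) {
  grid[order(grid$order, grid$f_lo, grid$f_hi, grid$k_normal,
             grid$k_impaired), , drop = FALSE]
}

# Fit both class subspaces for one config on the training rows and return
# training indices for those rows.
fit_config_on_features <- function(M, groups_vec, k_normal, k_impaired) {
  idx_n <- which(groups_vec == "normal")
  idx_i <- which(groups_vec == "impaired")
  if (k_normal >= length(idx_n) || k_impaired >= length(idx_i)) return(NULL)
  s_n <- fit_affine_subspace(M[idx_n, , drop = FALSE], k_normal, "normal")
  s_i <- fit_affine_subspace(M[idx_i, , drop = FALSE], k_impaired, "impaired")
  idx <- leapd_index(distances_to_subspace(M, s_n),
                     distances_to_subspace(M, s_i))
  list(subspace_normal = s_n, subspace_impaired = s_i, index = idx)
}

# Grid search over one channel's cached features (internal work-horse).
grid_search_channel_features <- function(features, channel, grid, groups_vec,
                                         scores, ages, train_rows,
                                         criterion = "partial_spearman") {
  grid <- order_grid(grid)
  best <- NULL
  best_crit <- -Inf
  for (gi in seq_len(nrow(grid))) {
    key <- feature_key(grid$f_lo[gi], grid$f_hi[gi], grid$order[gi])
    M <- features$feat[[channel]][[key]][train_rows, , drop = FALSE]
    fit <- fit_config_on_features(M, groups_vec, grid$k_normal[gi],
                                  grid$k_impaired[gi])
    if (is.null(fit)) next
    crit <- tryCatch({
      if (criterion == "partial_spearman") {
        spearman_partial(fit$index, scores, ages)$rho
      } else {
        roc_auc(fit$index, groups_vec == "normal")$auc
      }
    }, error = function(e) NA_real_)
    if (is.finite(crit) && crit > best_crit) {
      best_crit <- crit
      best <- list(
        config = channel_config(channel, grid$f_lo[gi], grid$f_hi[gi],
                                grid$order[gi], grid$k_normal[gi],
                                grid$k_impaired[gi]),
        subspace_normal = fit$subspace_normal,
        subspace_impaired = fit$subspace_impaired,
        train_correlation = best_crit
      )
    }
  }
  if (is.null(best)) {
    stop_leapd("no feasible configuration for channel %s (subspace dimensions must be below class sizes)",
               channel)
  }
  structure(best, class = "channel_model")
}

#' Hyperparameter search for one electrode
#'
#' Fits both class subspaces for every configuration in the grid on the
#' training subjects, scores each configuration by the age-controlled
#' Spearman correlation between the single-channel index and the cognitive
#' score (or by training AUC), and returns the best configuration's fitted
#' model. Ties break toward the lower LPC order, then the lower band edge.
#'
#' @param ds A [leapd_dataset()] (the training subjects).
#' @param channel Channel label.
#' @param grid Search grid (see [default_grid()]).
#' @param score_name Score column used for the criterion.
#' @param groups Named id -> class vector from [assign_groups()].
#' @param settings A [leapd_settings()] (criterion and notch are taken from
#'   here).
#' @return A `channel_model`: config, the two fitted subspaces, and the
#'   training criterion value.
#' @export
grid_search_channel <- function(ds, channel, grid = default_grid(),
                                score_name = "moca",
                                groups = assign_groups(ds$subjects, score_name),
                                settings = leapd_settings(grid = grid)) {
  features <- compute_lpc_features(ds, grid, line_freq = settings$line_freq)
  grid_search_channel_features(
    features, channel, grid,
    groups_vec = unname(groups[features$subject_ids]),
    scores = ds$subjects[[score_name]][match(features$subject_ids,
                                             ds$subjects$id)],
    ages = ds$subjects$age[match(features$subject_ids, ds$subjects$id)],
    train_rows = seq_along(features$subject_ids),
    criterion = settings$criterion
  )
}

#' Select the best-performing electrodes
#'
#' @param channel_models List of `channel_model` objects.
#' @param n Number of electrodes to keep.
#' @return Character vector of the `n` labels with the highest training
#'   criterion; ties break lexicographically by label.
#' @export
select_electrodes <- function(channel_models, n) {
  check_scalar(n, "n", 1, Inf)
  if (n > length(channel_models)) {
    stop_leapd("requested %d electrodes but only %d models given",
               n, length(channel_models))
  }
  labels <- vapply(channel_models, function(m) m$config$channel, character(1))
  corrs <- vapply(channel_models, function(m) m$train_correlation, numeric(1))
  ord <- order(-corrs, labels)
  labels[ord][seq_len(as.integer(n))]
}

# Internal fit on cached features over a subset of subjects (a CV training
# fold).  Returns the model plus enough bookkeeping to score any cached
# subject.
fit_leapd_features <- function(features, subjects, score_name, grouping,
                               settings, train_rows = NULL) {
  ids <- features$subject_ids
  if (is.null(train_rows)) train_rows <- seq_along(ids)
  sub <- subjects[match(ids[train_rows], subjects$id), , drop = FALSE]
  groups <- assign_groups(sub, score_name, grouping$rule,
                          cutoff = grouping$cutoff %||% 26)
  groups_vec <- unname(groups[sub$id])
  scores <- sub[[score_name]]
  ages <- sub$age
  if (settings$n_electrodes > length(features$channels)) {
    stop_leapd("n_electrodes (%d) exceeds available channels (%d)",
               settings$n_electrodes, length(features$channels))
  }
  models <- lapply(features$channels, function(ch) {
    grid_search_channel_features(features, ch, settings$grid, groups_vec,
                                 scores, ages, train_rows,
                                 settings$criterion)
  })
  names(models) <- features$channels
  keep <- select_electrodes(models, settings$n_electrodes)
  structure(
    list(channel_models = models[keep],
         n_electrodes = settings$n_electrodes,
         threshold = settings$threshold,
         grouping_rule = sprintf("%s %s (%s)", score_name, grouping$rule,
                                 grouping$cutoff %||% "median"),
         score_name = score_name,
         sample_rate = features$sample_rate,
         line_freq = features$line_freq),
    class = "leapd_model"
  )
}

# Score a cached subject row through a fitted model.
score_subject_features <- function(model, features, row) {
  idx <- vapply(model$channel_models, function(cm) {
    key <- feature_key(cm$config$band$f_lo, cm$config$band$f_hi,
                       cm$config$order)
    v <- features$feat[[cm$config$channel]][[key]][row, ]
    leapd_index(distance_to_subspace(v, cm$subspace_normal),
                distance_to_subspace(v, cm$subspace_impaired))
  }, numeric(1))
  combine_channels(idx)
}

#' Fit a combined-index model
#'
#' Runs the per-electrode configuration search on every channel of the
#' training set, ranks electrodes by the training criterion, and keeps the
#' top `n_electrodes`. Deterministic given its inputs.
#'
#' @param ds A [leapd_dataset()] (the training subjects).
#' @param score_name Cognitive score column driving class assignment and
#'   the search criterion (default `"moca"`).
#' @param grouping List with `rule` (`"fixed_cutoff"` or `"median_cut"`)
#'   and, for the former, `cutoff` (default: MoCA < 26 is impaired).
#' @param settings A [leapd_settings()].
#' @param features Optional precomputed [compute_lpc_features()] cache for
#'   exactly this dataset.
#' @return A `leapd_model`: the selected electrodes' fitted channel models,
#'   threshold, and grouping description.
#' @export
fit_leapd <- function(ds, score_name = "moca",
                      grouping = list(rule = "fixed_cutoff", cutoff = 26),
                      settings = leapd_settings(),
                      features = NULL) {
  if (is.null(features)) {
    features <- compute_lpc_features(ds, settings$grid,
                                     line_freq = settings$line_freq)
  }
  fit_leapd_features(features, ds$subjects, score_name, grouping, settings)
}

#' @export
print.leapd_model <- function(x, ...) {
  cat(sprintf("<combined-index model: %d electrodes (%s), threshold %.2f, grouping %s>\n",
              length(x$channel_models),
              paste(names(x$channel_models), collapse = ", "),
              x$threshold, x$grouping_rule))
  invisible(x)
}

#' Score a recording with a fitted model
#'
#' For each selected electrode: condition and LPC-encode the channel with
#' that electrode's configuration, take the distances to the two class
#' subspaces, and form the bounded index; the per-electrode indices are
#' fused by geometric mean.
#'
#' @param model A `leapd_model`.
#' @param rec An [eeg_recording()] containing every selected channel.
#' @return Combined index in [0, 1]; higher means closer to the
#'   cognitively normal class.
#' @export
score_subject <- function(model, rec) {
  idx <- vapply(model$channel_models, function(cm) {
    x <- get_channel(rec, cm$config$channel)
    v <- lpc_encode(x, rec$sample_rate, cm$config$band, cm$config$order,
                    line_freq = model$line_freq,
                    channel = cm$config$channel)$coefficients
    leapd_index(distance_to_subspace(v, cm$subspace_normal),
                distance_to_subspace(v, cm$subspace_impaired))
  }, numeric(1))
  combine_channels(idx)
}

#' Classify a recording
#'
#' @param model A `leapd_model`.
#' @param rec An [eeg_recording()].
#' @return `"normal"` if the combined index exceeds the model threshold,
#'   `"impaired"` otherwise (the boundary counts as impaired).
#' @export
classify_subject <- function(model, rec) {
  if (score_subject(model, rec) > model$threshold) "normal" else "impaired"
}

#' Serialize a fitted model to JSON
#'
#' @param model A `leapd_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_leapd_model <- function(model, path) {
  ser_sub <- function(s) list(centroid = s$centroid,
                              basis = unclass(s$basis), dim = s$dim,
                              class_label = s$class_label)
  doc <- list(
    format = "leapd-model", version = 1L,
    score_name = model$score_name, grouping_rule = model$grouping_rule,
    threshold = model$threshold, sample_rate = model$sample_rate,
    line_freq = model$line_freq, n_electrodes = model$n_electrodes,
    channel_models = lapply(model$channel_models, function(cm) {
      list(channel = cm$config$channel,
           f_lo = cm$config$band$f_lo, f_hi = cm$config$band$f_hi,
           order = cm$config$order,
           k_normal = cm$config$k_normal, k_impaired = cm$config$k_impaired,
           train_correlation = cm$train_correlation,
           subspace_normal = ser_sub(cm$subspace_normal),
           subspace_impaired = ser_sub(cm$subspace_impaired))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_leapd_model()]
#'
#' @param path JSON model file.
#' @return A `leapd_model`.
#' @export
read_leapd_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "leapd-model")) {
    stop_leapd("'%s' is not a serialized model", path)
  }
  de_sub <- function(s) {
    basis <- s$basis
    if (is.null(basis) || length(basis) == 0L) {
      basis <- matrix(numeric(0), nrow = length(s$centroid), ncol = 0L)
    }
    if (!is.matrix(basis)) basis <- matrix(basis, ncol = s$dim)
    structure(list(centroid = as.numeric(s$centroid), basis = basis,
                   dim = as.integer(s$dim), class_label = s$class_label),
              class = "affine_subspace")
  }
  cms <- lapply(doc$channel_models, function(cm) {
    structure(list(
      config = channel_config(cm$channel, cm$f_lo, cm$f_hi, cm$order,
                              cm$k_normal, cm$k_impaired),
      subspace_normal = de_sub(cm$subspace_normal),
      subspace_impaired = de_sub(cm$subspace_impaired),
      train_correlation = cm$train_correlation
    ), class = "channel_model")
  })
  names(cms) <- vapply(cms, function(cm) cm$config$channel, character(1))
  structure(
    list(channel_models = cms, n_electrodes = doc$n_electrodes,
         threshold = doc$threshold, grouping_rule = doc$grouping_rule,
         score_name = doc$score_name, sample_rate = doc$sample_rate,
         line_freq = doc$line_freq),
    class = "leapd_model"
  )
}
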