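# Training protocol: group assignment, per-electrode search, electrode
# selection, model fitting/scoring, serialization.

test_that("group assignment follows the cutoff and median rules", {
  subjects <- data.frame(id = c("a", "b", "c", "d"),
                         moca = c(25, 26, 30, 20), age = c(60, 61, 62, 63))
  g <- assign_groups(subjects, "moca", "fixed_cutoff", cutoff = 26)
  expect_equal(unname(g[c("a", "b")]), c("impaired", "normal"))

  subjects2 <- data.frame(id = letters[1:4], s = c(10, 20, 30, 40),
                          age = 60:63)
  g2 <- assign_groups(subjects2, "s", "median_cut")
  expect_equal(unname(g2), c("impaired", "impaired", "normal", "normal"))

  subjects3 <- data.frame(id = letters[1:4], s = rep(5, 4), age = 60:63)
  expect_error(assign_groups(subjects3, "s", "median_cut"), "empty")
})

test_that("electrode selection ranks by training correlation with lexicographic ties", {
  mk <- function(ch, r) {
    structure(list(config = channel_config(ch, 4, 13, 6),
                   train_correlation = r), class = "channel_model")
  }
  models <- list(mk("A", 0.9), mk("B", 0.5), mk("C", 0.7))
  expect_equal(select_electrodes(models, 2), c("A", "C"))
  ties <- list(mk("Pz", 0.6), mk("Cz", 0.6), mk("Fz", 0.8))
  expect_equal(select_electrodes(ties, 2), c("Fz", "Cz"))
  expect_error(select_electrodes(models, 5), "only 3")
  expect_error(select_electrodes(models, 0), "n must be")
})

test_that("the grid search prefers the band that contains the cognition effect", {
  coh <- tiny_cohort(n_subjects = 20, duration = 12, seed = 8)
  ds <- cohort_dataset(coh)
  grid <- data.frame(f_lo = c(4, 35), f_hi = c(13, 45), order = 6,
                     k_normal = 2, k_impaired = 2)
  cm <- grid_search_channel(ds, "P8", grid, "moca",
                            groups = assign_groups(ds$subjects, "moca",
                                                   "median_cut"),
                            settings = leapd_settings(grid = grid,
                                                      n_electrodes = 4))
  expect_equal(cm$config$band$f_lo, 4)
  expect_equal(cm$config$band$f_hi, 13)
  expect_true(is.finite(cm$train_correlation))
})

test_that("single-config grids return that config fitted, and ties break to lower order", {
  coh <- tiny_cohort(n_subjects = 12, duration = 8, seed = 10)
  ds <- cohort_dataset(coh)
  grid1 <- data.frame(f_lo = 6, f_hi = 13, order = 4, k_normal = 1,
                      k_impaired = 1)
  cm <- grid_search_channel(ds, "P8", grid1, "moca",
                            groups = assign_groups(ds$subjects, "moca",
                                                   "median_cut"),
                            settings = leapd_settings(grid = grid1,
                                                      n_electrodes = 4))
  expect_equal(cm$config$order, 4L)
  expect_equal(cm$subspace_normal$class_label, "normal")
  expect_equal(cm$subspace_impaired$class_label, "impaired")
  # duplicated config rows give an exact criterion tie; the first row in
  # (order, f_lo) order must win, i.e. the result is unchanged
  grid2 <- rbind(grid1, grid1)
  cm2 <- grid_search_channel(ds, "P8", grid2, "moca",
                             groups = assign_groups(ds$subjects, "moca",
                                                    "median_cut"),
                             settings = leapd_settings(grid = grid2,
                                                       n_electrodes = 4))
  expect_equal(cm2$config, cm$config)
  expect_equal(cm2$train_correlation, cm$train_correlation)
})

test_that("model fitting is deterministic, separates training groups, and validates", {
  coh <- tiny_cohort(n_subjects = 20, duration = 12, seed = 8)
  ds <- cohort_dataset(coh)
  settings <- leapd_settings(
    grid = data.frame(f_lo = c(4, 6), f_hi = c(13, 30), order = 6,
                      k_normal = 2, k_impaired = 2),
    n_electrodes = 4)
  grouping <- list(rule = "median_cut")
  m1 <- fit_leapd(ds, "moca", grouping, settings)
  m2 <- fit_leapd(ds, "moca", grouping, settings)
  expect_length(m1$channel_models, 4)
  expect_identical(names(m1$channel_models), names(m2$channel_models))
  expect_equal(m1$channel_models[[1]]$subspace_normal$centroid,
               m2$channel_models[[1]]$subspace_normal$centroid)

  groups <- assign_groups(ds$subjects, "moca", "median_cut")
  idx <- vapply(ds$subjects$id, function(id) {
    score_subject(m1, ds$recordings[[id]])
  }, numeric(1))
  expect_true(all(idx >= 0 & idx <= 1))
  expect_lt(mean(idx[groups[ds$subjects$id] == "impaired"]),
            mean(idx[groups[ds$subjects$id] == "normal"]))

  # determinism of scoring
  id1 <- ds$subjects$id[1]
  expect_identical(score_subject(m1, ds$recordings[[id1]]),
                   score_subject(m1, ds$recordings[[id1]]))

  # classification convention: boundary counts as impaired
  m_thr <- m1
  m_thr$threshold <- idx[[id1]]
  expect_equal(classify_subject(m_thr, ds$recordings[[id1]]), "impaired")

  expect_error(fit_leapd(ds, "moca", grouping,
                         leapd_settings(grid = settings$grid,
                                        n_electrodes = 99)),
               "exceeds")
})

test_that("scoring a recording without a selected channel names the channel", {
  coh <- tiny_cohort(n_subjects = 12, duration = 8, seed = 10)
  ds <- cohort_dataset(coh)
  settings <- leapd_settings(
    grid = data.frame(f_lo = 6, f_hi = 13, order = 4, k_normal = 1,
                      k_impaired = 1),
    n_electrodes = 2)
  m <- fit_leapd(ds, "moca", list(rule = "median_cut"), settings)
  rec <- ds$recordings[[1]]
  keep <- setdiff(rec$channel_labels, names(m$channel_models)[1])
  rec_sub <- eeg_recording(rec$subject_id, keep, rec$sample_rate,
                           rec$samples[match(keep, rec$channel_labels), ])
  expect_error(score_subject(m, rec_sub), names(m$channel_models)[1])
})

test_that("model serialization roundtrips scoring exactly", {
  coh <- tiny_cohort(n_subjects = 12, duration = 8, seed = 10)
  ds <- cohort_dataset(coh)
  settings <- leapd_settings(
    grid = data.frame(f_lo = c(4, 6), f_hi = c(13, 30), order = c(4, 6),
                      k_normal = 1, k_impaired = 1),
    n_electrodes = 3)
  m <- fit_leapd(ds, "moca", list(rule = "median_cut"), settings)
  path <- file.path(tempdir(), "model.json")
  write_leapd_model(m, path)
  m2 <- read_leapd_model(path)
  expect_identical(names(m2$channel_models), names(m$channel_models))
  for (id in ds$subjects$id[1:3]) {
    expect_equal(score_subject(m2, ds$recordings[[id]]),
                 score_subject(m, ds$recordings[[id]]), tolerance = 1e-12)
  }
})
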