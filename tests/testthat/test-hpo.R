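test_that("kfold_split yields balanced, disjoint, exhaustive folds", {
  ds50 <- random_dataset(50, 2, seed = 1)
  folds <- kfold_split(ds50, k = 5, seed = 7)
  expect_length(folds, 5L)
  val_sizes <- vapply(folds, function(f) length(f$validation$images), 0L)
  expect_identical(val_sizes, rep(10L, 5L))
  all_files <- morphmark:::dataset_files(ds50)
  val_files <- lapply(folds, function(f) morphmark:::dataset_files(f$validation))
  # partition: pairwise disjoint, union = everything
  expect_identical(sort(unlist(val_files)), sort(all_files))
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(val_files[[i]], val_files[[j]]), 0L)
  # no leak: validation images absent from the fold's training part
  for (f in folds)
    expect_length(intersect(morphmark:::dataset_files(f$train),
                            morphmark:::dataset_files(f$validation)), 0L)
  # remainder distribution rule
  ds52 <- random_dataset(52, 2, seed = 2)
  sizes52 <- sort(vapply(kfold_split(ds52, 5, seed = 1),
                         function(f) length(f$validation$images), 0L))
  expect_identical(sizes52, c(10L, 10L, 10L, 11L, 11L))
  # deterministic given seed
  expect_identical(
    lapply(kfold_split(ds50, 5, seed = 3), function(f)
      morphmark:::dataset_files(f$validation)),
    lapply(kfold_split(ds50, 5, seed = 3), function(f)
      morphmark:::dataset_files(f$validation)))
  expect_error(kfold_split(random_dataset(3, 2), k = 5), "exceeds")
})

test_that("run_trial scores by mean fold deviation and matches a manual loop", {
  d <- fixture_dir(15, fixture_params(seed = 61))
  ds <- read_landmark_xml(file.path(d, "landmarks.xml"))
  hp <- tiny_hp()
  tr <- run_trial(ds, hp, k = 5, seed = 11, trial_index = 3)
  expect_s3_class(tr, "trial_record")
  expect_equal(tr$trial_index, 3L)
  expect_length(tr$fold_deviations, 5L)
  expect_equal(tr$mean_deviation, mean(tr$fold_deviations))
  # independent oracle: the same folds and seeds, scripted by hand
  folds <- kfold_split(ds, k = 5, seed = 11)
  manual <- vapply(seq_along(folds), function(f) {
    m <- train_predictor(folds[[f]]$train, hp,
                         seed = morphmark:::derive_seed(11, f))
    mean_deviation(m, folds[[f]]$validation)
  }, 0)
  expect_equal(tr$fold_deviations, manual)
  expect_equal(tr$mean_deviation, mean(manual))
  unlink(d, recursive = TRUE)
})

test_that("study machinery: in-range sampling, argmin best, cumulative minimum", {
  d <- fixture_dir(12, fixture_params(seed = 71))
  ds <- read_landmark_xml(file.path(d, "landmarks.xml"))
  rg <- fixture_search_ranges()
  st <- run_study(ds, n_trials = 4, ranges = rg, k = 3, seed = 5,
                  sampler = "random")
  scores <- vapply(st$trials, `[[`, 0, "mean_deviation")
  expect_equal(st$best_index, which.min(scores))
  for (tr in st$trials)
    expect_true(morphmark:::hp_in_ranges(tr$hyperparameters, rg))
  # running minimum is non-increasing (the convergence-curve property)
  expect_true(all(diff(cummin(scores)) <= 0))
  # one-trial study trivially selects trial 0
  st1 <- run_study(ds, n_trials = 1, ranges = rg, k = 3, seed = 6)
  expect_equal(st1$best_index, 1L)
  expect_equal(best_trial(st1)$trial_index, 0L)
  # adaptive sampler also stays in range
  sta <- run_study(ds, n_trials = 4, ranges = rg, k = 3, seed = 7,
                   sampler = "adaptive")
  for (tr in sta$trials)
    expect_true(morphmark:::hp_in_ranges(tr$hyperparameters, rg))
  unlink(d, recursive = TRUE)
})

test_that("finalize_model retrains on all data with the winning trial's config", {
  d <- fixture_dir(10, fixture_params(seed = 81))
  ds <- read_landmark_xml(file.path(d, "landmarks.xml"))
  st <- run_study(ds, n_trials = 2, ranges = fixture_search_ranges(),
                  k = 2, seed = 3)
  m <- finalize_model(ds, st, seed = 4)
  bt <- best_trial(st)
  expect_identical(m$hyperparameters, bt$hyperparameters)
  expect_equal(m$n_train_images, 10L)
  expect_equal(m$provenance$best_trial_index, bt$trial_index)
  # the sidecar reports the study provenance, including cascade_depth
  mp <- tempfile(fileext = ".bin")
  save_predictor(m, mp)
  side <- jsonlite::read_json(paste0(mp, ".json"))
  expect_equal(side$hyperparameters$cascade_depth,
               bt$hyperparameters$cascade_depth)
  expect_equal(side$provenance$best_trial_index, bt$trial_index)
  unlink(c(d, mp, paste0(mp, ".json")), recursive = TRUE)
})

test_that("deviation_cdf counts trials below a relative deviation", {
  mk <- function(score, idx) structure(
    list(trial_index = idx, hyperparameters = tiny_hp(),
         fold_deviations = rep(score, 5), mean_deviation = score,
         status = if (is.finite(score)) "ok" else "failed"),
    class = "trial_record")
  trials <- Map(mk, c(1, 2, 3, 4), 0:3)
  cdf <- deviation_cdf(trials, diagonal_px = 100) # scores become 1..4%
  expect_equal(cdf(2), 0.5)
  expect_equal(cdf(0.5), 0)   # below the minimum score
  expect_equal(cdf(4), 1)     # at the maximum
  expect_equal(cdf(9), 1)
  # monotone non-decreasing, right-continuous step function
  xs <- seq(0, 5, by = 0.1)
  expect_true(all(diff(cdf(xs)) >= 0))
  # failed trials are excluded; all-failed errors
  expect_equal(deviation_cdf(c(trials, Map(mk, Inf, 4L)), 100)(4), 1)
  expect_error(deviation_cdf(Map(mk, Inf, 0L), 100), "no successful")
})

test_that("studies serialize to JSON and back, preserving the best trial", {
  d <- fixture_dir(8, fixture_params(seed = 91))
  ds <- read_landmark_xml(file.path(d, "landmarks.xml"))
  st <- run_study(ds, n_trials = 2, ranges = fixture_search_ranges(),
                  k = 2, seed = 12)
  p <- tempfile(fileext = ".json")
  write_study_json(st, p)
  back <- read_study_json(p)
  expect_equal(back$best_index, st$best_index)
  # real-valued fields round-trip through decimal JSON: tolerance 1e-12
  expect_equal(best_trial(back)$hyperparameters,
               best_trial(st)$hyperparameters, tolerance = 1e-12)
  expect_equal(best_trial(back)$mean_deviation,
               best_trial(st)$mean_deviation)
  expect_equal(back$k, st$k)
  expect_equal(vapply(back$trials, `[[`, 0, "mean_deviation"),
               vapply(st$trials, `[[`, 0, "mean_deviation"))
  unlink(c(d, p), recursive = TRUE)
})
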