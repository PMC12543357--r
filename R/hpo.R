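#' Hyperparameter search ranges
#'
#' Declares, for each of the nine shape-predictor hyperparameters, its
#' `(low, high)` bounds, sampling scale (`"linear"` or `"log"`), and type
#' (`"int"` or `"real"`). [default_search_ranges()] gives the
#' full-scale defaults; [fixture_search_ranges()] is a documented
#' desk-scale narrowing (same parameters, same scales) used by the test
#' suite so a complete cross-validated study finishes in minutes on one
#' CPU core.
#'
#' @param ... per-parameter specifications, each
#'   `list(low =, high =, scale =, type =)`.
#' @return a `search_ranges` object.
#' @export
search_ranges <- function(...) {
  rg <- list(...)
  needed <- names(formals(hyperparameters))
  if (!setequal(names(rg), needed))
    stop("search_ranges must specify exactly the nine hyperparameters; ",
         "missing: ", paste(setdiff(needed, names(rg)), collapse = ", "))
  for (nm in names(rg)) {
    r <- rg[[nm]]
    stopifnot(r$low <= r$high, r$scale %in% c("linear", "log"),
              r$type %in% c("int", "real"))
  }
  structure(rg[needed], class = "search_ranges")
}

range_spec <- function(low, high, scale = "linear", type = "real")
  list(low = low, high = high, scale = scale, type = type)

#' @rdname search_ranges
#' @export
default_search_ranges <- function() {
  search_ranges(
    cascade_depth = range_spec(8L, 18L, "linear", "int"),
    tree_depth = range_spec(2L, 5L, "linear", "int"),
    trees_per_cascade = range_spec(250L, 750L, "linear", "int"),
    learning_rate = range_spec(0.01, 0.3, "log", "real"),
    oversampling = range_spec(5L, 40L, "linear", "int"),
    feature_pool_size = range_spec(200L, 1000L, "linear", "int"),
    test_splits = range_spec(20L, 150L, "linear", "int"),
    feature_pool_padding = range_spec(0, 0.2, "linear", "real"),
    regularization = range_spec(0.01, 0.2, "log", "real"))
}

#' @rdname search_ranges
#' @export
fixture_search_ranges <- function() {
  search_ranges(
    cascade_depth = range_spec(4L, 8L, "linear", "int"),
    tree_depth = range_spec(2L, 3L, "linear", "int"),
    trees_per_cascade = range_spec(50L, 150L, "linear", "int"),
    learning_rate = range_spec(0.05, 0.3, "log", "real"),
    oversampling = range_spec(3L, 8L, "linear", "int"),
    feature_pool_size = range_spec(100L, 250L, "linear", "int"),
    test_splits = range_spec(20L, 40L, "linear", "int"),
    feature_pool_padding = range_spec(0, 0.2, "linear", "real"),
    regularization = range_spec(0.01, 0.2, "log", "real"))
}

# draw one hyperparameter set uniformly (per scale) from the ranges,
# using the caller's RNG stream
sample_hyperparameters <- function(ranges) {
  vals <- lapply(ranges, function(r) {
    if (r$scale == "log") {
      v <- exp(runif(1, log(r$low), log(r$high)))
    } else {
      v <- runif(1, r$low, r$high)
    }
    if (r$type == "int") as.integer(round(v)) else v
  })
  do.call(hyperparameters, vals)
}

# perturb the best hyperparameters within the ranges (adaptive sampler)
perturb_hyperparameters <- function(hp, ranges, sd_frac = 0.15) {
  vals <- lapply(names(ranges), function(nm) {
    r <- ranges[[nm]]
    cur <- hp[[nm]]
    if (r$scale == "log") {
      lo <- log(r$low); hi <- log(r$high)
      v <- exp(min(max(log(cur) + rnorm(1, 0, sd_frac * (hi - lo)), lo), hi))
    } else {
      v <- min(max(cur + rnorm(1, 0, sd_frac * (r$high - r$low)),
                   r$low), r$high)
    }
    if (r$type == "int") as.integer(round(v)) else v
  })
  names(vals) <- names(ranges)
  do.call(hyperparameters, vals)
}

hp_in_ranges <- function(hp, ranges) {
  all(vapply(names(ranges), function(nm)
    hp[[nm]] >= ranges[[nm]]$low && hp[[nm]] <= ranges[[nm]]$high,
    logical(1)))
}

#' Deterministic k-fold split of a landmark dataset
#'
#' Shuffles the images with the given seed and partitions them into `k`
#' validation folds whose sizes differ by at most one; each fold is paired
#' with the complementary training set.
#'
#' @param dataset a [landmark_dataset()].
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return list of `k` elements, each `list(train =, validation =)`.
#' @export
kfold_split <- function(dataset, k = 5L, seed = 1L) {
  n <- length(dataset$images)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds dataset size (", n, ")")
  perm <- with_seed(as.integer(seed), sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(f) {
    val_idx <- perm[starts[f]:ends[f]]
    list(train = dataset_subset(dataset, setdiff(perm, val_idx)),
         validation = dataset_subset(dataset, val_idx))
  })
}

#' Evaluate one hyperparameter configuration by cross-validation
#'
#' Trains `k` models, one per fold's training part, scores each on its
#' validation part with [mean_deviation()], and records the arithmetic
#' mean of the fold deviations — the quantity the study minimizes. A
#' training failure on any fold marks the trial failed with an infinite
#' score so the surrounding study can continue.
#'
#' @param dataset a [landmark_dataset()].
#' @param hp a [hyperparameters()] object.
#' @param k fold count (default 5).
#' @param seed integer seed (fold split and per-fold training seeds).
#' @param trial_index 0-based index of the trial within its study.
#' @return a `trial_record`: `trial_index`, `hyperparameters`,
#'   `fold_deviations`, `mean_deviation`, `status`.
#' @export
run_trial <- function(dataset, hp, k = 5L, seed = 1L, trial_index = 0L) {
  folds <- kfold_split(dataset, k = k, seed = seed)
  devs <- rep(NA_real_, length(folds))
  status <- "ok"
  for (f in seq_along(folds)) {
    fit <- tryCatch({
      m <- train_predictor(folds[[f]]$train, hp,
                           seed = derive_seed(seed, f))
      mean_deviation(m, folds[[f]]$validation)
    }, error = function(e) {
      warning("trial ", trial_index, " failed on fold ", f, ": ",
              conditionMessage(e))
      Inf
    })
    devs[f] <- fit
    if (!is.finite(fit)) status <- "failed"
  }
  structure(list(trial_index = as.integer(trial_index),
                 hyperparameters = hp,
                 fold_deviations = devs,
                 mean_deviation = mean(devs),
                 status = status),
            class = "trial_record")
}

#' Run a hyperparameter study
#'
#' Samples `n_trials` hyperparameter configurations inside `ranges`,
#' scores each with [run_trial()] (k-fold cross-validated mean pixel
#' deviation), and identifies the best trial — the one with the lowest
#' mean fold deviation, ties broken by the lowest trial index. With
#' `sampler = "random"` and a fixed seed the full trial sequence is
#' reproducible; with `sampler = "adaptive"` later draws concentrate
#' around the best configuration seen so far (a random warm-up of
#' one-third of the trials, then perturbation sampling).
#'
#' @param dataset a [landmark_dataset()].
#' @param n_trials number of trials in the study (the one knob the
#'   pipeline expects users to set).
#' @param ranges a [search_ranges()] object.
#' @param k fold count.
#' @param seed integer seed for all study randomness.
#' @param sampler `"random"` or `"adaptive"`.
#' @return a `study_result`: `trials`, `best_index` (1-based position in
#'   `trials`), `k`, `seed`, `ranges`, `sampler`.
#' @export
run_study <- function(dataset, n_trials, ranges = default_search_ranges(),
                      k = 5L, seed = 1L, sampler = c("random", "adaptive")) {
  sampler <- match.arg(sampler)
  stopifnot(n_trials >= 1L)
  trials <- vector("list", n_trials)
  best_score <- Inf
  best_hp <- NULL
  warmup <- max(1L, ceiling(n_trials / 3))
  for (i in seq_len(n_trials)) {
    hp <- with_seed(derive_seed(seed, 1000L + i), {
      if (sampler == "adaptive" && i > warmup && !is.null(best_hp) &&
          runif(1) < 0.7)
        perturb_hyperparameters(best_hp, ranges)
      else
        sample_hyperparameters(ranges)
    })
    tr <- run_trial(dataset, hp, k = k, seed = derive_seed(seed, 2000L + i),
                    trial_index = i - 1L)
    trials[[i]] <- tr
    if (is.finite(tr$mean_deviation) && tr$mean_deviation < best_score) {
      best_score <- tr$mean_deviation
      best_hp <- hp
    }
  }
  scores <- vapply(trials, `[[`, numeric(1), "mean_deviation")
  if (all(!is.finite(scores))) stop("all trials failed")
  structure(list(trials = trials,
                 best_index = which.min(scores),
                 k = as.integer(k),
                 seed = as.integer(seed),
                 ranges = ranges,
                 sampler = sampler),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  scores <- vapply(x$trials, `[[`, numeric(1), "mean_deviation")
  cat(sprintf(paste0("study_result: %d trial(s), %d-fold CV, sampler ",
                     "'%s'\n  best trial #%d, mean fold deviation %.3f px\n"),
              length(x$trials), x$k, x$sampler,
              x$trials[[x$best_index]]$trial_index, min(scores)))
  invisible(x)
}

#' Best trial of a study
#' @param study a `study_result`.
#' @return the winning `trial_record`.
#' @export
best_trial <- function(study) study$trials[[study$best_index]]

#' Derive the final model from a study
#'
#' Retrains a single predictor on the full dataset using the best trial's
#' hyperparameters (the standard "refit on all data" practice) and attaches
#' the study provenance so the model's sidecar records where its
#' configuration came from.
#'
#' @param dataset the full [landmark_dataset()] the study ran on.
#' @param study a `study_result`.
#' @param seed integer training seed.
#' @return a `predictor_model` with a `provenance` field.
#' @export
finalize_model <- function(dataset, study, seed = 1L) {
  bt <- best_trial(study)
  if (!is.finite(bt$mean_deviation)) stop("study has no successful trial")
  model <- train_predictor(dataset, bt$hyperparameters, seed = seed)
  model$provenance <- list(study_seed = study$seed,
                           sampler = study$sampler,
                           k = study$k,
                           n_trials = length(study$trials),
                           best_trial_index = bt$trial_index,
                           best_cv_deviation_px = bt$mean_deviation)
  model
}

#' Empirical CDF of trial scores as percent of image diagonal
#'
#' Converts each successful trial's mean fold deviation from pixels to a
#' percentage of the image diagonal and returns the empirical cumulative
#' distribution function over trials: the probability, within the study, of
#' reaching a given relative deviation. Failed trials are excluded.
#'
#' @param trials list of `trial_record`s (or a `study_result`).
#' @param diagonal_px normalizing image diagonal in pixels.
#' @return a right-continuous step function (class `ecdf`).
#' @export
deviation_cdf <- function(trials, diagonal_px) {
  if (inherits(trials, "study_result")) trials <- trials$trials
  scores <- vapply(trials, `[[`, numeric(1), "mean_deviation")
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0L) stop("no successful trials")
  ecdf(100 * scores / diagonal_px)
}

#' Serialize a study to JSON
#'
#' Full record of a study — every trial's hyperparameters and fold scores,
#' the ranges, seeds, and sampler — sufficient to reproduce the best
#' configuration without rerunning.
#'
#' @param study a `study_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_study_json <- function(study, path) {
  obj <- list(
    format = "morphmark-study", version = 1L,
    k = study$k, seed = study$seed, sampler = study$sampler,
    best_index = study$best_index,
    ranges = lapply(study$ranges, function(r) r[c("low", "high", "scale",
                                                  "type")]),
    trials = lapply(study$trials, function(t) list(
      trial_index = t$trial_index,
      hyperparameters = unclass(t$hyperparameters),
      fold_deviations = t$fold_deviations,
      mean_deviation = t$mean_deviation,
      status = t$status)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a study serialized by [write_study_json()]
#' @param path JSON path.
#' @return a `study_result` (without refitting anything).
#' @export
read_study_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "morphmark-study"))
    stop("'", path, "' is not a morphmark study file")
  trials <- lapply(obj$trials, function(t) structure(list(
    trial_index = as.integer(t$trial_index),
    hyperparameters = do.call(hyperparameters, t$hyperparameters),
    fold_deviations = vapply(t$fold_deviations, function(v)
      if (is.character(v)) Inf else as.numeric(v), numeric(1)),
    mean_deviation = if (is.character(t$mean_deviation)) Inf else
      as.numeric(t$mean_deviation),
    status = t$status), class = "trial_record"))
  ranges <- do.call(search_ranges, lapply(obj$ranges, function(r)
    range_spec(if (r$type == "int") as.integer(r$low) else as.numeric(r$low),
               if (r$type == "int") as.integer(r$high) else as.numeric(r$high),
               r$scale, r$type)))
  structure(list(trials = trials, best_index = as.integer(obj$best_index),
                 k = as.integer(obj$k), seed = as.integer(obj$seed),
                 ranges = ranges, sampler = obj$sampler),
            class = "study_result")
}
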