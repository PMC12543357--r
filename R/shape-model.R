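#' Shape-predictor training hyperparameters
#'
#' The nine tunable parameters of the cascaded-regression landmark
#' predictor. Defaults are mid-range values that train a 400x300 fixture
#' set in seconds on one CPU core; the search machinery in
#' [run_study()] explores them within declared ranges instead of asking
#' the user to set them.
#'
#' @param cascade_depth number of boosting cascades (refinement stages).
#' @param tree_depth depth of each regression tree.
#' @param trees_per_cascade number of boosted trees per cascade.
#' @param learning_rate shrinkage applied to every leaf ("nu"), in (0, 1].
#' @param oversampling perturbed shape initializations per training image.
#' @param feature_pool_size candidate pixel positions sampled per cascade.
#' @param test_splits candidate splits evaluated at each tree node.
#' @param feature_pool_padding relative margin around the box from which
#'   feature pixels may be drawn.
#' @param regularization spatial proximity prior on feature pairs
#'   ("lambda"); smaller values prefer closer pixel pairs.
#' @return a `morph_hyperparameters` object (named list).
#' @export
hyperparameters <- function(cascade_depth = 10L, tree_depth = 3L,
                            trees_per_cascade = 300L, learning_rate = 0.1,
                            oversampling = 10L, feature_pool_size = 400L,
                            test_splits = 30L, feature_pool_padding = 0.1,
                            regularization = 0.1) {
  hp <- list(cascade_depth = as.integer(cascade_depth),
             tree_depth = as.integer(tree_depth),
             trees_per_cascade = as.integer(trees_per_cascade),
             learning_rate = as.numeric(learning_rate),
             oversampling = as.integer(oversampling),
             feature_pool_size = as.integer(feature_pool_size),
             test_splits = as.integer(test_splits),
             feature_pool_padding = as.numeric(feature_pool_padding),
             regularization = as.numeric(regularization))
  with(hp, {
    stopifnot(cascade_depth >= 1L, tree_depth >= 1L, trees_per_cascade >= 1L,
              learning_rate > 0, learning_rate <= 1, oversampling >= 1L,
              feature_pool_size >= 1L, test_splits >= 1L,
              feature_pool_padding >= 0, regularization > 0)
  })
  structure(hp, class = "morph_hyperparameters")
}

#' @export
print.morph_hyperparameters <- function(x, ...) {
  cat("shape-predictor hyperparameters:\n")
  for (nm in names(x)) cat(sprintf("  %-21s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# load every image of a dataset as a greyscale matrix, plus shapes/boxes
# in the layout the C++ trainer expects
dataset_tensors <- function(dataset) {
  n <- length(dataset$images)
  if (n == 0L) stop("empty dataset")
  L <- dataset$n_landmarks
  if (L == 0L) stop("dataset has zero landmarks per image")
  imgs <- vector("list", n)
  shapes <- matrix(0, n, 2L * L)
  boxes <- matrix(0, n, 4L)
  for (i in seq_len(n)) {
    ann <- dataset$images[[i]]
    p <- resolve_image_path(dataset, ann)
    img <- tryCatch(load_image_gray(p), error = function(e)
      stop("cannot read image '", p, "': ", conditionMessage(e),
           call. = FALSE))
    imgs[[i]] <- img
    shapes[i, seq(1L, 2L * L, by = 2L)] <- ann$landmarks[, "x"]
    shapes[i, seq(2L, 2L * L, by = 2L)] <- ann$landmarks[, "y"]
    b <- ann$box
    if (anyNA(b)) b <- c(0L, 0L, ncol(img), nrow(img))
    boxes[i, ] <- as.numeric(b)
  }
  list(images = imgs, shapes = shapes, boxes = boxes)
}

#' Train a cascaded-regression landmark predictor
#'
#' Fits a gradient-boosted cascade of depth-limited regression trees on
#' pixel-intensity-difference features to the annotated training images.
#' Training is deterministic given `(train, hp, seed)`.
#'
#' @param train a [landmark_dataset()] with readable images.
#' @param hp a [hyperparameters()] object.
#' @param seed integer seed controlling all training randomness.
#' @return a `predictor_model` object.
#' @export
train_predictor <- function(train, hp = hyperparameters(), seed = 1L) {
  stopifnot(inherits(train, "landmark_dataset"))
  if (!inherits(hp, "morph_hyperparameters")) hp <- do.call(hyperparameters, hp)
  tensors <- dataset_tensors(train)
  fit <- .train_cascade_cpp(tensors$images, tensors$shapes, tensors$boxes,
                            unclass(hp), as.integer(seed))
  structure(list(n_landmarks = train$n_landmarks,
                 hyperparameters = hp,
                 training_seed = as.integer(seed),
                 n_train_images = length(train$images),
                 training_hash = dataset_hash(train),
                 fit = fit),
            class = "predictor_model")
}

dataset_hash <- function(dataset) {
  desc <- paste(vapply(dataset$images, function(a)
    paste(a$file, paste(a$landmarks, collapse = ","), sep = ":"), ""),
    collapse = ";")
  # cheap stable fingerprint (sum of char codes with rolling multiplier)
  codes <- utf8ToInt(desc)
  sprintf("%08x", as.integer(sum(codes * (seq_along(codes) %% 97 + 1)) %%
                               2147483647))
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf(paste0("predictor_model: %d landmarks, %d cascades x %d ",
                     "trees (depth %d), trained on %d image(s), seed %d\n"),
              x$n_landmarks, x$hyperparameters$cascade_depth,
              x$hyperparameters$trees_per_cascade,
              x$hyperparameters$tree_depth, x$n_train_images,
              x$training_seed))
  invisible(x)
}

#' Predict landmarks on one image
#'
#' Applies a trained predictor to an image, returning the landmark
#' coordinates in training order. The regression output is clamped to the
#' image frame and rounded to integer pixels.
#'
#' @param model a `predictor_model` from [train_predictor()].
#' @param image image matrix/array, or a path to a PNG file.
#' @return integer `n_landmarks x 2` matrix with columns `x`, `y`.
#' @export
predict_landmarks <- function(model, image) {
  stopifnot(inherits(model, "predictor_model"))
  img <- if (is.character(image)) load_image_gray(image) else to_gray(image)
  if (length(img) == 0L) stop("empty image")
  box <- c(0, 0, ncol(img), nrow(img))
  pts <- .predict_cascade_cpp(model$fit, img, box)
  out <- matrix(as.integer(round(pts)), ncol = 2L,
                dimnames = list(NULL, c("x", "y")))
  out[, 1] <- pmin(pmax(out[, 1], 0L), ncol(img) - 1L)
  out[, 2] <- pmin(pmax(out[, 2], 0L), nrow(img) - 1L)
  out
}

#' Mean pixel deviation of a model on an evaluation set
#'
#' The score the hyperparameter search optimizes: the mean over all images
#' and all landmarks of the Euclidean distance, in pixels, between each
#' predicted landmark and its ground-truth position.
#'
#' @param model a `predictor_model`.
#' @param eval_set a [landmark_dataset()] with the same landmark count.
#' @return mean deviation in pixels.
#' @export
mean_deviation <- function(model, eval_set) {
  stopifnot(inherits(model, "predictor_model"),
            inherits(eval_set, "landmark_dataset"))
  if (length(eval_set$images) == 0L) stop("empty evaluation set")
  if (eval_set$n_landmarks != model$n_landmarks)
    stop("landmark count mismatch between model and evaluation set")
  devs <- unlist(lapply(eval_set$images, function(ann) {
    img <- load_image_gray(resolve_image_path(eval_set, ann))
    pred <- predict_landmarks(model, img)
    sqrt(rowSums((pred - ann$landmarks)^2))
  }))
  mean(devs)
}

#' Save a trained predictor
#'
#' Writes the model to a single binary file plus a human-readable JSON
#' sidecar (`<path>.json`) recording the hyperparameters, seed, landmark
#' count, and a fingerprint of the training annotations.
#'
#' @param model a `predictor_model`.
#' @param path output file path for the binary model.
#' @return `path`, invisibly.
#' @export
save_predictor <- function(model, path) {
  stopifnot(inherits(model, "predictor_model"))
  saveRDS(model, path)
  sidecar <- list(format = "morphmark-predictor",
                  version = 1L,
                  tool_version =
                    as.character(utils::packageVersion("morphmark")),
                  n_landmarks = model$n_landmarks,
                  training_seed = model$training_seed,
                  n_train_images = model$n_train_images,
                  training_hash = model$training_hash,
                  hyperparameters = unclass(model$hyperparameters))
  if (!is.null(model$provenance)) sidecar$provenance <- model$provenance
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a predictor saved by [save_predictor()]
#'
#' @param path path to the binary model file.
#' @return a `predictor_model`.
#' @export
load_predictor <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "predictor_model"))
    stop("'", path, "' is not a morphmark predictor model")
  model
}
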