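#' Diagonal-normalized deviation
#'
#' Expresses a pixel deviation as a percentage of the image diagonal
#' `sqrt(width^2 + height^2)` — the largest error possible in the frame —
#' so that prediction errors are comparable across image geometries and
#' species. A 6-pixel deviation on a 1200x900 image is 0.40% of the
#' diagonal.
#'
#' @param d_px Euclidean deviation in pixels (vectorized, must be >= 0).
#' @param width,height image geometry in pixels.
#' @return deviation as percent of the image diagonal.
#' @export
normalized_deviation <- function(d_px, width, height) {
  stopifnot(width > 0, height > 0)
  if (any(d_px < 0)) stop("negative pixel deviation")
  100 * d_px / sqrt(width^2 + height^2)
}

#' Convert a percent-of-diagonal deviation back to pixels
#'
#' Inverse of [normalized_deviation()] up to rounding: the pixel value is
#' rounded to the nearest integer, halves away from zero — the convention
#' that reproduces the printed (percent, pixel) pairs of diagonal-normalized
#' accuracy reports.
#'
#' @param pct deviation in percent of the diagonal (vectorized, >= 0).
#' @param width,height image geometry in pixels.
#' @return integer pixel deviation.
#' @export
percent_to_pixels <- function(pct, width, height) {
  stopifnot(width > 0, height > 0)
  if (any(pct < 0)) stop("negative percentage")
  x <- pct / 100 * sqrt(width^2 + height^2)
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Compare two landmark datasets point by point
#'
#' Computes per-landmark and overall mean Euclidean deviations between
#' corresponding points of two datasets covering the same images — either
#' predictions against ground truth, or two annotation rounds by the same
#' observer (intra-observer error, the human baseline for model accuracy).
#' The comparison is symmetric in its two arguments.
#'
#' @param a,b [landmark_dataset()]s covering the same image files with
#'   equal landmark counts.
#' @param width,height evaluation geometry for diagonal normalization;
#'   defaults to the per-image dimensions stored in `a`. Pass explicitly
#'   when datasets were pre-resized to a stated geometry.
#' @return a `deviation_report` with fields `per_landmark_mean_px`,
#'   `per_landmark_mean_pct`, `overall_mean_px`, `overall_mean_pct`,
#'   `n_images`.
#' @export
compare_landmark_sets <- function(a, b, width = NULL, height = NULL) {
  stopifnot(inherits(a, "landmark_dataset"), inherits(b, "landmark_dataset"))
  fa <- dataset_files(a)
  fb <- dataset_files(b)
  if (!setequal(fa, fb)) {
    diff <- c(setdiff(fa, fb), setdiff(fb, fa))
    stop("datasets cover different images; symmetric difference: ",
         paste(diff, collapse = ", "))
  }
  if (a$n_landmarks != b$n_landmarks)
    stop("landmark count mismatch: ", a$n_landmarks, " vs ", b$n_landmarks)
  L <- a$n_landmarks
  bmap <- setNames(b$images, fb)
  dev_px <- matrix(NA_real_, length(a$images), L)
  dev_pct <- matrix(NA_real_, length(a$images), L)
  for (i in seq_along(a$images)) {
    ann_a <- a$images[[i]]
    ann_b <- bmap[[ann_a$file]]
    d <- sqrt(rowSums((ann_a$landmarks - ann_b$landmarks)^2))
    dev_px[i, ] <- d
    w <- width %||% ann_a$width
    h <- height %||% ann_a$height
    if (is.null(w) || is.na(w) || is.null(h) || is.na(h))
      stop("image geometry unknown for '", ann_a$file,
           "'; pass width/height explicitly")
    dev_pct[i, ] <- normalized_deviation(d, w, h)
  }
  structure(list(per_landmark_mean_px = colMeans(dev_px),
                 per_landmark_mean_pct = colMeans(dev_pct),
                 overall_mean_px = mean(dev_px),
                 overall_mean_pct = mean(dev_pct),
                 n_images = length(a$images)),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("deviation_report over %d image(s):\n", x$n_images))
  for (k in seq_along(x$per_landmark_mean_px))
    cat(sprintf("  LM%d: %.2f px (%.3f%% of diagonal)\n", k,
                x$per_landmark_mean_px[k], x$per_landmark_mean_pct[k]))
  cat(sprintf("  overall: %.2f px (%.3f%% of diagonal)\n",
              x$overall_mean_px, x$overall_mean_pct))
  invisible(x)
}

#' Per-landmark accuracy gap between model and observer
#'
#' Elementwise difference, in percent of the image diagonal, between a
#' model's deviation report and a human observer's: positive values mean
#' the model is that much worse than the manual baseline.
#'
#' @param model_report,observer_report `deviation_report`s over the same
#'   landmark schema.
#' @return numeric vector of per-landmark percent differences.
#' @export
error_gap <- function(model_report, observer_report) {
  m <- model_report$per_landmark_mean_pct
  o <- observer_report$per_landmark_mean_pct
  if (length(m) != length(o))
    stop("landmark schema mismatch between the two reports")
  m - o
}

#' Write a deviation report to JSON and CSV
#'
#' @param report a `deviation_report`.
#' @param path output path; `.json` and `.csv` files are written with this
#'   stem.
#' @return the JSON path, invisibly.
#' @export
write_deviation_report <- function(report, path) {
  stem <- sub("\\.(json|csv)$", "", path)
  jsonlite::write_json(unclass(report), paste0(stem, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  df <- data.frame(landmark = seq_along(report$per_landmark_mean_px) - 1L,
                   mean_px = report$per_landmark_mean_px,
                   mean_pct = report$per_landmark_mean_pct)
  write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  invisible(paste0(stem, ".json"))
}
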