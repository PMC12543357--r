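#' Hough line-detection parameters
#'
#' The three classic knobs of the probabilistic (segment-returning) Hough
#' transform: accumulator vote threshold, minimum accepted segment length,
#' and the largest gap of missing edge pixels a segment may bridge.
#'
#' @param threshold minimum accumulator votes (>= 1).
#' @param min_line_length minimum segment length in pixels (>= 1).
#' @param max_line_gap maximum bridgeable gap in pixels (>= 0).
#' @return a `hough_params` object.
#' @export
hough_params <- function(threshold = 50L, min_line_length = 100,
                         max_line_gap = 10) {
  stopifnot(threshold >= 1, min_line_length >= 1, max_line_gap >= 0)
  structure(list(threshold = as.integer(threshold),
                 min_line_length = as.numeric(min_line_length),
                 max_line_gap = as.numeric(max_line_gap)),
            class = "hough_params")
}

#' Line-enhancement pre-processing configuration
#'
#' @param blur_sigma Gaussian smoothing standard deviation in pixels
#'   (1.1 approximates a 5x5 kernel).
#' @param canny_low,canny_high hysteresis thresholds on the Sobel gradient
#'   magnitude.
#' @return a `line_config` object.
#' @export
line_config <- function(blur_sigma = 1.1, canny_low = 40, canny_high = 100) {
  stopifnot(blur_sigma >= 0, canny_low >= 0, canny_high >= canny_low)
  structure(list(blur_sigma = blur_sigma, canny_low = canny_low,
                 canny_high = canny_high), class = "line_config")
}

#' Pre-process an image to enhance line features
#'
#' Greyscale conversion (luminance weights), Gaussian smoothing, then
#' gradient-based edge detection with hysteresis thresholding. The result
#' is a binary edge map (values 0 and 255 only), deterministic for a given
#' input and configuration.
#'
#' @param img image matrix/array or PNG path.
#' @param config a [line_config()].
#' @return binary edge matrix (0 background, 255 edge).
#' @export
preprocess_for_lines <- function(img, config = line_config()) {
  g <- if (is.character(img)) load_image_gray(img) else to_gray(img)
  if (length(g) == 0L) stop("empty image")
  sm <- .gaussian_blur_cpp(g, config$blur_sigma)
  .canny_cpp(sm, config$canny_low, config$canny_high)
}

#' Detect line segments in a binary edge map
#'
#' Progressive probabilistic Hough transform. Collinear edge fragments
#' separated by at most `max_line_gap` pixels merge into one segment;
#' segments shorter than `min_line_length` are discarded. An empty result
#' is valid (e.g. a blank edge map).
#'
#' @param edges binary edge matrix from [preprocess_for_lines()].
#' @param params a [hough_params()].
#' @param seed seed for the point-sampling order (detection is
#'   deterministic given the seed).
#' @return a data frame of class `line_segments` with columns
#'   `x1, y1, x2, y2, length_px, angle_deg` (angle in `[-90, 90)`).
#' @export
detect_lines <- function(edges, params = hough_params(), seed = 1L) {
  stopifnot(is.matrix(edges))
  segs <- .hough_segments_cpp(edges, params$threshold,
                              params$min_line_length, params$max_line_gap,
                              as.integer(seed))
  df <- data.frame(x1 = segs[, 1], y1 = segs[, 2],
                   x2 = segs[, 3], y2 = segs[, 4])
  df$length_px <- sqrt((df$x2 - df$x1)^2 + (df$y2 - df$y1)^2)
  ang <- atan2(df$y2 - df$y1, df$x2 - df$x1) * 180 / pi
  ang[ang >= 90] <- ang[ang >= 90] - 180
  ang[ang < -90] <- ang[ang < -90] + 180
  df$angle_deg <- ang
  class(df) <- c("line_segments", "data.frame")
  df
}

#' Select the scale-bar segment among detected lines
#'
#' Policy: keep segments whose tilt from horizontal is at most `max_tilt`
#' degrees and (optionally) whose endpoints lie inside a rectangular region
#' of interest, then return the longest survivor. Both criteria are
#' configuration, not code edits, so the selector adapts to different
#' bar placements.
#'
#' @param lines a `line_segments` data frame from [detect_lines()].
#' @param max_tilt maximum absolute tilt from horizontal, degrees.
#' @param roi optional region `c(x, y, w, h)`; only segments fully inside
#'   are considered.
#' @return the selected segment (one-row data frame).
#' @export
select_scale_bar <- function(lines, max_tilt = 5, roi = NULL) {
  keep <- abs(lines$angle_deg) <= max_tilt
  if (!is.null(roi)) {
    inside <- function(x, y) x >= roi[1] & x <= roi[1] + roi[3] &
      y >= roi[2] & y <= roi[2] + roi[4]
    keep <- keep & inside(lines$x1, lines$y1) & inside(lines$x2, lines$y2)
  }
  cand <- lines[keep, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("no scale-bar candidate: no detected segment satisfies the ",
         "tilt/region criteria")
  cand[which.max(cand$length_px), , drop = FALSE]
}

#' Build a per-image scale calibration
#'
#' @param bar_px detected scale-bar length in pixels (> 0).
#' @param bar_mm known physical length of the bar in millimetres (> 0).
#' @param image path of the calibrated image (bookkeeping only).
#' @return a `scale_calibration` with `mm_per_px = bar_mm / bar_px`.
#' @export
calibrate <- function(bar_px, bar_mm, image = NA_character_) {
  if (!is.finite(bar_px) || bar_px <= 0) stop("bar_px must be positive")
  if (!is.finite(bar_mm) || bar_mm <= 0) stop("bar_mm must be positive")
  structure(list(mm_per_px = bar_mm / bar_px, bar_length_px = bar_px,
                 bar_length_mm = bar_mm, image = image),
            class = "scale_calibration")
}

#' Convert a pixel distance to millimetres
#'
#' @param d_px distance in pixels (vectorized).
#' @param cal a [calibrate()]d `scale_calibration`.
#' @return distance in millimetres.
#' @export
to_mm <- function(d_px, cal) {
  stopifnot(inherits(cal, "scale_calibration"))
  d_px * cal$mm_per_px
}

#' Batch scale-bar detection over a set of images
#'
#' Runs the full detect-and-calibrate chain per image: pre-processing,
#' probabilistic Hough, bar selection, calibration against the known bar
#' length. Each image gets its own `mm_per_px` because even small camera
#' or subject movements change the scale from frame to frame. Per-image
#' failures are recorded in the `status` column; the batch always
#' completes.
#'
#' @param images character vector of image paths, or a directory
#'   containing PNGs.
#' @param bar_mm known physical bar length in millimetres.
#' @param params a [hough_params()].
#' @param config a [line_config()].
#' @param max_tilt,roi bar-selection criteria (see [select_scale_bar()]).
#' @return data frame with columns `image, bar_px, mm_per_px, status` and
#'   an attached list of `scale_calibration`s (`attr(, "calibrations")`,
#'   named by image path).
#' @export
detect_scale_bars <- function(images, bar_mm, params = hough_params(),
                              config = line_config(), max_tilt = 5,
                              roi = NULL) {
  if (length(images) == 1L && dir.exists(images))
    images <- list.files(images, pattern = "\\.png$", full.names = TRUE)
  rows <- vector("list", length(images))
  cals <- list()
  for (i in seq_along(images)) {
    p <- images[i]
    res <- tryCatch({
      edges <- preprocess_for_lines(p, config)
      lines <- detect_lines(edges, params)
      bar <- select_scale_bar(lines, max_tilt = max_tilt, roi = roi)
      cal <- calibrate(bar$length_px, bar_mm, image = p)
      cals[[p]] <- cal
      data.frame(image = p, bar_px = bar$length_px,
                 mm_per_px = cal$mm_per_px, status = "ok")
    }, error = function(e)
      data.frame(image = p, bar_px = NA_real_, mm_per_px = NA_real_,
                 status = "scalebar_failed"))
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "calibrations") <- cals
  out
}
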