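#' Export predicted landmarks and inter-landmark lengths as CSV
#'
#' One row per image. The column schema is declared and stable:
#' `image`, then `lm<k>_x`/`lm<k>_y` for each landmark index `k` (0-based),
#' then `<name>_px` for every named landmark pair and, when a calibration
#' exists for the image, `<name>_mm`, and finally `status`
#' (`ok`, `scalebar_failed`). Pixel distances are always emitted; `mm`
#' columns are `NA` on rows whose image lacks a calibration.
#'
#' @param predictions a [landmark_dataset()] of predicted landmarks.
#' @param pairs named landmark pairs as a list of `list(i =, j =, name =)`
#'   (0-based landmark indices), e.g. standard length = snout to hypural
#'   joint. Defaults to none (coordinates only).
#' @param calibrations optional per-image calibrations: the data frame
#'   returned by [detect_scale_bars()] or a named list of
#'   `scale_calibration`s keyed by image path/file name.
#' @param path output CSV path.
#' @return the exported data frame, invisibly.
#' @export
export_csv <- function(predictions, pairs = list(), calibrations = NULL,
                       path) {
  stopifnot(inherits(predictions, "landmark_dataset"))
  L <- predictions$n_landmarks
  for (p in pairs)
    stopifnot(p$i >= 0, p$i < L, p$j >= 0, p$j < L, nzchar(p$name))

  cal_map <- list()
  if (!is.null(calibrations)) {
    if (is.data.frame(calibrations)) {
      cal_map <- attr(calibrations, "calibrations") %||% list()
      if (length(cal_map) == 0L) {
        ok <- calibrations$status == "ok"
        cal_map <- setNames(
          lapply(which(ok), function(i)
            calibrate(calibrations$bar_px[i],
                      calibrations$bar_px[i] * calibrations$mm_per_px[i],
                      calibrations$image[i])),
          calibrations$image[ok])
      }
    } else cal_map <- calibrations
    names(cal_map) <- basename(names(cal_map))
  }

  rows <- lapply(predictions$images, function(ann) {
    row <- list(image = ann$file)
    for (k in seq_len(L)) {
      row[[sprintf("lm%d_x", k - 1L)]] <- ann$landmarks[k, "x"]
      row[[sprintf("lm%d_y", k - 1L)]] <- ann$landmarks[k, "y"]
    }
    cal <- cal_map[[basename(ann$file)]]
    status <- "ok"
    for (p in pairs) {
      d <- sqrt(sum((ann$landmarks[p$i + 1L, ] -
                       ann$landmarks[p$j + 1L, ])^2))
      row[[paste0(p$name, "_px")]] <- d
      if (!is.null(calibrations)) {
        if (is.null(cal)) {
          row[[paste0(p$name, "_mm")]] <- NA_real_
          status <- "scalebar_failed"
        } else {
          row[[paste0(p$name, "_mm")]] <- to_mm(d, cal)
        }
      }
    }
    row$status <- status
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(out)
}

#' Batch-predict landmarks over an image directory
#'
#' Applies a trained model to every PNG in a directory, writing the
#' predictions as landmark XML and, optionally, overlay renderings for
#' visual confirmation. Images are processed independently; a corrupt
#' image is logged and skipped, and the batch completes.
#'
#' @param model a `predictor_model`.
#' @param image_dir directory of PNG images.
#' @param out_xml optional path for the predictions XML.
#' @param overlay_dir optional directory for overlay PNGs.
#' @param radius,colour overlay marker style.
#' @return the predicted [landmark_dataset()].
#' @export
pipeline_predict <- function(model, image_dir, out_xml = NULL,
                             overlay_dir = NULL, radius = 5,
                             colour = c(255, 0, 0)) {
  files <- sort(list.files(image_dir, pattern = "\\.png$"))
  if (length(files) == 0L) stop("no PNG images in '", image_dir, "'")
  if (!is.null(overlay_dir))
    dir.create(overlay_dir, recursive = TRUE, showWarnings = FALSE)
  anns <- list()
  for (f in files) {
    p <- file.path(image_dir, f)
    ann <- tryCatch({
      img <- read_image(p)
      lm <- predict_landmarks(model, img)
      if (!is.null(overlay_dir)) {
        ov <- render_overlay(img, lm, radius = radius, colour = colour)
        write_image(ov, file.path(overlay_dir,
                                  sub("\\.png$", "_overlay.png", f)))
      }
      g <- to_gray(img)
      image_annotation(file = f, width = ncol(g), height = nrow(g),
                       landmarks = lm)
    }, error = function(e) {
      warning("skipping '", f, "': ", conditionMessage(e))
      NULL
    })
    if (!is.null(ann)) anns[[length(anns) + 1L]] <- ann
  }
  if (length(anns) == 0L) stop("no image in '", image_dir,
                               "' could be processed")
  ds <- landmark_dataset(anns, base_dir = image_dir)
  if (!is.null(out_xml)) write_landmark_xml(ds, out_xml)
  ds
}

#' Standard-length landmark pair
#'
#' Convenience for the most common measurement: snout tip (LM0) to
#' hypural joint (LM1), the fish's standard length.
#' @export
standard_length_pair <- function()
  list(list(i = 0L, j = 1L, name = "standard_length"))
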