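#' Construct a per-image landmark annotation
#'
#' @param file image path (stored as given, usually relative to the XML).
#' @param width,height image size in pixels, or `NA` when unknown.
#' @param landmarks integer-valued `n x 2` matrix of `(x, y)` pixel
#'   coordinates, origin at the image's upper-left corner, ordered by
#'   landmark index (row `k` is landmark `k - 1`).
#' @param box bounding rectangle `c(left, top, width, height)`; defaults to
#'   the full image frame (the pipeline has no object-detection stage).
#' @return an `image_annotation` object.
#' @export
image_annotation <- function(file, width = NA_integer_, height = NA_integer_,
                             landmarks, box = NULL) {
  landmarks <- as.matrix(landmarks)
  if (ncol(landmarks) != 2L) stop("landmarks must be an n x 2 matrix")
  storage.mode(landmarks) <- "integer"
  colnames(landmarks) <- c("x", "y")
  if (is.null(box)) {
    box <- c(left = 0L, top = 0L,
             width = if (is.na(width)) NA_integer_ else as.integer(width),
             height = if (is.na(height)) NA_integer_ else as.integer(height))
  } else {
    box <- as.integer(box)
    names(box) <- c("left", "top", "width", "height")
  }
  ann <- structure(list(file = file, width = as.integer(width),
                        height = as.integer(height), box = box,
                        landmarks = landmarks),
                   class = "image_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  lm <- ann$landmarks
  if (nrow(lm) > 0L) {
    if (any(lm < 0L)) stop("negative landmark coordinate in ", ann$file)
    if (!is.na(ann$width) && any(lm[, "x"] >= ann$width))
      stop("landmark x beyond image width in ", ann$file)
    if (!is.na(ann$height) && any(lm[, "y"] >= ann$height))
      stop("landmark y beyond image height in ", ann$file)
  }
  if (!is.na(ann$width) && !is.na(ann$box["width"])) {
    if (ann$box["left"] < 0L || ann$box["top"] < 0L ||
        ann$box["left"] + ann$box["width"] > ann$width ||
        ann$box["top"] + ann$box["height"] > ann$height)
      stop("box extends beyond the image frame in ", ann$file)
  }
  invisible(ann)
}

#' Construct a landmark dataset
#'
#' A homogeneous collection of annotated images: every image carries the
#' same number of landmarks, and landmark `k` corresponds anatomically to
#' landmark `k` in every other image (positional identity).
#'
#' @param images list of [image_annotation()] objects.
#' @param base_dir directory that relative image paths are resolved
#'   against (usually the directory of the XML file).
#' @return a `landmark_dataset` object.
#' @export
landmark_dataset <- function(images, base_dir = ".") {
  counts <- vapply(images, function(a) nrow(a$landmarks), integer(1))
  if (length(images) > 0L && length(unique(counts)) > 1L) {
    bad <- vapply(images, `[[`, "", "file")[counts != counts[1L]]
    stop("heterogeneous landmark counts; offending images: ",
         paste(bad, collapse = ", "))
  }
  files <- vapply(images, `[[`, "", "file")
  if (anyDuplicated(files))
    stop("duplicate image file paths: ",
         paste(unique(files[duplicated(files)]), collapse = ", "))
  structure(list(images = images,
                 n_landmarks = if (length(images)) counts[1L] else 0L),
            base_dir = base_dir, class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf("landmark_dataset: %d image(s), %d landmark(s) per image\n",
              length(x$images), x$n_landmarks))
  invisible(x)
}

#' @export
length.landmark_dataset <- function(x) length(x$images)

# subset a dataset by image index, keeping the base directory
dataset_subset <- function(dataset, idx) {
  landmark_dataset(dataset$images[idx],
                   base_dir = attr(dataset, "base_dir") %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dataset_files <- function(dataset)
  vapply(dataset$images, `[[`, "", "file")

# absolute path of an image within a dataset
resolve_image_path <- function(dataset, ann) {
  f <- ann$file
  base <- attr(dataset, "base_dir") %||% "."
  if (grepl("^(/|[A-Za-z]:)", f)) f else file.path(base, f)
}

part_name <- function(k, n_total) {
  width <- max(2L, nchar(as.character(max(n_total - 1L, 0L))))
  formatC(k, width = width, flag = "0")
}

#' Read a landmark XML file
#'
#' Parses the image/box/part XML dialect used by shape-predictor tooling:
#' `dataset > images > image[file] > box[top,left,width,height] >
#' part[name,x,y]`. Parts are ordered by their zero-padded names, which
#' encode the landmark index. Coordinates are integer pixels with the
#' origin at the upper-left corner of the image. `width`/`height`
#' attributes on `image` are optional and tolerated when absent.
#'
#' @param path path to the XML file.
#' @return a [landmark_dataset()] whose `base_dir` is the XML's directory.
#' @export
read_landmark_xml <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed XML in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  img_nodes <- xml2::xml_find_all(doc, ".//images/image")
  images <- lapply(img_nodes, function(node) {
    file <- xml2::xml_attr(node, "file")
    if (is.na(file)) stop("malformed XML: <image> element without 'file' ",
                          "attribute in '", path, "'")
    width <- suppressWarnings(as.integer(xml2::xml_attr(node, "width")))
    height <- suppressWarnings(as.integer(xml2::xml_attr(node, "height")))
    box_node <- xml2::xml_find_first(node, "./box")
    parts <- xml2::xml_find_all(node, "./box/part")
    nms <- xml2::xml_attr(parts, "name")
    ord <- order(nms)
    xs <- as.integer(xml2::xml_attr(parts, "x"))[ord]
    ys <- as.integer(xml2::xml_attr(parts, "y"))[ord]
    if (anyNA(xs) || anyNA(ys))
      stop("malformed XML: non-integer part coordinates for image '",
           file, "' in '", path, "'")
    box <- NULL
    if (!inherits(box_node, "xml_missing")) {
      b <- suppressWarnings(as.integer(vapply(
        c("left", "top", "width", "height"),
        function(a) xml2::xml_attr(box_node, a), "")))
      if (!anyNA(b)) box <- b
    }
    image_annotation(file = file, width = width, height = height,
                     landmarks = cbind(xs, ys), box = box)
  })
  landmark_dataset(images, base_dir = dirname(path))
}

#' Write a landmark XML file
#'
#' Inverse of [read_landmark_xml()]: emits one XML document in the
#' image/box/part dialect. Part names are zero-padded to at least width 2
#' so lexicographic order equals landmark order. Re-reading the file yields
#' an equal dataset.
#'
#' @param dataset a [landmark_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landmark_xml <- function(dataset, path) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  doc <- xml2::xml_new_root("dataset")
  xml2::xml_add_child(doc, "name", "morphmark landmark dataset")
  images <- xml2::xml_add_child(doc, "images")
  n <- dataset$n_landmarks
  for (ann in dataset$images) {
    validate_annotation(ann)
    img <- xml2::xml_add_child(images, "image", file = ann$file)
    if (!is.na(ann$width)) xml2::xml_set_attr(img, "width", ann$width)
    if (!is.na(ann$height)) xml2::xml_set_attr(img, "height", ann$height)
    b <- ann$box
    box <- xml2::xml_add_child(img, "box",
                               top = as.character(b[["top"]]),
                               left = as.character(b[["left"]]),
                               width = as.character(b[["width"]]),
                               height = as.character(b[["height"]]))
    if (nrow(ann$landmarks) > 0L)
      for (k in seq_len(nrow(ann$landmarks)))
        xml2::xml_add_child(box, "part",
                            name = part_name(k - 1L, n),
                            x = as.character(ann$landmarks[k, "x"]),
                            y = as.character(ann$landmarks[k, "y"]))
  }
  ok <- tryCatch({ xml2::write_xml(doc, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write annotation XML to '", path, "'")
  invisible(path)
}

#' Draw landmark markers on an image
#'
#' Returns a copy of the image with a filled disc of the given radius
#' centred on each landmark; the input is never modified. Intended for
#' visual confirmation of manual or predicted landmark placements.
#' Landmarks outside the frame are clamped to the border and flagged with a
#' warning rather than failing, so batch rendering always completes.
#'
#' @param img greyscale matrix or RGB array.
#' @param landmarks `n x 2` matrix of `(x, y)` pixel coordinates.
#' @param radius marker radius in pixels.
#' @param colour marker colour as `c(r, g, b)` on 0--255.
#' @return an RGB array with the markers drawn.
#' @export
render_overlay <- function(img, landmarks, radius = 5,
                           colour = c(255, 0, 0)) {
  out <- gray_to_rgb(img)
  h <- dim(out)[1]
  w <- dim(out)[2]
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) == 0L) return(out)
  xs <- landmarks[, 1]
  ys <- landmarks[, 2]
  if (any(xs < 0 | xs >= w | ys < 0 | ys >= h)) {
    warning("landmark outside the image frame; clamped for drawing")
    xs <- pmin(pmax(xs, 0), w - 1)
    ys <- pmin(pmax(ys, 0), h - 1)
  }
  r <- ceiling(radius)
  for (k in seq_along(xs)) {
    cx <- xs[k]
    cy <- ys[k]
    xr <- max(0, floor(cx - r)):min(w - 1, ceiling(cx + r))
    yr <- max(0, floor(cy - r)):min(h - 1, ceiling(cy + r))
    dist2 <- outer((yr - cy)^2, (xr - cx)^2, `+`)
    hit <- which(dist2 <= radius^2, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    rows <- yr[hit[, 1]] + 1L
    cols <- xr[hit[, 2]] + 1L
    for (ch in 1:3) out[cbind(rows, cols, ch)] <- colour[ch]
  }
  out
}
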