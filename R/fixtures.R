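#' Synthetic fish-fixture parameters
#'
#' Describes the stated world the generator draws from: standardized
#' orientation (no rotation or flipping, as recommended for training
#' input), a homogeneous light background, a dark ellipsoid body with a
#' lighter caudal fin, and controllable exposure, blur, body-size and
#' fin-shape variation. Ground truth is exact by construction: landmarks
#' are placed analytically on the drawn geometry before rendering.
#'
#' Landmark schema (positional identity):
#' \itemize{
#'   \item LM0 — tip of the snout (anterior body vertex; high contrast
#'     against the background).
#'   \item LM1 — hypural joint, where the caudal fin begins (body--fin
#'     boundary; lower contrast, the harder landmark). LM0--LM1 is the
#'     fish's standard length.
#'   \item LM2 — fork of the tail fin (4-landmark schema only).
#'   \item LM3 — base of the dorsal fin (4-landmark schema only).
#' }
#'
#' @param width,height frame size in pixels. The 400x300 default is
#'   proportional to a 1800x1200 evaluation geometry at desk-scale
#'   runtime.
#' @param body_length_px range (min, max) of the standard length in
#'   pixels.
#' @param translation_jitter body-centre jitter as a fraction of the
#'   frame (uniform in +/- this value on each axis).
#' @param brightness_jitter uniform whole-image exposure jitter as a
#'   fraction of the 255 intensity scale.
#' @param brightness_offset fixed exposure offset in intensity units
#'   (positive = overexposed, negative = underexposed).
#' @param blur_sigma range (min, max) of Gaussian blur sigma in pixels.
#' @param caudal_irregularity probability that an image's caudal fin is
#'   irregular/unspread (narrower, fork shifted towards the tip).
#' @param noise_sd standard deviation of per-pixel Gaussian sensor noise
#'   (intensity units), applied after blurring. Photographic captures are
#'   never noise-free; without this axis, degradations such as low
#'   contrast would cost an exact-arithmetic predictor nothing.
#' @param background_level background grey value (0--255).
#' @param body_level,fin_level grey values of body and fin.
#' @param with_scale_bar draw a dark horizontal scale bar near the bottom
#'   of the frame.
#' @param bar_px,bar_mm rendered bar length in pixels and the physical
#'   length it represents.
#' @param n_landmarks 2 (snout + hypural joint) or 4 (adds tail fork and
#'   dorsal-fin base).
#' @param rotation_deg range of body rotation in degrees; 0 by default,
#'   honouring the standardization requirement. Only meant for the
#'   documented sensitivity analysis.
#' @param seed integer seed; image `index` under the same seed is always
#'   identical.
#' @return a `fixture_params` object.
#' @export
fixture_params <- function(width = 400L, height = 300L,
                           body_length_px = c(150, 200),
                           translation_jitter = 0.05,
                           brightness_jitter = 0.05,
                           brightness_offset = 0,
                           blur_sigma = c(0.4, 0.8),
                           noise_sd = 2,
                           caudal_irregularity = 0,
                           background_level = 230,
                           body_level = 80, fin_level = 150,
                           with_scale_bar = FALSE,
                           bar_px = 120, bar_mm = 12,
                           n_landmarks = 2L,
                           rotation_deg = c(0, 0),
                           seed = 1L) {
  stopifnot(n_landmarks %in% c(2L, 4L), length(body_length_px) == 2L,
            body_length_px[1] <= body_length_px[2],
            translation_jitter >= 0, caudal_irregularity >= 0,
            caudal_irregularity <= 1)
  p <- list(width = as.integer(width), height = as.integer(height),
            body_length_px = as.numeric(body_length_px),
            translation_jitter = translation_jitter,
            brightness_jitter = brightness_jitter,
            brightness_offset = brightness_offset,
            blur_sigma = as.numeric(blur_sigma),
            noise_sd = noise_sd,
            caudal_irregularity = caudal_irregularity,
            background_level = background_level,
            body_level = body_level, fin_level = fin_level,
            with_scale_bar = isTRUE(with_scale_bar),
            bar_px = bar_px, bar_mm = bar_mm,
            n_landmarks = as.integer(n_landmarks),
            rotation_deg = as.numeric(rotation_deg),
            seed = as.integer(seed))
  # sanity: largest possible fish must fit the frame at maximal jitter
  max_extent <- p$body_length_px[2] * 1.45
  if (max_extent > p$width * (0.9 - 2 * p$translation_jitter))
    stop("body larger than frame for the configured jitter")
  structure(p, class = "fixture_params")
}

#' Degradation profiles mirroring common dataset flaws
#'
#' `clean` is the stated baseline; `overexposed`, `underexposed`,
#' `blurred` and `irregular` each push one degradation axis.
#'
#' @param profile profile name.
#' @param ... overrides passed on to [fixture_params()].
#' @return a `fixture_params` object.
#' @export
fixture_profile <- function(profile = c("clean", "overexposed",
                                        "underexposed", "blurred",
                                        "irregular"), ...) {
  profile <- match.arg(profile)
  args <- switch(profile,
    clean = list(),
    overexposed = list(brightness_offset = 55),
    underexposed = list(brightness_offset = -90),
    blurred = list(blur_sigma = c(1.6, 2.6)),
    irregular = list(caudal_irregularity = 1))
  do.call(fixture_params, utils::modifyList(args, list(...)))
}

# analytic fish geometry for one image; all randomness from the local RNG
fish_geometry <- function(params) {
  p <- params
  sl <- runif(1, p$body_length_px[1], p$body_length_px[2])
  a <- sl / 2                       # semi-major axis; SL = 2a
  b <- 0.28 * sl                    # semi-minor axis
  cx <- p$width * 0.45 + runif(1, -1, 1) * p$translation_jitter * p$width
  cy <- p$height * 0.45 + runif(1, -1, 1) * p$translation_jitter * p$height
  irregular <- runif(1) < p$caudal_irregularity
  fin_len <- 0.40 * sl
  spread <- if (irregular) 0.10 * sl else 0.26 * sl
  fork_frac <- if (irregular) 0.85 else 0.60
  theta <- if (diff(p$rotation_deg) == 0) p$rotation_deg[1] else
    runif(1, p$rotation_deg[1], p$rotation_deg[2])
  list(cx = cx, cy = cy, a = a, b = b, fin_len = fin_len, spread = spread,
       fork_frac = fork_frac, theta = theta * pi / 180,
       blur = runif(1, p$blur_sigma[1], p$blur_sigma[2]),
       bright = p$brightness_offset +
         runif(1, -1, 1) * p$brightness_jitter * 255)
}

# rotate offsets (dx, dy) about the body centre
rot_xy <- function(dx, dy, th)
  list(x = dx * cos(th) - dy * sin(th), y = dx * sin(th) + dy * cos(th))

#' Generate one synthetic fish image with exact landmark ground truth
#'
#' Draws an ellipse body plus a forked triangular caudal fin on a
#' homogeneous background, optionally with a scale bar, applies the
#' configured exposure and blur, and returns the rendered image together
#' with the analytically placed landmarks. Deterministic given
#' `(params$seed, index)`.
#'
#' @param params a [fixture_params()].
#' @param index image index within the dataset (>= 1).
#' @return `list(image = matrix, landmarks = n x 2 integer matrix)`.
#' @export
generate_fish_image <- function(params, index = 1L) {
  stopifnot(inherits(params, "fixture_params"), index >= 1L)
  with_seed(derive_seed(params$seed, index), {
    g <- fish_geometry(params)
    w <- params$width
    h <- params$height
    px <- matrix(rep(0:(w - 1), each = h), h, w)   # x coordinate per pixel
    py <- matrix(rep(0:(h - 1), times = w), h, w)  # y coordinate per pixel
    th <- g$theta
    # body-frame coordinates (rotation about the centre)
    bx <- (px - g$cx) * cos(th) + (py - g$cy) * sin(th)
    by <- -(px - g$cx) * sin(th) + (py - g$cy) * cos(th)

    img <- matrix(params$background_level, h, w)
    # caudal fin: quadrilateral J -> upper tip -> fork -> lower tip,
    # rendered as two triangles so the fork notch is concave
    jx <- g$a
    tipx <- g$a + g$fin_len
    fx <- g$a + g$fork_frac * g$fin_len
    tri <- function(x1, y1, x2, y2, x3, y3) {
      d <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
      l1 <- ((y2 - y3) * (bx - x3) + (x3 - x2) * (by - y3)) / d
      l2 <- ((y3 - y1) * (bx - x3) + (x1 - x3) * (by - y3)) / d
      l3 <- 1 - l1 - l2
      l1 >= 0 & l2 >= 0 & l3 >= 0
    }
    fin <- tri(jx, 0, tipx, -g$spread, fx, 0) |
      tri(jx, 0, fx, 0, tipx, g$spread)
    img[fin] <- params$fin_level
    body <- (bx / g$a)^2 + (by / g$b)^2 <= 1
    img[body] <- params$body_level

    if (params$with_scale_bar) {
      bar_y <- h - 22
      bar_x0 <- (w - params$bar_px) / 2
      bar <- px >= bar_x0 & px < bar_x0 + params$bar_px &
        py >= bar_y & py < bar_y + 6
      img[bar] <- 20
    }

    lm_body <- list(c(-g$a, 0), c(g$a, 0), c(fx, 0), c(0, -g$b))
    lms <- t(vapply(lm_body[seq_len(params$n_landmarks)], function(o) {
      r <- rot_xy(o[1], o[2], th)
      c(g$cx + r$x, g$cy + r$y)
    }, numeric(2)))
    lms <- cbind(pmin(pmax(round(lms[, 1]), 0), w - 1),
                 pmin(pmax(round(lms[, 2]), 0), h - 1))
    storage.mode(lms) <- "integer"
    colnames(lms) <- c("x", "y")

    if (g$blur > 0) img <- .gaussian_blur_cpp(img, g$blur)
    if (params$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, params$noise_sd),
                          nrow(img), ncol(img))
    img <- round(pmin(pmax(img + g$bright, 0), 255))
    list(image = img, landmarks = lms)
  })
}

#' Generate a fixture dataset on disk
#'
#' Writes `n` PNG images and one ground-truth annotation XML consumable by
#' [read_landmark_xml()]. File paths inside the XML are relative to the
#' output directory.
#'
#' @param n number of images (>= 1).
#' @param params a [fixture_params()].
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the generated [landmark_dataset()], invisibly; its XML lives at
#'   `file.path(dir, "landmarks.xml")`.
#' @export
generate_dataset <- function(n, params = fixture_params(), dir,
                             overwrite = FALSE) {
  stopifnot(n >= 1L)
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite)
    stop("output directory '", dir, "' is not empty; set overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  anns <- vector("list", n)
  for (i in seq_len(n)) {
    fx <- generate_fish_image(params, i)
    fname <- sprintf("fish_%04d.png", i)
    write_image(fx$image, file.path(dir, fname))
    anns[[i]] <- image_annotation(file = fname, width = params$width,
                                  height = params$height,
                                  landmarks = fx$landmarks)
  }
  ds <- landmark_dataset(anns, base_dir = dir)
  write_landmark_xml(ds, file.path(dir, "landmarks.xml"))
  invisible(ds)
}

#' In-memory fixture dataset (no files written)
#'
#' Same content as [generate_dataset()] but keeps images in memory;
#' used where tests need a dataset without disk I/O. Returned as
#' `list(dataset =, images = named list of matrices)`.
#'
#' @inheritParams generate_dataset
#' @keywords internal
#' @export
generate_dataset_memory <- function(n, params = fixture_params()) {
  anns <- vector("list", n)
  imgs <- vector("list", n)
  for (i in seq_len(n)) {
    fx <- generate_fish_image(params, i)
    fname <- sprintf("fish_%04d.png", i)
    anns[[i]] <- image_annotation(file = fname, width = params$width,
                                  height = params$height,
                                  landmarks = fx$landmarks)
    imgs[[i]] <- fx$image
  }
  names(imgs) <- vapply(anns, `[[`, "", "file")
  list(dataset = landmark_dataset(anns), images = imgs)
}
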