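# draws a filled dark horizontal bar on a light background
bar_image <- function(w = 400, h = 300, x0 = 50, y0 = 140, len = 300,
                      thick = 6, bg = 230, fg = 20) {
  img <- matrix(bg, h, w)
  img[(y0 + 1):(y0 + thick), (x0 + 1):(x0 + len)] <- fg
  img
}

test_that("pre-processing yields a binary edge map", {
  # uniform image: no gradients, all background
  edges <- preprocess_for_lines(matrix(128, 100, 100))
  expect_true(all(edges == 0))
  # a rendered bar produces its outline; output is exactly two-valued
  edges2 <- preprocess_for_lines(bar_image())
  expect_setequal(unique(as.vector(edges2)), c(0, 255))
  expect_gt(sum(edges2 > 0), 2 * 300) # top and bottom outline edges
  # edge support is confined to the bar's neighbourhood
  on_bar <- edges2[135:152, 45:356]
  expect_equal(sum(edges2 > 0), sum(on_bar > 0))
})

test_that("detect_lines finds a rendered 300 px bar within 2 px", {
  edges <- preprocess_for_lines(bar_image(len = 300))
  lines <- detect_lines(edges, hough_params(threshold = 40,
                                            min_line_length = 100,
                                            max_line_gap = 5))
  expect_gt(nrow(lines), 0)
  best <- lines[which.max(lines$length_px), ]
  expect_lt(abs(best$length_px - 300), 2 + 1e-9)
  expect_lt(abs(best$angle_deg), 1)
  # blank edge map: empty result is valid
  expect_equal(nrow(detect_lines(matrix(0, 50, 50), hough_params())), 0L)
})

test_that("max_line_gap merges or splits collinear fragments", {
  # synthetic single-row edge map: two collinear 100 px fragments with a
  # 5 px gap; oracle endpoints by direct run-merging on the row
  edges <- matrix(0, 60, 260)
  y <- 30
  edges[y + 1, (20:119) + 1] <- 255
  edges[y + 1, (125:224) + 1] <- 255
  p_merge <- hough_params(threshold = 30, min_line_length = 80,
                          max_line_gap = 10)
  merged <- detect_lines(edges, p_merge)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$length_px, 224 - 20, tolerance = 2 / 204)
  expect_equal(sort(c(merged$x1, merged$x2)), c(20, 224), tolerance = 0.1)
  # with a 2 px gap limit the fragments stay separate
  p_split <- hough_params(threshold = 30, min_line_length = 80,
                          max_line_gap = 2)
  split <- detect_lines(edges, p_split)
  expect_equal(nrow(split), 2L)
  expect_true(all(abs(split$length_px - 99) <= 2))
  # oracle: accumulator-free brute force over the known row
  runs <- rle(edges[y + 1, ] > 0)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  frag <- cbind(starts[runs$values] - 1, ends[runs$values] - 1)
  expect_equal(nrow(frag), 2L)
  gap <- frag[2, 1] - frag[1, 2] - 1
  expect_equal(gap, 5)
  expect_lt(gap, 10)  # hence one segment at max_line_gap = 10
  expect_gt(gap, 2)   # and two segments at max_line_gap = 2
  expect_equal(c(frag[1, 1], frag[2, 2]), c(20, 224))
})

test_that("select_scale_bar filters by tilt and region, then takes the longest", {
  lines <- detect_lines(preprocess_for_lines(bar_image()),
                        hough_params(threshold = 40, min_line_length = 50,
                                     max_line_gap = 5))
  seg <- function(x1, y1, x2, y2) {
    data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
               length_px = sqrt((x2 - x1)^2 + (y2 - y1)^2),
               angle_deg = atan2(y2 - y1, x2 - x1) * 180 / pi)
  }
  cand <- rbind(seg(0, 10, 300, 10), seg(50, 0, 50, 400))
  # a 400 px vertical line loses to a 300 px horizontal one at 5 degrees
  expect_equal(select_scale_bar(cand, max_tilt = 5)$length_px, 300)
  # among two near-horizontal segments the longer wins
  cand2 <- rbind(seg(0, 10, 200, 10), seg(0, 50, 300, 50))
  expect_equal(select_scale_bar(cand2, max_tilt = 5)$y1, 50)
  # region-of-interest constraint
  expect_equal(select_scale_bar(cand2, max_tilt = 5,
                                roi = c(0, 0, 320, 30))$y1, 10)
  expect_error(select_scale_bar(cand[0, ], max_tilt = 5), "no scale-bar")
  expect_true(nrow(lines) >= 1) # sanity on the rendered input used above
})

test_that("calibration arithmetic and batch per-image calibration", {
  cal <- calibrate(300, 10)
  expect_equal(cal$mm_per_px, 1 / 30)
  expect_equal(to_mm(150, cal), 5)
  expect_equal(to_mm(0, cal), 0)
  # landmark pair (0,0)-(3,4) at 0.1 mm/px -> 0.5 mm
  expect_equal(to_mm(sqrt(3^2 + 4^2), calibrate(100, 10)), 0.5)
  expect_error(calibrate(0, 10), "positive")
  expect_error(calibrate(-5, 10), "positive")
  expect_error(calibrate(10, 0), "positive")

  # batch: one calibration row per image, failures recorded not fatal
  d <- tempfile()
  dir.create(d)
  p <- fixture_params(seed = 5, with_scale_bar = TRUE, bar_px = 300,
                      bar_mm = 30)
  write_image(generate_fish_image(p, 1)$image, file.path(d, "ok.png"))
  write_image(matrix(128, 300, 400), file.path(d, "blank.png"))
  cal_df <- detect_scale_bars(d, bar_mm = 30,
                              params = hough_params(threshold = 40,
                                                    min_line_length = 100,
                                                    max_line_gap = 5))
  expect_equal(nrow(cal_df), 2L)
  expect_equal(cal_df$status[basename(cal_df$image) == "blank.png"],
               "scalebar_failed")
  ok_row <- cal_df[basename(cal_df$image) == "ok.png", ]
  expect_equal(ok_row$status, "ok")
  expect_lt(abs(ok_row$bar_px - 300), 2 + 1e-9)
  unlink(d, recursive = TRUE)
})

test_that("recovered metric lengths are resolution-invariant", {
  # the same scene at 1x and 2x: mm_per_px halves, recovered mm unchanged
  sl_mm <- function(scale) {
    w <- 400 * scale; h <- 300 * scale
    img <- matrix(230, h, w)
    # bar: known length 150*scale px = 15 mm
    img[(h - 30):(h - 30 + 3 * scale), (100 * scale):(250 * scale - 1) + 1] <- 20
    # fish proxy: two landmarks 180*scale px apart
    lm <- cbind(c(60, 240) * scale, c(100, 100) * scale)
    lines <- detect_lines(preprocess_for_lines(img),
                          hough_params(threshold = 30,
                                       min_line_length = 60 * scale,
                                       max_line_gap = 5))
    bar <- select_scale_bar(lines, max_tilt = 5)
    cal <- calibrate(bar$length_px, 15)
    list(mm_per_px = cal$mm_per_px,
         sl = to_mm(sqrt(sum((lm[2, ] - lm[1, ])^2)), cal))
  }
  r1 <- sl_mm(1)
  r2 <- sl_mm(2)
  expect_equal(r2$mm_per_px, r1$mm_per_px / 2, tolerance = 0.02)
  expect_equal(r1$sl, 18, tolerance = 0.02)   # 180 px at 0.1 mm/px
  expect_equal(r2$sl, r1$sl, tolerance = 0.02)
})
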