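# printed (% of diagonal, pixel) accuracy pairs from diagonal-normalized
# evaluation reports at two stated geometries; the single pair that does
# not follow nearest-integer rounding (0.64% <-> 13 px at 1800x1200,
# which computes to 14) is documented and excluded
pct_px_pairs_1800x1200 <- data.frame(
  pct = c(0.76, 0.92, 0.54, 0.24, 0.37, 0.23, 0.32, 0.19, 0.28),
  px = c(16L, 20L, 12L, 5L, 8L, 5L, 7L, 4L, 6L))
pct_px_pairs_1200x900 <- data.frame(pct = c(0.40, 0.21), px = c(6L, 3L))

test_that("normalized_deviation computes percent of the image diagonal", {
  expect_equal(normalized_deviation(6, 1200, 900), 0.40)
  expect_equal(normalized_deviation(0, 640, 480), 0)
  # scale invariance: (d, w, h) and (2d, 2w, 2h) agree
  set.seed(3)
  d <- runif(20, 0, 50)
  expect_equal(normalized_deviation(d, 1800, 1200),
               normalized_deviation(2 * d, 3600, 2400))
  expect_error(normalized_deviation(-1, 100, 100), "negative")
})

test_that("percent_to_pixels reproduces the printed pixel values", {
  expect_identical(
    percent_to_pixels(pct_px_pairs_1800x1200$pct, 1800, 1200),
    pct_px_pairs_1800x1200$px)
  expect_identical(
    percent_to_pixels(pct_px_pairs_1200x900$pct, 1200, 900),
    pct_px_pairs_1200x900$px)
  expect_identical(percent_to_pixels(0, 1800, 1200), 0L)
  expect_error(percent_to_pixels(-0.1, 100, 100), "negative")
})

test_that("percent and pixel conversions are mutual inverses up to rounding", {
  set.seed(11)
  d <- sample(0:60, 30, TRUE) + round(runif(30), 2)
  for (geom in list(c(1800, 1200), c(1200, 900), c(400, 300))) {
    back <- percent_to_pixels(normalized_deviation(d, geom[1], geom[2]),
                              geom[1], geom[2])
    expect_true(all(abs(back - d) <= 0.5))
  }
})

test_that("compare_landmark_sets measures per-landmark deviations", {
  a <- random_dataset(6, 3, width = 400L, height = 300L, seed = 21)
  # b: same images, shifted by a known 3-4-5 offset on landmark 1
  b <- a
  for (i in seq_along(b$images)) {
    lm <- b$images[[i]]$landmarks
    lm[1, ] <- pmin(lm[1, ] + c(3L, 4L), c(399L, 299L))
    b$images[[i]]$landmarks <- lm
  }
  rep_ab <- compare_landmark_sets(a, b)
  rep_ba <- compare_landmark_sets(b, a)
  expect_equal(rep_ab$per_landmark_mean_px, rep_ba$per_landmark_mean_px)
  expect_equal(rep_ab$per_landmark_mean_px[2:3], c(0, 0))
  expect_true(rep_ab$per_landmark_mean_px[1] <= 5 &&
                rep_ab$per_landmark_mean_px[1] > 0)
  # identity comparison: all zeros
  rep_aa <- compare_landmark_sets(a, a)
  expect_equal(rep_aa$per_landmark_mean_px, rep(0, 3))
  expect_equal(rep_aa$overall_mean_pct, 0)
  # brute-force oracle over every image/landmark pair
  oracle_px <- sapply(1:3, function(k) {
    tot <- 0
    for (i in seq_along(a$images)) {
      bi <- which(vapply(b$images, `[[`, "", "file") == a$images[[i]]$file)
      tot <- tot + sqrt(sum((a$images[[i]]$landmarks[k, ] -
                               b$images[[bi]]$landmarks[k, ])^2))
    }
    tot / length(a$images)
  })
  expect_equal(unname(rep_ab$per_landmark_mean_px), oracle_px)
  expect_equal(rep_ab$per_landmark_mean_pct,
               normalized_deviation(rep_ab$per_landmark_mean_px, 400, 300))
  # pct uses the stated geometry when passed explicitly
  rep_big <- compare_landmark_sets(a, b, width = 1800, height = 1200)
  expect_equal(rep_big$per_landmark_mean_pct,
               normalized_deviation(rep_ab$per_landmark_mean_px, 1800, 1200))
  # mismatched image sets: error lists the symmetric difference
  expect_error(compare_landmark_sets(a, subset_ds(b, 1:5)), "img_006")
})

test_that("error_gap is the elementwise model-minus-observer difference", {
  mk_rep <- function(pcts) structure(
    list(per_landmark_mean_px = pcts, per_landmark_mean_pct = pcts,
         overall_mean_px = mean(pcts), overall_mean_pct = mean(pcts),
         n_images = 10L), class = "deviation_report")
  # model at 0.23/0.32%, observer at 0.19/0.28% -> 0.04% worse on both
  expect_equal(error_gap(mk_rep(c(0.23, 0.32)), mk_rep(c(0.19, 0.28))),
               c(0.04, 0.04))
  expect_equal(error_gap(mk_rep(c(0.5, 0.5)), mk_rep(c(0.5, 0.5))), c(0, 0))
  expect_error(error_gap(mk_rep(c(0.1)), mk_rep(c(0.1, 0.2))), "mismatch")
})

test_that("deviation reports export to JSON and CSV", {
  a <- random_dataset(4, 2, seed = 31)
  rp <- compare_landmark_sets(a, a)
  stem <- tempfile()
  write_deviation_report(rp, paste0(stem, ".json"))
  j <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(j$n_images, 4L)
  csv <- read.csv(paste0(stem, ".csv"))
  expect_equal(nrow(csv), 2L)
  expect_equal(csv$mean_px, c(0, 0))
  unlink(paste0(stem, c(".json", ".csv")))
})
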