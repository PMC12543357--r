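test_that("write/read round-trips valid datasets (property)", {
  for (case in 1:8) {
    n_img <- case %% 5L
    n_lm <- 1L + case %% 4L
    ds <- random_dataset(n_img, n_lm, seed = 100 + case)
    p <- tempfile(fileext = ".xml")
    write_landmark_xml(ds, p)
    back <- read_landmark_xml(p)
    expect_equal(length(back$images), n_img)
    if (n_img > 0) expect_equal(back$n_landmarks, n_lm)
    for (i in seq_len(n_img)) {
      expect_identical(back$images[[i]]$file, ds$images[[i]]$file)
      expect_identical(back$images[[i]]$landmarks, ds$images[[i]]$landmarks)
      expect_identical(back$images[[i]]$width, ds$images[[i]]$width)
      expect_identical(back$images[[i]]$box, ds$images[[i]]$box)
    }
    unlink(p)
  }
})

test_that("part names map ordinally and coordinates verbatim", {
  xml <- paste0(
    "<dataset><images><image file='a.png' width='100' height='100'>",
    "<box top='0' left='0' width='100' height='100'>",
    "<part name='001' x='30' y='40'/><part name='000' x='10' y='20'/>",
    "</box></image></images></dataset>")
  p <- tempfile(fileext = ".xml")
  writeLines(xml, p)
  ds <- read_landmark_xml(p)
  # lexicographic part order = landmark order, regardless of file order
  expect_identical(unname(ds$images[[1]]$landmarks[, "x"]), c(10L, 30L))
  expect_identical(unname(ds$images[[1]]$landmarks[, "y"]), c(20L, 40L))
  # a landmark at the origin is the upper-left pixel and is legal
  ds0 <- landmark_dataset(list(image_annotation(
    "o.png", 50L, 50L, landmarks = cbind(0L, 0L))))
  expect_silent(write_landmark_xml(ds0, p))
  expect_identical(read_landmark_xml(p)$images[[1]]$landmarks[1, ],
                   c(x = 0L, y = 0L))
})

test_that("written XML has zero-padded parts and verbatim attributes", {
  ds <- random_dataset(3, 2, seed = 5)
  ds$images[[1]]$landmarks[1, ] <- c(5L, 7L)
  p <- tempfile(fileext = ".xml")
  write_landmark_xml(ds, p)
  doc <- xml2::read_xml(p)
  parts <- xml2::xml_find_all(doc, ".//part")
  expect_length(parts, 6L) # 3 images x 2 landmarks
  expect_setequal(unique(xml2::xml_attr(parts, "name")), c("00", "01"))
  first <- xml2::xml_find_first(doc, ".//part[@name='00']")
  expect_identical(xml2::xml_attr(first, "x"), "5")
  expect_identical(xml2::xml_attr(first, "y"), "7")
})

test_that("empty dataset writes valid XML with zero image entries", {
  p <- tempfile(fileext = ".xml")
  write_landmark_xml(landmark_dataset(list()), p)
  expect_length(xml2::xml_find_all(xml2::read_xml(p), ".//image"), 0L)
})

test_that("malformed and inconsistent files give informative errors", {
  p <- tempfile(fileext = ".xml")
  writeLines("<dataset><images><image file='a.png'>", p)
  expect_error(read_landmark_xml(p), "malformed XML")

  writeLines(paste0(
    "<dataset><images>",
    "<image file='a.png'><box top='0' left='0' width='9' height='9'>",
    "<part name='00' x='1' y='1'/><part name='01' x='2' y='2'/></box></image>",
    "<image file='b.png'><box top='0' left='0' width='9' height='9'>",
    "<part name='00' x='1' y='1'/></box></image>",
    "</images></dataset>"), p)
  expect_error(read_landmark_xml(p), "heterogeneous.*b\\.png")

  expect_error(landmark_dataset(list(
    image_annotation("dup.png", 10L, 10L, landmarks = cbind(1L, 1L)),
    image_annotation("dup.png", 10L, 10L, landmarks = cbind(2L, 2L)))),
    "duplicate")
  expect_error(image_annotation("a.png", 10L, 10L,
                                landmarks = cbind(10L, 3L)),
               "beyond image width")
})

test_that("render_overlay draws filled discs on a copy", {
  img <- matrix(100, 61, 81)
  # no landmarks: pixel-identical output (as RGB expansion of the input)
  out0 <- render_overlay(img, matrix(integer(0), 0, 2))
  expect_true(all(out0 == 100))
  # one centred disc of radius 5
  centre <- cbind(40L, 30L)
  out <- render_overlay(img, centre, radius = 5, colour = c(255, 0, 0))
  expect_true(all(img == 100)) # input untouched
  xs <- matrix(rep(0:80, each = 61), 61, 81)
  ys <- matrix(rep(0:60, times = 81), 61, 81)
  inside <- (xs - 40)^2 + (ys - 30)^2 <= 25
  expect_true(all(out[, , 1][inside] == 255))
  expect_true(all(out[, , 2][inside] == 0))
  expect_true(all(out[, , 1][!inside] == 100))
  # predicted vs manual marker sets are distinguishable by colour
  both <- render_overlay(render_overlay(img, cbind(10L, 10L),
                                        colour = c(255, 0, 0)),
                         cbind(60L, 50L), colour = c(0, 0, 255))
  expect_true(any(both[, , 1] == 255 & both[, , 3] == 0))
  expect_true(any(both[, , 3] == 255 & both[, , 1] == 0))
  # out-of-frame landmark clamps with a warning, never crashes
  expect_warning(render_overlay(img, cbind(500L, 500L)), "clamped")
})
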