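test_that("scale calibration is the physical/pixel ratio", {
  expect_equal(calibrate_scale(1000, 1000), 1)
  expect_equal(calibrate_scale(2560, 1000), 0.390625)
  expect_error(calibrate_scale(0, 1000), "positive")
  expect_error(calibrate_scale(100, -1), "positive")
})

test_that("binarize thresholds 8-bit images and rejects empty foregrounds", {
  img <- calibrated_image(matrix(200, 20, 30), 1)
  expect_true(all(binarize(img, 128)))
  expect_error(binarize(calibrated_image(matrix(0, 10, 10), 1), 128),
               "empty foreground")
  expect_error(binarize(img, 300), "\\[0, 255\\]")
})

test_that("otsu binarization recovers the drawn area of a rendering", {
  prof <- make_profile(bump_spec("rounded", W = 80, H = 20, noise_sd = 0))
  img <- render_profile_image(prof, 1, ruler_length = 50)
  mask <- binarize(img, "otsu")
  gt <- attr(img, "ground_truth")
  expect_lt(abs(sum(mask) - gt$drawn_area_px) / gt$drawn_area_px, 0.05)
})

test_that("outline tracing orders components by size, largest first", {
  m <- matrix(FALSE, 40, 60)
  m[10:30, 5:25] <- TRUE   # 21 x 21 block
  m[5:10, 40:55] <- TRUE   # smaller block
  segs <- trace_outline(m)
  expect_length(segs, 2)
  expect_gt(nrow(segs[[1]]), nrow(segs[[2]]))
  # rectilinear boundary of a filled rectangle touches all four corners
  s <- segs[[1]]
  expect_setequal(range(s[, "x"]), c(4, 24))              # 0-based columns
  expect_setequal(range(s[, "y"]), c(39 - 29, 39 - 9))    # y flipped upward
  expect_error(trace_outline(matrix(FALSE, 5, 5)), "no foreground")
})

test_that("line-graph extraction keeps the topmost boundary per column", {
  # a filled semicircle: the extracted profile is its upper half only
  r <- 30
  m <- matrix(FALSE, 60, 100)
  for (cx in 1:100) for (cy in 1:60) {
    if ((cx - 50)^2 + (60 - cy)^2 <= r^2) m[cy, cx] <- TRUE
  }
  seg <- trace_outline(m)[[1]]
  prof <- extract_profile(seg, 1)
  expect_true(all(diff(prof[, "x"]) > 0))   # single-valued in x
  mid <- unname(prof[which.min(abs(prof[, "x"] - 49)), "y"])
  expect_equal(mid, r, tolerance = 2)
  expect_error(extract_profile(seg[seg[, "x"] == 49, , drop = FALSE]),
               "fewer than 20")
})

test_that("render -> binarize -> trace -> extract round trip is faithful", {
  for (shape in c("rounded", "acute")) {
    prof <- make_profile(bump_spec(shape, noise_sd = 0), n_points = 150)
    mpp <- 0.5
    img <- render_profile_image(prof, mpp, ruler_length = 50)
    gt <- attr(img, "ground_truth")
    seg <- trace_outline(binarize(img, "otsu"))[[1]]
    ext <- extract_profile(seg, mpp)
    # compare at the rendered columns against the generated profile
    x0 <- gt$base_px["left"] * mpp
    truth <- approx(gt$profile[, 1], gt$profile[, 2],
                    xout = ext[, "x"] - x0, rule = 2)$y
    base_y <- min(ext[, "y"])
    expect_lt(max(abs((ext[, "y"] - base_y) - truth)), 2 * mpp)
  }
})

test_that("segmenting re-zeroes the base line and crops correctly", {
  prof <- make_profile(bump_spec("rounded", W = 60, H = 15, noise_sd = 0))
  full <- segment_tubercle(prof)
  expect_equal(unname(measure_width_height(full)["W"]), 60, tolerance = 0.01)
  # a tilted profile: base line through the base points is subtracted
  x <- seq(0, 50, length.out = 60)
  tilted <- cbind(x, 0.3 * x + 10 * sin(pi * x / 50))
  tp <- segment_tubercle(tilted, 5, 45)
  expect_equal(unname(tp[1, "y"]), 0, tolerance = 1e-9)
  expect_equal(unname(tp[nrow(tp), "y"]), 0, tolerance = 1e-9)
  expect_equal(max(tp[, "x"]), 40)
  expect_error(segment_tubercle(tilted, 45, 5), "smaller")
  expect_error(segment_tubercle(tilted, -10, 45), "outside")
})

test_that("coordinate CSVs round trip through the declared column names", {
  prof <- make_profile(bump_spec("rounded", noise_sd = 0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, f)
  back <- read_profile_csv(f)
  expect_equal(unname(back[, "x"]), unname(prof[, "x"]), tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1:25, b = 1:25), bad, row.names = FALSE)
  expect_error(read_profile_csv(bad), "x_micron")
})

test_that("doubling the scale doubles coordinates and halves curvature", {
  prof <- make_profile(bump_spec("rounded", W = 60, H = 18, noise_sd = 0),
                       n_points = 150)
  img <- render_profile_image(prof, 1, ruler_length = 50)
  seg <- trace_outline(binarize(img, "otsu"))[[1]]
  e1 <- extract_profile(seg, 1)
  e2 <- extract_profile(seg, 2)
  expect_equal(e2, e1 * 2, tolerance = 1e-12, ignore_attr = TRUE)
  r1 <- analyze_tubercle(e1)
  r2 <- analyze_tubercle(e2)
  expect_equal(r2$kmax / r1$kmax, 0.5, tolerance = 1e-6)
  expect_equal(r2$W / r1$W, 2, tolerance = 1e-9)
})
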