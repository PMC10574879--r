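test_that("a curve exactly representable at the fitted degree is recovered", {
  b <- bezier(rbind(c(0, 0), c(50, 40), c(100, 0)))
  pts <- predict(b, seq(0, 1, length.out = 11))
  fit <- bezier_fit(pts, degree = 2)
  expect_lt(max(abs(coef(fit) - coef(b))), 1e-6)
  expect_lt(fit$rms, 1e-8)
})

test_that("evaluation interpolates the endpoints and matches de Casteljau", {
  set.seed(42)
  for (deg in 2:6) {
    b <- random_bezier(deg)
    expect_equal(drop(predict(b, 0)), b$control[1, ], ignore_attr = TRUE)
    expect_equal(drop(predict(b, 1)), b$control[deg + 1, ],
                 ignore_attr = TRUE)
    tt <- runif(20)
    expect_lt(max(abs(predict(b, tt) - predict(b, tt, method = "casteljau"))),
              1e-9)
  }
  b <- bezier(rbind(c(0, 0), c(50, 40), c(100, 0)))
  expect_equal(drop(predict(b, 0.5)), c(x = 50, y = 20))
  expect_error(predict(b, 1.2), "\\[0, 1\\]")
  expect_error(predict(b, -0.1), "\\[0, 1\\]")
})

test_that("fitting requires enough points and a sensible degree", {
  pts <- cbind(1:4, c(0, 1, 1, 0))
  expect_error(bezier_fit(pts, degree = 5), "at least 6")
  expect_error(bezier_fit(pts, degree = 1), "at least 2")
  expect_error(bezier_fit(rbind(c(0, 0), c(0, 0), c(1, 1), c(2, 2)),
                          degree = 2), "duplicate")
})

test_that("a straight segment fits exactly with zero curvature", {
  pts <- cbind(seq(0, 100, length.out = 40), 0)
  for (deg in c(2, 5)) {
    prof <- curvature_profile(bezier_fit(pts, degree = deg))
    expect_lt(max(prof$kappa_scaled), 1e-6)
  }
})

test_that("circular arcs are recovered at the stated unit convention", {
  # mean |kappa| x 1000 must land within 2% of 1000/r
  for (r in c(10, 25, 50, 100)) {
    fit <- bezier_fit(arc_points(r), degree = 5)
    prof <- curvature_profile(fit)
    expect_gt(mean_abs_curvature(prof), 0.98 * 1000 / r)
    expect_lt(mean_abs_curvature(prof), 1.02 * 1000 / r)
    # constant-curvature input: the whole profile is constant within 2%
    expect_lt(diff(range(prof$kappa_scaled)) / mean(prof$kappa_scaled), 0.02)
  }
})

test_that("analytic curvature agrees with a finite-difference oracle", {
  set.seed(7)
  for (rep in 1:10) {
    b <- random_bezier(sample(2:6, 1))
    tt <- seq(0.05, 0.95, length.out = 25)
    ana <- bezier_curvature(b, tt)
    ora <- fd_curvature(b, tt)
    expect_lt(max(abs(ana - ora) / pmax(abs(ora), 1e-8)), 1e-5)
  }
  # the worked parabola case
  b <- bezier(rbind(c(0, 0), c(50, 40), c(100, 0)))
  expect_equal(unname(bezier_curvature(b, 0.5)), fd_curvature(b, 0.5),
               tolerance = 1e-6)
})

test_that("curvature is Euclidean invariant and scales inversely with size", {
  set.seed(11)
  pts <- predict(random_bezier(5), seq(0, 1, length.out = 50))
  base <- curvature_profile(bezier_fit(pts, degree = 5))$kappa_scaled
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(pts %*% t(R), 2, c(-30, 12), "+")
  rot <- curvature_profile(bezier_fit(moved, degree = 5))$kappa_scaled
  expect_lt(max(abs(base - rot)), 1e-9 * max(base))
  scaled <- curvature_profile(bezier_fit(pts * 2.5, degree = 5))$kappa_scaled
  expect_equal(scaled, base / 2.5, tolerance = 1e-9)
})

test_that("a cusp is flagged as NA, never silently zeroed", {
  b <- bezier(rbind(c(0, 0), c(0, 0), c(50, 40), c(100, 0)))
  expect_warning(k <- bezier_curvature(b, c(0, 0.5)), "cusp")
  expect_true(is.na(k[1]))
  expect_false(is.na(k[2]))
})

test_that("curvature profiles locate the maxima the shapes imply", {
  # single acute bump: unique interior maximum, found where dense sampling
  # of the fitted curve puts it (auto degree resolves the apex)
  fit <- bezier_fit(make_profile(bump_spec("acute", noise_sd = 0)),
                    degree = "auto")
  prof <- curvature_profile(fit, 200)
  t_max <- prof$t[which.max(prof$kappa_scaled)]
  dense <- curvature_profile(fit, 5000)
  expect_equal(t_max, dense$t[which.max(dense$kappa_scaled)],
               tolerance = 0.02)
  expect_gt(t_max, 0.2)
  expect_lt(t_max, 0.8)
  # compound bump: at least two local maxima above half the global mean
  fitc <- bezier_fit(make_profile(bump_spec("compound", noise_sd = 0)),
                     degree = "auto")
  k <- curvature_profile(fitc, 500)$kappa_scaled
  interior <- 2:(length(k) - 1)
  peaks <- interior[k[interior] > k[interior - 1] &
                    k[interior] >= k[interior + 1] &
                    k[interior] > mean(k) / 2]
  expect_gte(length(unique(round(peaks / 10))), 2)
  expect_error(curvature_profile(fit, 10), "at least 50")
})

test_that("profile summaries obey max >= mean and ratio >= 1", {
  set.seed(3)
  for (rep in 1:8) {
    pts <- predict(random_bezier(5), seq(0, 1, length.out = 60))
    prof <- curvature_profile(bezier_fit(pts, degree = 4))
    kmax <- max_abs_curvature(prof)
    kmean <- mean_abs_curvature(prof)
    expect_gte(kmax, kmean)
    expect_gte(curvature_ratio(kmax, kmean), 1)
  }
  # constant-curvature arc: ratio ~ 1
  prof <- curvature_profile(bezier_fit(arc_points(50), degree = 5))
  expect_equal(curvature_ratio(prof), 1, tolerance = 0.02)
  # straight profile: undefined ratio is flagged
  expect_warning(r <- curvature_ratio(0, 0), "undefined")
  expect_true(is.nan(r))
})

test_that("arc-length weighting of the mean is available and close for
          near-uniform parameterizations", {
  prof <- curvature_profile(bezier_fit(arc_points(50), degree = 5))
  expect_equal(mean_abs_curvature(prof, weighted = TRUE),
               mean_abs_curvature(prof), tolerance = 0.01)
})

test_that("automatic degree selection stops at the residual target", {
  pts <- make_profile(bump_spec("acute", noise_sd = 0), n_points = 120)
  fit <- bezier_fit(pts, degree = "auto")
  expect_true(fit$rms < 0.5 || fit$degree == 10)
  expect_gte(fit$degree, 3)
})

test_that("profiles serialize to CSV and JSON round-trippably", {
  fit <- bezier_fit(arc_points(50), degree = 5)
  prof <- curvature_profile(fit)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_curvature_csv(prof, csv)
  back <- read.csv(csv)
  expect_equal(back$kappa_scaled, prof$kappa_scaled, tolerance = 1e-6)
  write_curvature_json(prof, js, curve = fit)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(obj$kappa_mean, attr(prof, "kappa_mean"), tolerance = 1e-9)
  expect_equal(dim(obj$control_points), c(6, 2))
})
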