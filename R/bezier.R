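#' Fit an endpoint-constrained Bezier curve to planar points
#'
#' Least-squares fit of a polynomial Bezier curve in the Bernstein basis to an
#' ordered sequence of planar points, under chord-length parameterization. The
#' first and last control points are constrained to coincide with the first and
#' last data points, so the fitted curve interpolates the profile ends exactly;
#' the interior control points are solved by linear least squares.
#'
#' The chord-length parameter values are used as initialization and then
#' refined by Gauss-Newton parameter correction (foot-point projection of
#' each data point onto the current curve, followed by a refit), the
#' standard scheme for least-squares fitting of digitized outlines; a curve
#' exactly representable at the fitted degree is thereby recovered to
#' machine precision. Set `correct_parameters = 0` for a plain chord-length
#' fit.
#'
#' Digitized tubercle outlines are typically supplied in microns (see
#' [extract_profile()]); curvatures derived from the fit are then in
#' micron^-1. With `degree = "auto"` the degree is increased from
#' `min_degree` until the residual RMS drops below `rms_target` microns or
#' `max_degree` is reached.
#'
#' @param points a two-column matrix or data.frame of ordered (x, y)
#'   coordinates, or a numeric vector `x` when `y` is given separately.
#'   Consecutive duplicate points are not allowed.
#' @param y optional numeric vector of ordinates when `points` is a vector.
#' @param degree integer polynomial degree (>= 2), or `"auto"`.
#' @param rms_target residual RMS (microns) at which automatic degree
#'   selection stops.
#' @param min_degree,max_degree degree range searched when `degree = "auto"`.
#' @param correct_parameters maximum number of parameter-correction
#'   iterations (0 disables).
#' @return an object of class `c("bezier_fit", "bezier")` with components
#'   `control` (the (degree+1) x 2 control polygon), `degree`, `t` (the
#'   chord-length parameter values of the input points), `data`, `residuals`
#'   (per-point Euclidean residuals) and `rms`.
#' @examples
#' th <- seq(-pi / 3, pi / 3, length.out = 60)
#' arc <- cbind(50 * sin(th), 50 * cos(th))
#' fit <- bezier_fit(arc, degree = 5)
#' fit$rms
#' mean_abs_curvature(curvature_profile(fit)) # ~ 20 (micron^-1 x 1000)
#' @seealso [curvature_profile()], [bezier_curvature()], [analyze_tubercle()]
#' @export
bezier_fit <- function(points, y = NULL, degree = 5, rms_target = 0.5,
                       min_degree = 3, max_degree = 10,
                       correct_parameters = 10) {
  P <- as_planar_points(points, y)
  if (identical(degree, "auto")) {
    fit <- NULL
    for (d in seq(min_degree, max_degree)) {
      if (nrow(P) < d + 1) break
      fit <- bezier_fit(P, degree = d, correct_parameters = correct_parameters)
      if (fit$rms < rms_target) break
    }
    if (is.null(fit)) stop("too few points for degree ", min_degree,
                           ": need at least ", min_degree + 1)
    return(fit)
  }
  degree <- as.integer(degree)
  if (degree < 2) stop("degree must be at least 2")
  if (nrow(P) < degree + 1) {
    stop("too few points (", nrow(P), ") for degree ", degree,
         ": need at least ", degree + 1)
  }
  tt <- chord_length_param(P)
  fit <- bezier_fit_at(P, tt, degree)
  # Gauss-Newton parameter correction: project points onto the current
  # curve, refit, repeat. Iterates are accepted only while the residual at
  # least halves: on data the degree can represent, the iteration converges
  # geometrically to machine precision; on data it cannot (pixel noise, a
  # near-corner), slow parameter drift would instead let the unconstrained
  # end spans of the curve whip, so the chord-length fit stands.
  for (it in seq_len(correct_parameters)) {
    tt_new <- project_parameters(fit, tt)
    new_fit <- bezier_fit_at(P, tt_new, degree)
    if (!is.finite(new_fit$rms) || new_fit$rms > 0.5 * fit$rms) break
    fit <- new_fit
    tt <- tt_new
  }
  fit
}

bezier_fit_at <- function(P, tt, degree) {
  B <- bernstein_basis(tt, degree)
  n1 <- degree + 1L
  # endpoint constraint: move the first/last basis contribution to the rhs
  rhs <- P - tcrossprod(B[, 1L], P[1L, ]) - tcrossprod(B[, n1], P[nrow(P), ])
  mid <- qr.solve(qr(B[, 2:degree, drop = FALSE]), rhs)
  control <- rbind(P[1L, , drop = FALSE], mid, P[nrow(P), , drop = FALSE])
  dimnames(control) <- list(NULL, c("x", "y"))
  res <- sqrt(rowSums((B %*% control - P)^2))
  structure(
    list(control = control, degree = degree, t = tt, data = P,
         residuals = res, rms = sqrt(mean(res^2))),
    class = c("bezier_fit", "bezier")
  )
}

# one Newton foot-point step per data point; endpoints stay pinned at 0, 1.
# Steps are damped to a fraction of the local parameter gap and the sequence
# kept monotone, so parameters cannot collapse and leave curve segments
# unconstrained by data (which whips the fit near the ends).
project_parameters <- function(fit, tt) {
  d1 <- bezier_hodograph(fit)
  d2 <- bezier_hodograph(d1)
  C <- predict.bezier(fit, tt)
  v1 <- bernstein_basis(tt, d1$degree) %*% d1$control
  v2 <- bernstein_basis(tt, d2$degree) %*% d2$control
  diffp <- C - fit$data
  num <- rowSums(diffp * v1)
  den <- rowSums(v1^2) + rowSums(diffp * v2)
  step <- ifelse(abs(den) > .Machine$double.eps, num / den, 0)
  n <- length(tt)
  gap <- pmin(c(tt[2] - tt[1], diff(tt)), c(diff(tt), tt[n] - tt[n - 1]))
  step <- sign(step) * pmin(abs(step), 0.4 * gap)
  out <- pmin(1, pmax(0, tt - step))
  out[1L] <- 0
  out[n] <- 1
  cummax(out)
}

#' Construct a Bezier curve from a control polygon
#'
#' @param control a (degree+1) x 2 matrix of control points (microns);
#'   the degree is `nrow(control) - 1` and must be at least 2.
#' @return an object of class `"bezier"`.
#' @examples
#' b <- bezier(rbind(c(0, 0), c(50, 40), c(100, 0)))
#' predict(b, t = 0.5) # (50, 20)
#' @export
bezier <- function(control) {
  control <- as.matrix(control)
  if (ncol(control) != 2L || nrow(control) < 3L) {
    stop("control must be a matrix of at least 3 planar points")
  }
  storage.mode(control) <- "double"
  dimnames(control) <- list(NULL, c("x", "y"))
  structure(list(control = control, degree = nrow(control) - 1L),
            class = "bezier")
}

# Bernstein design matrix: length(t) x (degree+1)
bernstein_basis <- function(t, degree) {
  outer(t, 0:degree, function(t, j) {
    choose(degree, j) * t^j * (1 - t)^(degree - j)
  })
}

# chord-length parameter values in [0, 1]; errors on duplicate points
chord_length_param <- function(P) {
  d <- sqrt(rowSums(diff(P)^2))
  if (any(d == 0)) stop("consecutive duplicate points are not allowed")
  c(0, cumsum(d)) / sum(d)
}

as_planar_points <- function(points, y = NULL) {
  if (!is.null(y)) points <- cbind(points, y)
  P <- as.matrix(points)
  if (ncol(P) != 2L) stop("points must have two columns (x, y)")
  if (nrow(P) < 3L) stop("at least 3 points are required")
  if (anyNA(P)) stop("points must not contain NA")
  storage.mode(P) <- "double"
  dimnames(P) <- list(NULL, c("x", "y"))
  P
}

#' Evaluate a Bezier curve
#'
#' Evaluates the curve at parameter values `t` by the Bernstein sum. The
#' numerically independent de Casteljau recursion is available through
#' `method = "casteljau"` and agrees with the Bernstein sum to machine
#' precision; `t = 0` and `t = 1` return the first and last control point
#' exactly.
#'
#' @param object a `"bezier"` or `"bezier_fit"` object.
#' @param t numeric vector of parameter values in `[0, 1]`.
#' @param method `"bernstein"` (default) or `"casteljau"`.
#' @param ... unused.
#' @return a `length(t)` x 2 matrix of curve points.
#' @export
predict.bezier <- function(object, t, method = c("bernstein", "casteljau"),
                           ...) {
  method <- match.arg(method)
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  C <- object$control
  if (method == "bernstein") {
    out <- bernstein_basis(t, object$degree) %*% C
  } else {
    out <- t(vapply(t, function(ti) de_casteljau(C, ti), numeric(2)))
  }
  colnames(out) <- c("x", "y")
  out
}

de_casteljau <- function(C, t) {
  while (nrow(C) > 1L) {
    C <- (1 - t) * C[-nrow(C), , drop = FALSE] + t * C[-1L, , drop = FALSE]
  }
  drop(C)
}

# hodograph: the derivative of a Bezier curve is a Bezier curve of one
# degree less with control points n * diff(C)
bezier_hodograph <- function(curve) {
  bezier_raw(curve$degree * diff(curve$control))
}

# like bezier() but permits degree < 2 (used for hodographs only)
bezier_raw <- function(control) {
  structure(list(control = control, degree = nrow(control) - 1L),
            class = "bezier")
}

#' Signed planar curvature of a Bezier curve
#'
#' Curvature is the rate of change of the unit tangent with respect to arc
#' length; for a planar parametric curve it equals
#' \deqn{\kappa(t) = \frac{x'y'' - y'x''}{(x'^2 + y'^2)^{3/2}},}
#' with derivatives taken on the Bezier hodographs. Units are micron^-1 when
#' the control points are in microns. Parameter values at which the first
#' derivative effectively vanishes (below `1e-9` times the control-polygon
#' chord length; a cusp) yield `NA` with a warning, never a silent zero.
#'
#' @param curve a `"bezier"` or `"bezier_fit"` object.
#' @param t numeric vector of parameter values in `[0, 1]`.
#' @param signed logical; if `FALSE`, absolute curvature is returned.
#' @return numeric vector of curvatures (micron^-1).
#' @examples
#' b <- bezier(rbind(c(0, 0), c(50, 40), c(100, 0)))
#' bezier_curvature(b, 0.5)
#' @export
bezier_curvature <- function(curve, t, signed = TRUE) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  d1 <- bezier_hodograph(curve)
  d2 <- bezier_hodograph(d1)
  v1 <- bernstein_basis(t, d1$degree) %*% d1$control
  v2 <- bernstein_basis(t, d2$degree) %*% d2$control
  speed2 <- rowSums(v1^2)
  chord <- sum(sqrt(rowSums(diff(curve$control)^2)))
  cusp <- sqrt(speed2) < 1e-9 * chord
  k <- (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]) / speed2^1.5
  if (any(cusp)) {
    warning(sum(cusp), " sample(s) at a vanishing first derivative (cusp); ",
            "curvature set to NA there")
    k[cusp] <- NA_real_
  }
  if (signed) k else abs(k)
}

#' Sample the absolute curvature profile of a fitted curve
#'
#' Samples `|kappa(t)| * 1000` (micron^-1 x 1000, the reporting convention in
#' which a curvature of 20 corresponds to an osculating circle of radius 50
#' microns) at `n_samples` uniformly spaced parameter values, together with
#' the curve points and cumulative arc length for plotting. Cusp samples (see
#' [bezier_curvature()]) are `NA` and are excluded from the summary
#' statistics.
#'
#' @param curve a `"bezier"` or `"bezier_fit"` object with coordinates in
#'   microns.
#' @param n_samples number of uniform parameter samples (>= 50).
#' @return a data.frame of class `"curvature_profile"` with columns `t`, `x`,
#'   `y`, `kappa` (signed, micron^-1), `kappa_scaled` (absolute, x 1000) and
#'   `arc` (cumulative arc length, microns), and attributes `kappa_max`,
#'   `kappa_mean` and `kappa_ratio`.
#' @examples
#' th <- seq(-pi / 3, pi / 3, length.out = 60)
#' prof <- curvature_profile(bezier_fit(cbind(50 * sin(th), 50 * cos(th))))
#' attr(prof, "kappa_mean")
#' @export
curvature_profile <- function(curve, n_samples = 200) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 50L) stop("n_samples must be at least 50")
  tt <- seq(0, 1, length.out = n_samples)
  xy <- predict.bezier(curve, tt)
  k <- suppressWarnings(bezier_curvature(curve, tt, signed = TRUE))
  if (anyNA(k)) {
    warning(sum(is.na(k)), " cusp sample(s) excluded from curvature summary")
  }
  out <- data.frame(t = tt, x = xy[, 1], y = xy[, 2], kappa = k,
                    kappa_scaled = abs(k) * 1000,
                    arc = c(0, cumsum(sqrt(rowSums(diff(xy)^2)))))
  class(out) <- c("curvature_profile", "data.frame")
  attr(out, "kappa_max") <- max(out$kappa_scaled, na.rm = TRUE)
  attr(out, "kappa_mean") <- mean(out$kappa_scaled, na.rm = TRUE)
  attr(out, "kappa_ratio") <- attr(out, "kappa_max") / attr(out, "kappa_mean")
  out
}

#' Curvature summary statistics
#'
#' `max_abs_curvature()` and `mean_abs_curvature()` return the maximum and the
#' arithmetic mean of the sampled absolute curvature (micron^-1 x 1000);
#' `mean_abs_curvature(weighted = TRUE)` weights samples by local arc length
#' instead of uniformly in the curve parameter. `curvature_ratio()` is their
#' dimensionless ratio (>= 1 by construction); it is `NaN` with a warning for
#' a perfectly straight profile (zero mean curvature).
#'
#' @param profile a `"curvature_profile"`.
#' @param weighted logical; arc-length weighting for the mean.
#' @param kmax,kmean maximum and mean absolute curvature.
#' @return a scalar.
#' @export
max_abs_curvature <- function(profile) {
  stopifnot(inherits(profile, "curvature_profile"))
  max(profile$kappa_scaled, na.rm = TRUE)
}

#' @rdname max_abs_curvature
#' @export
mean_abs_curvature <- function(profile, weighted = FALSE) {
  stopifnot(inherits(profile, "curvature_profile"))
  k <- profile$kappa_scaled
  if (!weighted) return(mean(k, na.rm = TRUE))
  w <- c(0, diff(profile$arc))
  ok <- !is.na(k)
  sum(k[ok] * w[ok]) / sum(w[ok])
}

#' @rdname max_abs_curvature
#' @export
curvature_ratio <- function(kmax, kmean) {
  if (inherits(kmax, "curvature_profile")) {
    profile <- kmax
    kmax <- max_abs_curvature(profile)
    kmean <- mean_abs_curvature(profile)
  }
  if (kmean == 0) {
    warning("mean curvature is zero (straight profile); ratio undefined")
    return(NaN)
  }
  kmax / kmean
}

#' @export
print.bezier <- function(x, ...) {
  cat("Bezier curve of degree", x$degree, "\n")
  cat("Control points (microns):\n")
  print(round(x$control, 3))
  invisible(x)
}

#' @export
print.bezier_fit <- function(x, ...) {
  cat("Endpoint-constrained Bezier fit, degree", x$degree, "\n")
  cat(sprintf("  %d points, residual RMS %.4g microns\n",
              nrow(x$data), x$rms))
  invisible(x)
}

#' @export
coef.bezier <- function(object, ...) object$control

#' @export
residuals.bezier_fit <- function(object, ...) object$residuals

#' @export
fitted.bezier_fit <- function(object, ...) {
  predict.bezier(object, object$t)
}

#' Plot a fitted tubercle curve and its curvature trace
#'
#' Draws the data and fitted curve in the upper panel and the absolute
#' curvature profile (micron^-1 x 1000) in the lower panel, with the mean
#' curvature drawn as a dashed line.
#'
#' @param x a `"bezier_fit"`.
#' @param n_samples samples along the curve.
#' @param ... passed to the profile `lines()` call.
#' @return the `"curvature_profile"`, invisibly.
#' @export
plot.bezier_fit <- function(x, n_samples = 200, ...) {
  prof <- curvature_profile(x, n_samples)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$data, asp = 1, pch = 16, cex = 0.4, col = "grey50",
       xlab = "x (micron)", ylab = "y (micron)")
  graphics::lines(prof$x, prof$y, lwd = 2, ...)
  plot(prof$t, prof$kappa_scaled, type = "l", lwd = 2,
       xlab = "t", ylab = expression("|" * kappa * "| (" * micron^-1 %*% 1000 * ")"))
  graphics::abline(h = attr(prof, "kappa_mean"), lty = 2)
  invisible(prof)
}

#' @export
plot.curvature_profile <- function(x, ...) {
  plot(x$t, x$kappa_scaled, type = "l", lwd = 2, xlab = "t",
       ylab = expression("|" * kappa * "| (" * micron^-1 %*% 1000 * ")"), ...)
  graphics::abline(h = attr(x, "kappa_mean"), lty = 2)
  invisible(x)
}

#' Serialize a curvature profile or control polygon
#'
#' `write_curvature_csv()` writes columns `t, x, y, kappa_scaled`;
#' `write_curvature_json()` writes the same samples plus the control polygon
#' and summary statistics as JSON.
#'
#' @param profile a `"curvature_profile"`.
#' @param path output file path.
#' @param curve optional `"bezier"` whose control polygon is embedded in the
#'   JSON output.
#' @return `path`, invisibly.
#' @export
write_curvature_csv <- function(profile, path) {
  stopifnot(inherits(profile, "curvature_profile"))
  utils::write.csv(profile[, c("t", "x", "y", "kappa_scaled")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_curvature_csv
#' @export
write_curvature_json <- function(profile, path, curve = NULL) {
  stopifnot(inherits(profile, "curvature_profile"))
  obj <- list(
    samples = profile[, c("t", "x", "y", "kappa_scaled")],
    kappa_max = attr(profile, "kappa_max"),
    kappa_mean = attr(profile, "kappa_mean"),
    kappa_ratio = attr(profile, "kappa_ratio")
  )
  if (!is.null(curve)) obj$control_points <- unname(curve$control)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
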