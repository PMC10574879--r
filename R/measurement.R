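#' Tubercle width at the base and height
#'
#' Width `W` is the distance between the two base points along the base line;
#' height `H` is the maximum perpendicular distance from the base line to the
#' profile. For a profile produced by [segment_tubercle()] the base line is
#' the segment between the two base points; for a bare profile the first and
#' last points are taken as the base.
#'
#' @param profile a `"tubercle_profile"` or a two-column matrix (microns).
#' @return named numeric vector `c(W, H)` in microns.
#' @examples
#' th <- seq(0, pi, length.out = 50)
#' semi <- cbind(30 - 30 * cos(th), 30 * sin(th))
#' measure_width_height(semi) # W = 60, H = 30
#' @export
measure_width_height <- function(profile) {
  P <- unclass_profile(profile)
  a <- P[1L, ]
  b <- P[nrow(P), ]
  W <- sqrt(sum((b - a)^2))
  if (W == 0) stop("degenerate profile: base points coincide")
  # perpendicular distance of every point from the base chord
  u <- (b - a) / W
  d <- (P[, 1] - a[1]) * (-u[2]) + (P[, 2] - a[2]) * u[1]
  H <- max(abs(d))
  if (H < .Machine$double.eps * W) {
    stop("degenerate profile: height is zero (flat profile)")
  }
  c(W = W, H = H)
}

unclass_profile <- function(profile) {
  P <- profile
  attr(P, "base") <- NULL
  attr(P, "baseline_tilt") <- NULL
  class(P) <- NULL
  as_planar_points(P)
}

#' Tubercle slope index
#'
#' The dimensionless steepness index `S = 200 * H / W`: the percent slope of
#' the flank of the symmetric triangle with the same base and height (height
#' over half-width, x 100).
#'
#' @param W width at the base (microns), positive.
#' @param H height (microns), positive.
#' @return the slope index.
#' @examples
#' tubercle_slope(87, 15) # 34.5 (to 1 d.p.)
#' tubercle_slope(35, 69) # 394.3
#' @export
tubercle_slope <- function(W, H) {
  if (any(W <= 0)) stop("W must be positive")
  if (any(H <= 0)) stop("H must be positive")
  200 * H / W
}

#' Measure the six standard variables of one tubercle
#'
#' Runs the full per-tubercle pipeline: base segmentation (if not already
#' done), width/height/slope measurement, light profile smoothing, the
#' endpoint-constrained Bezier fit, and the curvature summary. The six
#' variables are width `W`, height `H`, slope `S = 200 H / W`, maximum and
#' mean absolute curvature (micron^-1 x 1000) and their ratio.
#'
#' Digitized outlines carry pixel-scale jitter that an endpoint-constrained
#' fit converts into spurious curvature spikes near the profile ends; a
#' 3-point moving average is therefore applied before fitting by default
#' (`smooth_window = 0` disables it).
#'
#' @param profile a `"tubercle_profile"` or two-column matrix (microns).
#' @param degree Bezier degree (or `"auto"`), passed to [bezier_fit()].
#' @param n_samples curvature samples, passed to [curvature_profile()].
#' @param smooth_window odd moving-average window applied to the profile
#'   ordinates before fitting; `0` disables.
#' @param species,seed_id,tubercle_no,type_label,subgenus provenance fields
#'   copied into the record.
#' @return a one-row data.frame (a tubercle record) with the provenance
#'   columns, `W`, `H`, `S`, `kmax`, `kmean`, `ratio` and the fit residual
#'   RMS `rms`.
#' @examples
#' prof <- make_profile(bump_spec("rounded", W = 87, H = 15, noise_sd = 0))
#' analyze_tubercle(prof, species = "example")[, c("W", "H", "S")]
#' @export
analyze_tubercle <- function(profile, degree = 5, n_samples = 200,
                             smooth_window = 3,
                             species = NA_character_, seed_id = NA_character_,
                             tubercle_no = NA_integer_,
                             type_label = NA_character_,
                             subgenus = NA_character_) {
  if (!inherits(profile, "tubercle_profile")) {
    profile <- segment_tubercle(profile)
  }
  wh <- measure_width_height(profile)
  P <- unclass_profile(profile)
  P[, 2] <- smooth_moving_average(P[, 2], smooth_window)
  fit <- bezier_fit(P, degree = degree)
  prof <- curvature_profile(fit, n_samples)
  kmax <- max_abs_curvature(prof)
  kmean <- mean_abs_curvature(prof)
  data.frame(species = species, seed_id = seed_id, tubercle_no = tubercle_no,
             type_label = type_label, subgenus = subgenus,
             W = unname(wh["W"]), H = unname(wh["H"]),
             S = unname(tubercle_slope(wh["W"], wh["H"])),
             kmax = kmax, kmean = kmean,
             ratio = curvature_ratio(kmax, kmean),
             rms = fit$rms)
}

#' Round a tubercle record for report parity
#'
#' Applies the reporting precision of the reference tables: `W` and `H` to
#' integers, `S`, curvatures and the ratio to one decimal.
#'
#' @param records a data.frame of tubercle records.
#' @return the rounded data.frame.
#' @export
round_records <- function(records) {
  for (v in c("W", "H")) {
    if (v %in% names(records)) records[[v]] <- round(records[[v]])
  }
  for (v in c("S", "kmax", "kmean", "ratio")) {
    if (v %in% names(records)) records[[v]] <- round(records[[v]], 1)
  }
  records
}
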