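#' Specification of one synthetic tubercle bump
#'
#' Parameterizes the profile shapes the generator can draw, emulating the
#' tubercle morphologies seen on *Silene* seed coats:
#'
#' * `"rounded"` — a raised-cosine bump, the rugose morphology (wide, low,
#'   low curvature). Class defaults W = 83.3, H = 20.7 microns (the pooled
#'   rugose means).
#' * `"acute"` — a triangular bump with the apex smoothed at corner radius
#'   W/20, the echinate morphology (narrow, tall, sharply peaked). Class
#'   defaults W = 72.0, H = 43.6 microns (the pooled echinate means).
#' * `"compound"` — a rounded bump carrying a smaller off-center secondary
#'   excrescence of amplitude `secondary_amp`.
#' * `"arc"` — a circular arc of radius `arc_radius` (120 degree span),
#'   the constant-curvature control shape: downstream mean curvature is
#'   1000 / `arc_radius`.
#'
#' @param shape one of `"rounded"`, `"acute"`, `"compound"`, `"arc"`.
#' @param W,H base width and height in microns (ignored for `"arc"`).
#' @param noise_sd standard deviation of additive Gaussian y-noise
#'   (microns); about sub-pixel at typical stereomicroscope image scales.
#' @param secondary_amp amplitude of the secondary bump (`"compound"` only).
#' @param arc_radius circle radius in microns (`"arc"` only).
#' @param seed integer seed making the noise realization reproducible.
#' @return an object of class `"bump_spec"`.
#' @export
bump_spec <- function(shape = c("rounded", "acute", "compound", "arc"),
                      W = NULL, H = NULL, noise_sd = 0.5,
                      secondary_amp = NULL, arc_radius = 50, seed = 1L) {
  shape <- match.arg(shape)
  defaults <- switch(shape,
    rounded = c(W = 83.3, H = 20.7),
    acute = c(W = 72.0, H = 43.6),
    compound = c(W = 83.3, H = 20.7),
    arc = c(W = NA_real_, H = NA_real_)
  )
  if (is.null(W)) W <- unname(defaults["W"])
  if (is.null(H)) H <- unname(defaults["H"])
  if (shape != "arc" && (W <= 0 || H <= 0)) stop("W and H must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (shape == "compound" && is.null(secondary_amp)) secondary_amp <- H / 3
  if (shape == "arc" && arc_radius <= 0) stop("arc_radius must be positive")
  structure(list(shape = shape, W = W, H = H, noise_sd = noise_sd,
                 secondary_amp = secondary_amp, arc_radius = arc_radius,
                 seed = as.integer(seed)),
            class = "bump_spec")
}

# evaluate the seed before restoring, or lazy evaluation escapes the scope
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate one synthetic tubercle profile
#'
#' Samples the shape described by a [bump_spec()] at `n_points` abscissae and
#' adds the specified Gaussian y-noise under the spec's seed (the global RNG
#' state is left untouched). The profile is apex-up with its base on y = 0.
#'
#' @param spec a `"bump_spec"`.
#' @param n_points number of profile points (>= 30); the default matches the
#'   column count of a typical tubercle crop at stereomicroscope image
#'   scales.
#' @return a `"tubercle_profile"` (see [segment_tubercle()]).
#' @examples
#' prof <- make_profile(bump_spec("arc", arc_radius = 50, noise_sd = 0))
#' analyze_tubercle(prof)$kmean # ~ 20
#' @export
make_profile <- function(spec, n_points = 100) {
  stopifnot(inherits(spec, "bump_spec"))
  n_points <- as.integer(n_points)
  if (n_points < 30L) stop("n_points must be at least 30")
  W <- spec$W; H <- spec$H
  if (spec$shape == "arc") {
    th <- seq(-pi / 3, pi / 3, length.out = n_points)
    x <- spec$arc_radius * (sin(th) + sin(pi / 3))
    y <- spec$arc_radius * (cos(th) - cos(pi / 3))
  } else {
    x <- seq(0, W, length.out = n_points)
    y <- switch(spec$shape,
      rounded = raised_cosine(x, W, H),
      acute = smoothed_triangle(x, W, H),
      compound = raised_cosine(x, W, H) +
        raised_cosine(x - 0.7 * W + W / 6, W / 3, spec$secondary_amp)
    )
  }
  if (spec$noise_sd > 0) {
    y <- y + with_seed(spec$seed, stats::rnorm(n_points, 0, spec$noise_sd))
  }
  segment_tubercle(cbind(x = x, y = y))
}

raised_cosine <- function(x, W, H) {
  ifelse(x >= 0 & x <= W, H / 2 * (1 + cos(2 * pi * (x / W - 0.5))), 0)
}

# triangle bump of base width W and apex height H, the apex blended by a
# parabola of curvature radius r = W/20 tangent to both flanks. The flank
# slope m solves m^2 r/2 - m W/2 + H = 0 so that the flanks meet y = 0 at
# the base corners while the cap peaks at exactly H; for spikes too steep
# to fit that cap the plain triangle slope is used and the bump rescaled.
smoothed_triangle <- function(x, W, H, r = W / 20) {
  u <- abs(x - W / 2)
  disc <- W^2 / 4 - 2 * r * H
  if (disc > 0) {
    m <- (W / 2 - sqrt(disc)) / r
    ifelse(u >= m * r, pmax(0, m * (W / 2 - u)), H - u^2 / (2 * r))
  } else {
    m <- 2 * H / W
    y <- ifelse(u >= m * r,
                pmax(0, H + m^2 * r / 2 - m * u),
                H - u^2 / (2 * r))
    pmax(0, y - m^2 * r / 2) * H / (H - m^2 * r / 2)
  }
}

#' Generate a labeled multi-species synthetic dataset
#'
#' Draws per-tubercle (W, H) parameters from log-normal distributions around
#' each species' class means (positivity plus the CV ranges typical of the
#' reference tables) and generates one profile per tubercle. The default
#' design is one rugose and one echinate species at the pooled reference
#' class means and CVs, so the simulated group contrasts reproduce the
#' published sign pattern: wider tubercles in the rugose group, larger
#' values of the other variables in the echinate group.
#'
#' @param species data.frame with columns `species`, `type` (`"rugose"` maps
#'   to rounded bumps, `"echinate"` to acute), `subgenus`, `n_tubercles`,
#'   `W_mean`, `W_cv`, `H_mean`, `H_cv` (CVs in percent). Default: the
#'   two-class pooled design.
#' @param noise_sd Gaussian y-noise sd in microns.
#' @param n_points profile points per tubercle.
#' @param seed global seed; the same seed reproduces the dataset exactly.
#' @return a list with `profiles` (list of `"tubercle_profile"`) and
#'   `labels` (data.frame with `species`, `type`, `subgenus`, `seed_id`,
#'   `tubercle_no`, and the drawn `W_true`, `H_true`).
#' @export
make_species_dataset <- function(species = default_species_design(),
                                 noise_sd = 0.5, n_points = 100, seed = 1L) {
  req <- c("species", "type", "n_tubercles", "W_mean", "W_cv", "H_mean", "H_cv")
  if (!all(req %in% names(species))) {
    stop("species design needs columns: ", paste(req, collapse = ", "))
  }
  if (!"subgenus" %in% names(species)) species$subgenus <- NA_character_
  with_seed(seed, {
    profiles <- list()
    labels <- NULL
    for (s in seq_len(nrow(species))) {
      row <- species[s, ]
      n <- row$n_tubercles
      Wd <- rlnorm_mean_cv(n, row$W_mean, row$W_cv / 100)
      Hd <- rlnorm_mean_cv(n, row$H_mean, row$H_cv / 100)
      shape <- if (row$type == "echinate") "acute" else "rounded"
      for (i in seq_len(n)) {
        spec <- bump_spec(shape, W = Wd[i], H = Hd[i], noise_sd = noise_sd,
                          seed = sample.int(.Machine$integer.max, 1L))
        profiles[[length(profiles) + 1L]] <- make_profile(spec, n_points)
        labels <- rbind(labels, data.frame(
          species = row$species, type = row$type, subgenus = row$subgenus,
          seed_id = paste0(row$species, "_seed1"), tubercle_no = i,
          W_true = Wd[i], H_true = Hd[i]))
      }
    }
    list(profiles = profiles, labels = labels)
  })
}

#' @rdname make_species_dataset
#' @export
default_species_design <- function() {
  data.frame(
    species = c("synthetic rugose sp.", "synthetic echinate sp."),
    type = c("rugose", "echinate"),
    subgenus = c("Silene", "Behenantha"),
    n_tubercles = c(50L, 50L),
    W_mean = c(83.3, 72.0), W_cv = c(24.8, 23.1),
    H_mean = c(20.7, 43.6), H_cv = c(35.5, 49.7)
  )
}

# log-normal with given arithmetic mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
}

#' Measure every profile of a synthetic dataset
#'
#' Convenience wrapper running [analyze_tubercle()] over the profiles of a
#' [make_species_dataset()] result, carrying the labels through.
#'
#' @param dataset list with `profiles` and `labels`.
#' @param ... passed to [analyze_tubercle()].
#' @return a data.frame of tubercle records.
#' @export
measure_dataset <- function(dataset, ...) {
  rows <- lapply(seq_along(dataset$profiles), function(i) {
    lab <- dataset$labels[i, ]
    analyze_tubercle(dataset$profiles[[i]], species = lab$species,
                     seed_id = lab$seed_id, tubercle_no = lab$tubercle_no,
                     type_label = lab$type, subgenus = lab$subgenus, ...)
  })
  do.call(rbind, rows)
}

#' Render a tubercle profile into a calibrated 8-bit image
#'
#' Draws the filled region under the profile as foreground (255) on a black
#' canvas, together with a horizontal ruler bar of known physical length in
#' a reserved bottom-left corner, and returns the ground truth needed for
#' round-trip tests (scale, base pixel positions, drawn area, ruler pixel
#' length).
#'
#' @param profile a `"tubercle_profile"` or two-column matrix (microns).
#' @param microns_per_pixel rendering scale.
#' @param ruler_length physical ruler length in microns.
#' @param margin margin around the bump, in pixels.
#' @return a `"calibrated_image"` with attribute `ground_truth` (list with
#'   `microns_per_pixel`, `base_px`, `ruler_px`, `drawn_area_px`,
#'   `profile`).
#' @export
render_profile_image <- function(profile, microns_per_pixel = 1,
                                 ruler_length = 100, margin = 20) {
  P <- unclass_profile(profile)
  wpx <- ceiling(diff(range(P[, 1])) / microns_per_pixel)
  hpx <- ceiling(max(P[, 2]) / microns_per_pixel)
  ruler_px <- round(ruler_length / microns_per_pixel)
  ruler_room <- 12L # reserved rows under the bump for the ruler bar
  width <- max(wpx + 2 * margin, ruler_px + 2 * margin)
  height <- hpx + 2 * margin + ruler_room
  if (width > 8192 || height > 8192) {
    stop("profile exceeds the rendering canvas at this scale")
  }
  img <- matrix(0, nrow = height, ncol = width)
  x0 <- margin # bump base starts at this 0-based column
  base_row <- height - margin - ruler_room # 1-based row of the base line
  # fill columns under the linearly interpolated profile
  cols <- seq(0, wpx)
  ycol <- stats::approx(P[, 1], P[, 2], xout = cols * microns_per_pixel,
                        rule = 2)$y
  area <- 0L
  for (i in seq_along(cols)) {
    # noise can dip a re-zeroed profile slightly below its base line;
    # nothing is drawn above the base there beyond the base pixel itself
    npix <- max(0L, floor(ycol[i] / microns_per_pixel + 0.5))
    rows <- (base_row - npix):base_row
    img[rows, x0 + cols[i] + 1L] <- 255
    area <- area + length(rows)
  }
  # ruler bar: 3 px tall, bottom-left corner
  img[(height - 4L):(height - 2L), (margin + 1L):(margin + ruler_px)] <- 255
  out <- calibrated_image(img, microns_per_pixel, source = "synthetic")
  attr(out, "ground_truth") <- list(
    microns_per_pixel = microns_per_pixel,
    base_px = c(left = x0, right = x0 + wpx), # 0-based columns
    base_row = base_row,
    ruler_px = ruler_px, ruler_length = ruler_length,
    drawn_area_px = area + 3L * ruler_px,
    profile = P
  )
  out
}
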