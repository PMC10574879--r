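#' Scale calibration from a ruler of known physical length
#'
#' Converts the measured pixel length of an in-image ruler (typically a 1 mm
#' bar) into a microns-per-pixel factor.
#'
#' @param ruler_pixel_length length of the ruler in pixels.
#' @param ruler_physical_length physical ruler length in microns
#'   (default 1000, i.e. 1 mm).
#' @return microns per pixel (scalar).
#' @examples
#' calibrate_scale(2560, 1000) # 0.390625
#' @export
calibrate_scale <- function(ruler_pixel_length, ruler_physical_length = 1000) {
  if (ruler_pixel_length <= 0 || ruler_physical_length <= 0) {
    stop("ruler lengths must be positive")
  }
  ruler_physical_length / ruler_pixel_length
}

#' Calibrated 8-bit grayscale image
#'
#' Wraps an 8-bit grayscale pixel matrix (rows are image rows, top first;
#' values 0-255) together with its spatial calibration.
#'
#' @param pixels numeric matrix of gray levels in `[0, 255]`, rows top-down.
#' @param microns_per_pixel positive calibration factor.
#' @param source provenance string (e.g. a file name).
#' @return an object of class `"calibrated_image"`.
#' @export
calibrated_image <- function(pixels, microns_per_pixel, source = "") {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("image must be nonempty")
  if (microns_per_pixel <= 0) stop("microns_per_pixel must be positive")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel,
                 source = source),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("Calibrated image %d x %d px, %.4g micron/px",
              ncol(x$pixels), nrow(x$pixels), x$microns_per_pixel))
  if (nzchar(x$source)) cat(" [", x$source, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Read a seed image and attach its calibration
#'
#' Reads JPEG/PNG/TIFF through EBImage, converts RGB to 8-bit grayscale by
#' channel averaging, and returns a [calibrated_image()].
#'
#' @param path image file path.
#' @param microns_per_pixel calibration, e.g. from [calibrate_scale()].
#' @return a `"calibrated_image"`.
#' @export
read_seed_image <- function(path, microns_per_pixel) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) dat <- apply(dat, c(1, 2), mean)
  # EBImage stores [x, y] with y down; convert to rows-top-down matrix
  pixels <- round(255 * t(dat))
  calibrated_image(pixels, microns_per_pixel, source = basename(path))
}

#' Threshold a calibrated image to a foreground mask
#'
#' @param image a `"calibrated_image"` (or bare 0-255 matrix).
#' @param threshold a gray level in `[0, 255]`, or `"otsu"` for Otsu's
#'   method. Pixels at or above the threshold are foreground.
#' @return a logical matrix (same layout as the pixels) with at least one
#'   foreground pixel; an empty foreground is an error.
#' @export
binarize <- function(image, threshold = "otsu") {
  pixels <- if (inherits(image, "calibrated_image")) image$pixels else
    as.matrix(image)
  if (identical(threshold, "otsu")) {
    threshold <- 255 * EBImage::otsu(EBImage::Image(t(pixels) / 255),
                                     range = c(0, 1))
    # otsu returns the level below foreground; keep the >= convention
    threshold <- threshold + .Machine$double.eps * 255
  } else {
    if (!is.numeric(threshold) || threshold < 0 || threshold > 255) {
      stop("threshold must be in [0, 255] or \"otsu\"")
    }
  }
  mask <- pixels >= threshold
  if (!any(mask)) stop("empty foreground after thresholding")
  mask
}

#' Trace ordered outlines of mask components
#'
#' Labels the connected components of a foreground mask and returns each
#' component's ordered boundary as an outline segment, largest component
#' first. Coordinates are pixel centers with 0-based columns, and the y axis
#' is flipped so that y increases upward (apex-up convention for vertically
#' oriented tubercles).
#'
#' @param mask logical matrix from [binarize()].
#' @return a list of `"outline_segment"` matrices with columns `x`, `y`.
#' @export
trace_outline <- function(mask) {
  if (!any(mask)) stop("mask has no foreground component")
  lab <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  contours <- EBImage::ocontour(lab)
  sizes <- tabulate(as.integer(EBImage::imageData(lab)))
  ord <- order(sizes, decreasing = TRUE)
  lapply(ord, function(i) {
    xy <- contours[[i]]
    out <- cbind(x = xy[, 1], y = (nrow(mask) - 1L) - xy[, 2])
    class(out) <- c("outline_segment", class(out))
    out
  })
}

#' Extract a single-valued line-graph profile from an outline
#'
#' Emulates the line-graph reading of a thresholded tubercle image: for each
#' pixel column crossed by the boundary, the topmost boundary pixel is taken,
#' yielding a single-valued profile y(x). Overhangs are therefore lost (a
#' message is emitted when columns carry multiple well-separated boundary
#' pixels). Coordinates are converted to microns.
#'
#' @param segment an `"outline_segment"` from [trace_outline()] (apex-up
#'   pixel coordinates).
#' @param microns_per_pixel calibration factor.
#' @param smooth_window odd moving-average window (pixels) applied to the
#'   profile ordinates; `0` disables smoothing.
#' @return a two-column matrix (`x`, `y`, microns) sorted by `x`.
#' @export
extract_profile <- function(segment, microns_per_pixel = 1,
                            smooth_window = 0) {
  xs <- segment[, 1]
  ys <- segment[, 2]
  cols <- sort(unique(xs))
  if (length(cols) < 20L) {
    stop("fewer than 20 usable columns (", length(cols),
         "); profile too short or degenerate")
  }
  top <- vapply(cols, function(cx) max(ys[xs == cx]), numeric(1))
  runs <- vapply(cols, function(cx) {
    yy <- sort(unique(ys[xs == cx]))
    1L + sum(diff(yy) > 1L)
  }, integer(1))
  if (any(runs > 2L)) {
    message("overhanging columns found; keeping the topmost boundary pixel")
  }
  y <- smooth_moving_average(top, smooth_window)
  cbind(x = cols * microns_per_pixel, y = y * microns_per_pixel)
}

smooth_moving_average <- function(y, window) {
  if (window <= 1) return(y)
  if (window %% 2 == 0) stop("smooth_window must be odd")
  half <- (window - 1) / 2
  n <- length(y)
  out <- y
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    out[i] <- mean(y[j])
  }
  out
}

#' Crop a profile to one tubercle and re-zero it on its base line
#'
#' Crops a single-valued profile between two base abscissae and subtracts the
#' base line through the two base points, so that the tubercle sits on y = 0
#' between x = 0 and x = `right_base - left_base` plus the base-line tilt.
#'
#' @param profile two-column matrix (`x`, `y`, microns), e.g. from
#'   [extract_profile()] or [make_profile()].
#' @param left_base,right_base base abscissae in microns,
#'   `left_base < right_base`, both within the profile span.
#' @return an object of class `"tubercle_profile"`: the cropped points with
#'   attributes `base` (the two base points, original coordinates) and
#'   `baseline_tilt`.
#' @export
segment_tubercle <- function(profile, left_base = NULL, right_base = NULL) {
  P <- as_planar_points(profile)
  if (is.null(left_base)) left_base <- min(P[, 1])
  if (is.null(right_base)) right_base <- max(P[, 1])
  if (left_base >= right_base) stop("left_base must be smaller than right_base")
  if (left_base < min(P[, 1]) - 1e-9 || right_base > max(P[, 1]) + 1e-9) {
    stop("base bounds fall outside the profile span")
  }
  yl <- stats::approx(P[, 1], P[, 2], xout = left_base)$y
  yr <- stats::approx(P[, 1], P[, 2], xout = right_base)$y
  keep <- P[, 1] >= left_base & P[, 1] <= right_base
  Q <- P[keep, , drop = FALSE]
  if (abs(Q[1, 1] - left_base) > 1e-9) Q <- rbind(c(left_base, yl), Q)
  if (abs(Q[nrow(Q), 1] - right_base) > 1e-9) Q <- rbind(Q, c(right_base, yr))
  slope <- (yr - yl) / (right_base - left_base)
  out <- cbind(x = Q[, 1] - left_base,
               y = Q[, 2] - (yl + slope * (Q[, 1] - left_base)))
  structure(out, class = c("tubercle_profile", class(out)),
            base = rbind(c(left_base, yl), c(right_base, yr)),
            baseline_tilt = slope)
}

#' Read and write tubercle coordinate files
#'
#' Coordinate CSVs carry the columns `x_micron`, `y_micron` and connect the
#' image-extraction stage to the curve-fitting stage.
#'
#' @param profile two-column matrix in microns.
#' @param path CSV file path.
#' @return `write_profile_csv()` returns `path` invisibly;
#'   `read_profile_csv()` returns a two-column matrix.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(x_micron = profile[, 1],
                              y_micron = profile[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x_micron", "y_micron") %in% names(d))) {
    stop("coordinate file must have columns x_micron, y_micron: ", path)
  }
  cbind(x = d$x_micron, y = d$y_micron)
}
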