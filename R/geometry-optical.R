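# Optical method: pixel-calibrated layer heights in a tube image, and
# conversion of heights to cylinder volumes.

#' Tube geometry
#'
#' Geometry of the reaction tube: a vertical cylinder holding a sebum
#' column under the applied solution. Defaults are a 16 mm diameter tube
#' (radius 8 mm) with a 20 mm sebum column.
#'
#' @param radius_mm Inner tube radius, mm (> 0).
#' @param sebum_column_height_mm Initial height of the sebum column, mm
#'   (>= 0).
#' @return An object of class `tube_geometry`.
#' @export
tube_geometry <- function(radius_mm = 8.0, sebum_column_height_mm = 20.0) {
  stopifnot(is.numeric(radius_mm), is.numeric(sebum_column_height_mm))
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("radius_mm must be positive")
  if (!is.finite(sebum_column_height_mm) || sebum_column_height_mm < 0)
    stop("sebum_column_height_mm must be non-negative")
  structure(list(radius_mm = radius_mm,
                 sebum_column_height_mm = sebum_column_height_mm),
            class = "tube_geometry")
}

#' Pixel calibration
#'
#' Conversion between image pixels and millimetres. The default of
#' 50 px/mm corresponds to a fifty-fold on-screen magnification with a
#' measurement accuracy of 0.02 mm (one pixel).
#'
#' @param pixels_per_mm Pixels per millimetre (> 0).
#' @return An object of class `pixel_calibration`.
#' @export
pixel_calibration <- function(pixels_per_mm = 50.0) {
  if (!is.numeric(pixels_per_mm) || !is.finite(pixels_per_mm) ||
      pixels_per_mm <= 0)
    stop("pixels_per_mm must be positive")
  structure(list(pixels_per_mm = pixels_per_mm), class = "pixel_calibration")
}

#' Layer heights measured from a tube image
#'
#' `penetration_depth_mm` is the depth the reacted (etched) layer extends
#' below the initial sebum level; `increase_height_mm` is the height of
#' reaction products risen above that level.
#'
#' @param penetration_depth_mm Penetration depth, mm (>= 0).
#' @param increase_height_mm Increase height, mm (>= 0).
#' @param flag Optional character flag (e.g. `"no_reacted_band"`).
#' @return An object of class `layer_heights`.
#' @export
layer_heights <- function(penetration_depth_mm, increase_height_mm,
                          flag = NULL) {
  stopifnot(is.numeric(penetration_depth_mm), is.numeric(increase_height_mm))
  if (penetration_depth_mm < 0 || increase_height_mm < 0)
    stop("layer heights must be non-negative")
  structure(list(penetration_depth_mm = penetration_depth_mm,
                 increase_height_mm = increase_height_mm,
                 flag = flag),
            class = "layer_heights")
}

#' In-memory grayscale tube image
#'
#' A stand-in for a digital macro photograph of the tube: an integer
#' matrix of 0-255 intensities (row 1 at the top), together with the pixel
#' row of the initial sebum level and a pixel calibration.
#'
#' @param intensities Numeric matrix, values in [0, 255].
#' @param baseline_row Row index of the initial sebum surface (within the
#'   image).
#' @param calibration A [pixel_calibration()].
#' @return An object of class `tube_image`.
#' @export
tube_image <- function(intensities, baseline_row,
                       calibration = pixel_calibration()) {
  stopifnot(is.matrix(intensities), is.numeric(intensities))
  if (any(!is.finite(intensities)) ||
      any(intensities < 0) || any(intensities > 255))
    stop("intensities must lie in [0, 255]")
  if (baseline_row < 1 || baseline_row > nrow(intensities))
    stop("baseline_row outside the image")
  if (!inherits(calibration, "pixel_calibration"))
    stop("calibration must be a pixel_calibration object")
  structure(list(intensities = intensities,
                 baseline_row = as.integer(baseline_row),
                 calibration = calibration),
            class = "tube_image")
}

#' Cylinder volume from a column height
#'
#' \deqn{V = \pi r^2 h}
#'
#' @param h Height(s) in mm (>= 0).
#' @param geometry A [tube_geometry()] supplying the radius.
#' @return Volume(s) in mm^3.
#' @examples
#' cylinder_volume(1, tube_geometry())  # pi * 64
#' @export
cylinder_volume <- function(h, geometry = tube_geometry()) {
  stopifnot(is.numeric(h), inherits(geometry, "tube_geometry"))
  if (any(!is.finite(h)) || any(h < 0)) stop("h must be non-negative")
  pi * geometry$radius_mm^2 * h
}

#' Convert pixel counts to millimetres
#'
#' `mm = pixels / pixels_per_mm`; with the default 50 px/mm one pixel is
#' 0.02 mm, the resolution limit of the optical measurement.
#'
#' @param pixel_counts Non-negative pixel counts (vectorized).
#' @param calibration A [pixel_calibration()].
#' @return Heights in mm.
#' @export
heights_from_pixels <- function(pixel_counts,
                                calibration = pixel_calibration()) {
  stopifnot(is.numeric(pixel_counts),
            inherits(calibration, "pixel_calibration"))
  if (any(!is.finite(pixel_counts)) || any(pixel_counts < 0))
    stop("pixel counts must be non-negative")
  pixel_counts / calibration$pixels_per_mm
}

# Classify one intensity into the three optical zones.
.classify_zone <- function(x, dark_below = 60, bright_above = 180) {
  ifelse(x < dark_below, "sebum",
         ifelse(x > bright_above, "reacted", "solution"))
}

#' Measure layer heights from a tube image
#'
#' The image is expected to show three vertically stacked zones: solution
#' (intermediate intensity, possibly noisy) on top, a bright reacted band
#' around the initial sebum level, and dark intact sebum below. For each
#' column the band boundaries are found by scanning from the baseline row:
#' downwards to the first dark pixel (penetration depth) and upwards to the
#' first solution-class pixel (increase height). Per-column pixel counts
#' are aggregated by the median across columns (robust to meniscus and
#' wall artifacts, ties broken toward the baseline by taking the
#' lower median) and converted to mm through the calibration as the final
#' step, so rounding happens exactly once.
#'
#' @param image A [tube_image()].
#' @param dark_below Intensity threshold below which a pixel is intact
#'   sebum (default 60).
#' @param bright_above Intensity threshold above which a pixel is reacted
#'   layer (default 180).
#' @return A [layer_heights()] object; when no reacted band is present at
#'   the baseline the heights are zero and `flag = "no_reacted_band"`.
#' @export
measure_layer_heights <- function(image, dark_below = 60,
                                  bright_above = 180) {
  stopifnot(inherits(image, "tube_image"))
  img <- image$intensities
  b <- image$baseline_row
  nr <- nrow(img)
  nc <- ncol(img)

  pen_px <- integer(nc)
  inc_px <- integer(nc)
  band_seen <- logical(nc)

  for (j in seq_len(nc)) {
    col <- img[, j]
    zones <- .classify_zone(col, dark_below, bright_above)
    # zone ordering check: collapsed runs must follow solution->reacted->sebum
    runs <- rle(zones)$values
    allowed <- c("solution", "reacted", "sebum")
    if (any(diff(match(runs, allowed)) < 0))
      stop("non-monotone zone ordering in column ", j)

    at_b <- zones[b] == "reacted"
    above_b <- b > 1 && zones[b - 1L] == "reacted"
    band_seen[j] <- at_b || above_b
    if (!band_seen[j]) next

    if (at_b) {
      r <- b
      while (r <= nr && zones[r] == "reacted") r <- r + 1L
      pen_px[j] <- r - b
    }
    if (above_b) {
      r <- b - 1L
      while (r >= 1L && zones[r] == "reacted") r <- r - 1L
      inc_px[j] <- b - 1L - r
    }
  }

  if (!any(band_seen))
    return(layer_heights(0, 0, flag = "no_reacted_band"))

  # lower median: ties and even counts resolve toward the baseline
  lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]
  layer_heights(
    heights_from_pixels(lower_median(pen_px[band_seen]), image$calibration),
    heights_from_pixels(lower_median(inc_px[band_seen]), image$calibration)
  )
}

#' Convert measured layer heights to penetrated and increased volumes
#'
#' Applies [cylinder_volume()] to the penetration depth and the increase
#' height.
#'
#' @param heights A [layer_heights()] object.
#' @param geometry A [tube_geometry()].
#' @return Named numeric vector with `v_penetrated_mm3` and
#'   `v_increased_mm3`.
#' @examples
#' heights_to_volumes(layer_heights(1.03, 0))  # ~207 mm^3 penetrated
#' @export
heights_to_volumes <- function(heights, geometry = tube_geometry()) {
  stopifnot(inherits(heights, "layer_heights"),
            inherits(geometry, "tube_geometry"))
  c(v_penetrated_mm3 = cylinder_volume(heights$penetration_depth_mm, geometry),
    v_increased_mm3 = cylinder_volume(heights$increase_height_mm, geometry))
}
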