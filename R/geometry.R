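#' Screen geometry for an eye-tracking setup
#'
#' Describes the display on which the pursuit stimulus is shown: pixel
#' resolution, physical diagonal and viewing distance. The physical-to-pixel
#' scale assumes square pixels, so one scale factor
#' `mm_per_px = diagonal_mm / sqrt(width_px^2 + height_px^2)` serves both axes.
#'
#' The default is the 14-inch laptop display used for the reference pursuit
#' task: 1366 x 768 pixels, 355.6 mm diagonal, viewed from 500 mm.
#'
#' @param width_px,height_px Display resolution in pixels (positive integers).
#' @param diagonal_mm Physical diagonal of the display area in millimetres.
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#'
#' @return An object of class `screen_geometry`: a list with the four fields
#'   plus the derived `mm_per_px` scale.
#' @export
#' @examples
#' geom <- screen_geometry()
#' geom$mm_per_px      # ~0.2269 mm per pixel
#' mm_to_px(5, geom)   # a 5 mm radius in pixels
screen_geometry <- function(width_px = 1366L, height_px = 768L,
                            diagonal_mm = 355.6, viewing_distance_mm = 500) {
  stopifnot(length(width_px) == 1L, length(height_px) == 1L,
            length(diagonal_mm) == 1L, length(viewing_distance_mm) == 1L)
  if (width_px <= 0 || height_px <= 0)
    stop("screen resolution must be positive", call. = FALSE)
  if (diagonal_mm <= 0)
    stop("'diagonal_mm' must be positive", call. = FALSE)
  if (viewing_distance_mm <= 0)
    stop("'viewing_distance_mm' must be positive", call. = FALSE)
  geom <- list(
    width_px = as.integer(width_px),
    height_px = as.integer(height_px),
    diagonal_mm = as.numeric(diagonal_mm),
    viewing_distance_mm = as.numeric(viewing_distance_mm),
    mm_per_px = diagonal_mm / sqrt(width_px^2 + height_px^2)
  )
  class(geom) <- "screen_geometry"
  geom
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, diagonal %.1f mm (%.5f mm/px), viewed at %.0f mm\n",
              x$width_px, x$height_px, x$diagonal_mm, x$mm_per_px,
              x$viewing_distance_mm))
  invisible(x)
}

#' Convert between millimetres and pixels
#'
#' Lengths on the stimulus screen can be stated physically (ball radii in mm)
#' or in device units (pixels). Conversion uses the square-pixel scale of a
#' [screen_geometry()]. `mm_to_px()` and `px_to_mm()` are exact inverses.
#'
#' @param length_mm,length_px Non-negative length to convert.
#' @param geometry A [screen_geometry()].
#' @return The converted length (real-valued; pixel lengths are not rounded).
#' @export
#' @examples
#' mm_to_px(5, screen_geometry())   # ~22.03 px
mm_to_px <- function(length_mm, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (any(length_mm < 0)) stop("length must be non-negative", call. = FALSE)
  length_mm / geometry$mm_per_px
}

#' @rdname mm_to_px
#' @export
px_to_mm <- function(length_px, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (any(length_px < 0)) stop("length must be non-negative", call. = FALSE)
  length_px * geometry$mm_per_px
}

# Round half away from zero (round() in R rounds half to even). Used when
# snapping positions to the pixel lattice and when comparing against printed
# 2-decimal tables.
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
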