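#' Shadow-projection geometry
#'
#' The geometry underlying depth from cast shadows on a frontoparallel
#' background: an object at separation `d` (degrees of visual angle, dva)
#' from the background, lit from a direction with slant `sigma` away from
#' the surface normal, casts a shadow displaced by `o = d * tan(sigma)`.
#' Knowing any two of offset, depth and slant recovers the third.
#'
#' All angles are in degrees; all retinal sizes in dva.
#'
#' @name shadow-geometry
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Illumination direction
#'
#' @param slant Degrees away from the surface normal, in `[0, 90)`.
#'   0 is light from the observer's direction, 90 would graze the surface.
#' @param tilt Degrees of rotation around the surface normal; normalized
#'   to `[0, 360)`. The tilt is opposite the direction of the shadow offset.
#' @return An object of class `"light_direction"`.
#' @export
light_direction <- function(slant, tilt = 0) {
  stopifnot(is.numeric(slant), is.numeric(tilt), length(slant) == 1L,
            length(tilt) == 1L, is.finite(slant), is.finite(tilt))
  if (slant < 0 || slant >= 90)
    stop("'slant' must lie in [0, 90) degrees", call. = FALSE)
  structure(list(slant = slant, tilt = tilt %% 360),
            class = "light_direction")
}

#' Display geometry for pixel/visual-angle conversion
#'
#' Defaults are a CRT showing 800 x 600 pixels over 26.6 x 20 cm viewed
#' from 100 cm; pixels are assumed square, with the pitch taken as
#' width / horizontal resolution.
#'
#' @param resolution_px Integer vector `c(horizontal, vertical)` pixels.
#' @param physical_size_cm Numeric `c(width, height)` in cm.
#' @param viewing_distance_cm Eye-to-screen distance in cm.
#' @return An object of class `"display_geometry"`.
#' @export
display_geometry <- function(resolution_px = c(800, 600),
                             physical_size_cm = c(26.6, 20),
                             viewing_distance_cm = 100) {
  stopifnot(length(resolution_px) == 2L, length(physical_size_cm) == 2L,
            length(viewing_distance_cm) == 1L,
            all(resolution_px > 0), all(physical_size_cm > 0),
            viewing_distance_cm > 0)
  structure(list(resolution_px = as.numeric(resolution_px),
                 physical_size_cm = as.numeric(physical_size_cm),
                 viewing_distance_cm = as.numeric(viewing_distance_cm)),
            class = "display_geometry")
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf("Display: %d x %d px over %.1f x %.1f cm at %.0f cm\n",
              x$resolution_px[1], x$resolution_px[2],
              x$physical_size_cm[1], x$physical_size_cm[2],
              x$viewing_distance_cm))
  invisible(x)
}

#' Shadow observation and scene configuration
#'
#' Lightweight validated records: `shadow_observation()` holds what is
#' measurable in the image (offset, diagonal direction, penumbra width),
#' `scene_config()` holds the scene parameters (object-background depth and
#' the angular extent of the light source).
#'
#' @param offset Shadow offset in dva, `>= 0`.
#' @param direction One of `"upper-left"`, `"upper-right"`, `"lower-left"`,
#'   `"lower-right"`.
#' @param penumbra_width Width of the blur gradient at the shadow edge, dva.
#' @return A classed list.
#' @export
shadow_observation <- function(offset, direction = "lower-right",
                               penumbra_width = 0) {
  direction <- match.arg(direction, shadow_directions())
  stopifnot(is.numeric(offset), offset >= 0, penumbra_width >= 0)
  structure(list(offset = offset, direction = direction,
                 penumbra_width = penumbra_width),
            class = "shadow_observation")
}

#' @rdname shadow_observation
#' @param depth Object-background separation in frontoparallel dva, `>= 0`.
#' @param source_extent Angular diameter of the light source, degrees.
#' @export
scene_config <- function(depth, source_extent = 0) {
  stopifnot(is.numeric(depth), depth >= 0, source_extent >= 0)
  structure(list(depth = depth, source_extent = source_extent),
            class = "scene_config")
}

#' The four diagonal shadow directions
#'
#' Screen convention: y grows downward; the light tilt is the shadow
#' direction plus 180 degrees, so the four diagonals map to tilts
#' 45, 135, 225 and 315 degrees.
#' @return Character vector of direction labels.
#' @export
shadow_directions <- function() {
  c("upper-left", "upper-right", "lower-left", "lower-right")
}

#' Convert between shadow offset, depth and illumination slant
#'
#' `offset_from_depth()` projects an object at separation `depth` lit at
#' `slant` degrees to a shadow offset `depth * tan(slant)`;
#' `depth_from_offset()` inverts it. `slant_from_slope()` converts a fitted
#' depth-versus-offset slope to the equivalent illumination slant,
#' `atan(1/slope)` in degrees; `slope_from_slant()` is its inverse,
#' `1/tan(slant)`.
#'
#' @param depth Object-background separation, dva, `>= 0`.
#' @param slant Illumination slant in degrees, in `[0, 90)`.
#' @return dva (offset or depth) or degrees (slant), as named.
#' @examples
#' offset_from_depth(1, 45)            # 1
#' depth_from_offset(0.7133, 35.5)     # ~1
#' slant_from_slope(1.40)              # ~35.5 degrees
#' @export
offset_from_depth <- function(depth, slant) {
  check_nonneg(depth, "depth")
  check_slant(slant, allow_zero = TRUE)
  depth * tan(deg2rad(slant))
}

#' @rdname offset_from_depth
#' @param offset Shadow offset, dva, `>= 0`.
#' @export
depth_from_offset <- function(offset, slant) {
  check_nonneg(offset, "offset")
  check_slant(slant, allow_zero = TRUE)
  if (any(slant == 0 & offset > 0))
    stop("slant 0 with a positive offset has no finite depth", call. = FALSE)
  out <- ifelse(offset == 0, 0, offset / tan(deg2rad(slant)))
  out
}

#' @rdname offset_from_depth
#' @param slope Depth/offset ratio, dimensionless, `> 0`.
#' @export
slant_from_slope <- function(slope) {
  if (any(!is.finite(slope)) || any(slope <= 0))
    stop("'slope' must be finite and > 0", call. = FALSE)
  rad2deg(atan(1 / slope))
}

#' @rdname offset_from_depth
#' @export
slope_from_slant <- function(slant) {
  check_slant(slant, allow_zero = FALSE)
  1 / tan(deg2rad(slant))
}

#' Penumbra width of a shadow cast by an extended source
#'
#' Leading-order umbra/penumbra geometry for a distant extended source:
#' the blur gradient at the shadow edge spans `depth * tan(source_extent)`.
#' A point source (`source_extent = 0`) casts a sharp shadow.
#'
#' @param depth Object-background separation, dva, `>= 0`.
#' @param source_extent Angular diameter of the light source, degrees,
#'   `>= 0` and `< 90`.
#' @return Penumbra width in dva.
#' @export
penumbra_width <- function(depth, source_extent) {
  check_nonneg(depth, "depth")
  check_nonneg(source_extent, "source_extent")
  if (any(source_extent >= 90))
    stop("'source_extent' must be < 90 degrees", call. = FALSE)
  depth * tan(deg2rad(source_extent))
}

#' Convert between pixels and degrees of visual angle
#'
#' Uses the full-angle formula `2 * atan(n * pitch / (2 * D))` with the
#' pixel pitch `width / horizontal resolution`, so large extents remain
#' correct; for small extents it agrees with the linear small-angle
#' approximation to well under 1%.
#'
#' @param pixels Extent in pixels, `>= 0`.
#' @param display A [display_geometry()].
#' @return `px_to_dva()`: dva; `dva_to_px()`: (fractional) pixels.
#' @examples
#' px_to_dva(13, display_geometry())   # ~0.25 dva
#' @export
px_to_dva <- function(pixels, display = display_geometry()) {
  check_nonneg(pixels, "pixels")
  stopifnot(inherits(display, "display_geometry"))
  pitch <- display$physical_size_cm[1] / display$resolution_px[1]
  rad2deg(2 * atan(pixels * pitch / (2 * display$viewing_distance_cm)))
}

#' @rdname px_to_dva
#' @param dva Extent in degrees of visual angle, `>= 0`.
#' @export
dva_to_px <- function(dva, display = display_geometry()) {
  check_nonneg(dva, "dva")
  stopifnot(inherits(display, "display_geometry"))
  pitch <- display$physical_size_cm[1] / display$resolution_px[1]
  2 * display$viewing_distance_cm * tan(deg2rad(dva) / 2) / pitch
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be finite and >= 0", name), call. = FALSE)
  invisible(x)
}

check_slant <- function(slant, allow_zero = TRUE) {
  if (any(!is.finite(slant)) || any(slant < 0) || any(slant >= 90))
    stop("'slant' must lie in [0, 90) degrees", call. = FALSE)
  if (!allow_zero && any(slant == 0))
    stop("'slant' must be strictly positive here", call. = FALSE)
  invisible(slant)
}
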