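#' Stimulus specification
#'
#' Describes one experiment image: a textured background, a central
#' textured square, and the square's shadow displaced by `shadow_offset_px`
#' and blurred by convolution with a disc kernel. The shadow attenuates
#' each background pixel by `attenuation` (default 50%), tapering to 0%
#' across the penumbra.
#'
#' The default texture cells (2 px background, 4 px square) correspond to
#' the 0.04 and 0.08 dva noise elements at the default display geometry,
#' where one pixel subtends about 0.019 dva.
#'
#' @param image_size_px `c(width, height)` of the image.
#' @param square_size_px Side of the central square, px.
#' @param shadow_offset_px `c(dx, dy)` signed displacement of the shadow,
#'   px; screen convention, y grows downward. The experiment's diagonal
#'   conditions use `|dx| == |dy|`.
#' @param blur_diameter_px Odd positive diameter of the blur disc, px;
#'   1 means a sharp (point-source) shadow.
#' @param attenuation Peak fractional luminance reduction inside the
#'   shadow, in `[0, 1]`.
#' @param background_cell_px,square_cell_px Texture element sizes, px.
#' @param background_level Mean background luminance (relative, `[0, 1]`).
#' @param background_contrast Half-range of the background noise levels.
#' @param square_levels The two luminance levels of the square's
#'   high-contrast check texture.
#' @param seed Integer seed for the background texture; the square's
#'   texture is held fixed across seeds, as in the experiment.
#' @return An object of class `"stimulus_spec"`.
#' @export
stimulus_spec <- function(image_size_px = c(256, 256),
                          square_size_px = 116,
                          shadow_offset_px = c(20, 20),
                          blur_diameter_px = 13,
                          attenuation = 0.5,
                          background_cell_px = 2,
                          square_cell_px = 4,
                          background_level = 0.55,
                          background_contrast = 0.06,
                          square_levels = c(0.12, 0.45),
                          seed = 1L) {
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 4),
            length(shadow_offset_px) == 2L,
            square_size_px >= 1,
            length(square_levels) == 2L)
  if (blur_diameter_px < 1 || blur_diameter_px %% 2 == 0)
    stop("'blur_diameter_px' must be an odd positive integer", call. = FALSE)
  if (attenuation < 0 || attenuation > 1)
    stop("'attenuation' must lie in [0, 1]", call. = FALSE)
  spec <- list(image_size_px = as.integer(image_size_px),
               square_size_px = as.integer(square_size_px),
               shadow_offset_px = as.integer(round(shadow_offset_px)),
               blur_diameter_px = as.integer(blur_diameter_px),
               attenuation = attenuation,
               background_cell_px = as.integer(background_cell_px),
               square_cell_px = as.integer(square_cell_px),
               background_level = background_level,
               background_contrast = background_contrast,
               square_levels = square_levels,
               seed = as.integer(seed))
  class(spec) <- "stimulus_spec"
  spec
}

# top-left (row, col) of the square footprint, 1-based
square_origin <- function(spec) {
  w <- spec$image_size_px[1]; h <- spec$image_size_px[2]
  s <- spec$square_size_px
  c(row = floor((h - s) / 2) + 1L, col = floor((w - s) / 2) + 1L)
}

square_footprint <- function(spec, shift = c(0L, 0L)) {
  h <- spec$image_size_px[2]; w <- spec$image_size_px[1]
  o <- square_origin(spec)
  s <- spec$square_size_px
  rows <- (o["row"] + shift[2]):(o["row"] + shift[2] + s - 1L)
  cols <- (o["col"] + shift[1]):(o["col"] + shift[1] + s - 1L)
  if (min(rows) < 1 || max(rows) > h || min(cols) < 1 || max(cols) > w)
    stop("square/shadow footprint falls outside the image", call. = FALSE)
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

#' Binary shadow mask of a stimulus
#'
#' The shadow region is the square's footprint translated by the shadow
#' offset, minus the square's own footprint (the square occludes its
#' shadow). For `|dx|, |dy| <= s` the visible L-shaped area is
#' `s^2 - (s - |dx|) (s - |dy|)` pixels.
#'
#' @param spec A [stimulus_spec()].
#' @return A `height x width` matrix of 0/1 values.
#' @export
make_shadow_mask <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  shadow <- square_footprint(spec, spec$shadow_offset_px)
  square <- square_footprint(spec)
  (shadow & !square) * 1
}

#' Disc blur kernel
#'
#' Normalized kernel of a blur circle of odd `diameter` pixels: a pixel
#' belongs to the disc iff its center lies within `diameter/2` of the
#' kernel center; entries sum to 1. Diameter 1 is the identity kernel.
#'
#' @param diameter Odd positive integer, px.
#' @return A `diameter x diameter` matrix summing to 1.
#' @export
disc_kernel <- function(diameter) {
  if (diameter < 1 || diameter %% 2 == 0)
    stop("'diameter' must be an odd positive integer", call. = FALSE)
  r <- (diameter - 1L) / 2L
  idx <- -r:r
  d2 <- outer(idx^2, idx^2, "+")
  k <- (d2 <= (diameter / 2)^2) * 1
  k / sum(k)
}

#' Blur a mask with a disc kernel
#'
#' Zero-padded 2-D convolution with [disc_kernel()]. Zero padding is
#' adequate here because experiment shadows sit in the image interior.
#' Diameter 1 returns the input unchanged.
#'
#' @param mask Numeric matrix with values in `[0, 1]`.
#' @param blur_diameter_px Odd positive kernel diameter, px.
#' @return Matrix of the same size, values in `[0, 1]`.
#' @export
blur_mask <- function(mask, blur_diameter_px) {
  stopifnot(is.matrix(mask))
  if (blur_diameter_px == 1) return(mask)
  k <- disc_kernel(blur_diameter_px)
  r <- (blur_diameter_px - 1L) / 2L
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(0, h + 2L * r, w + 2L * r)
  padded[(r + 1L):(r + h), (r + 1L):(r + w)] <- mask
  out <- matrix(0, h, w)
  nz <- which(k > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(nz))) {
    di <- nz[i, 1]; dj <- nz[i, 2]
    out <- out + k[di, dj] * padded[di:(di + h - 1L), dj:(dj + w - 1L)]
  }
  pmin(pmax(out, 0), 1)
}

# cell-grid noise texture: independent levels on cell_px x cell_px blocks
texture_grid <- function(h, w, cell_px, draw) {
  ch <- ceiling(h / cell_px); cw <- ceiling(w / cell_px)
  cells <- matrix(draw(ch * cw), ch, cw)
  expanded <- cells[rep(seq_len(ch), each = cell_px)[1:h],
                    rep(seq_len(cw), each = cell_px)[1:w], drop = FALSE]
  expanded
}

#' Render a shadow stimulus image
#'
#' Composites, in order: a fresh low-contrast background texture (from
#' `spec$seed`), the shadow (each background pixel multiplied by
#' `1 - attenuation * blurred_mask`), and finally the square with its
#' fixed high-contrast check texture, which occludes the shadow.
#' The square's texture is identical across seeds, mirroring the
#' experiment where only the background noise changed between trials.
#'
#' @param spec A [stimulus_spec()].
#' @return A `height x width` luminance matrix in `[0, 1]` with
#'   attributes `"square_mask"` and `"shadow_mask"` (binary matrices).
#' @export
render_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  h <- spec$image_size_px[2]; w <- spec$image_size_px[1]
  mask <- make_shadow_mask(spec)
  soft <- blur_mask(mask, spec$blur_diameter_px)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  set.seed(spec$seed)
  bg <- texture_grid(h, w, spec$background_cell_px, function(n)
    stats::runif(n, spec$background_level - spec$background_contrast,
                 spec$background_level + spec$background_contrast))
  img <- bg * (1 - spec$attenuation * soft)

  # square texture fixed across trials: dedicated constant seed
  set.seed(20210915L)
  sq_full <- texture_grid(h, w, spec$square_cell_px, function(n)
    sample(spec$square_levels, n, replace = TRUE))
  square <- square_footprint(spec) > 0
  img[square] <- sq_full[square]

  img <- pmin(pmax(img, 0), 1)
  attr(img, "square_mask") <- square * 1
  attr(img, "shadow_mask") <- mask
  img
}

#' Write an image matrix to a lossless PNG
#'
#' 8-bit grayscale by default; with `color = TRUE` the square region is
#' tinted cyan (its red channel suppressed) while all luminance values are
#' preserved, echoing the experiment's blue square. Reading the file back
#' reproduces values to within the 1/255 quantization step.
#'
#' @param image Luminance matrix in `[0, 1]`, e.g. from [render_stimulus()].
#' @param path Output file path.
#' @param color Tint the square region (requires the `"square_mask"`
#'   attribute set by [render_stimulus()]).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, color = FALSE) {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= 1))
  if (color) {
    sq <- attr(image, "square_mask")
    if (is.null(sq)) stop("no 'square_mask' attribute; render first",
                          call. = FALSE)
    arr <- array(as.numeric(image), c(nrow(image), ncol(image), 3))
    red <- arr[, , 1]
    red[sq > 0] <- red[sq > 0] * 0.25
    arr[, , 1] <- red
    png::writePNG(arr, path)
  } else {
    png::writePNG(matrix(as.numeric(image), nrow(image), ncol(image)), path)
  }
  invisible(path)
}
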