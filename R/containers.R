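#' @title Raster containers for section analysis
#' @description S3 containers shared across the pipeline: an RGB section
#'   image with physical pixel pitch, a binary mask, and a per-pixel tissue
#'   fraction image. All rasters are row-major with the origin at the
#'   top-left corner and 0-based pixel coordinates in the documentation
#'   (R matrices are 1-indexed internally).
#' @name containers
NULL

#' Construct a section image
#'
#' An RGB raster of a stained whole lung section together with its physical
#' pixel pitch in micrometres per pixel. Channel values are integers in
#' 0--255.
#'
#' @param pixels numeric array `height x width x 3` with values in 0--255.
#'   A `height x width` matrix is promoted to three identical channels.
#' @param pixel_size_um physical pixel pitch, micrometres per pixel (> 0).
#' @param label free-text identifier (animal/section).
#' @return An object of class `section_image` with elements `pixels`,
#'   `pixel_size_um` and `label`.
#' @export
section_image <- function(pixels, pixel_size_um, label = "") {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3L] == 3L)
  if (dim(pixels)[1L] < 1L || dim(pixels)[2L] < 1L)
    stop("section image must be at least 1x1")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         label = as.character(label)),
    class = "section_image")
}

#' Construct a binary mask
#'
#' A `{0,1}` raster aligned to a section image. The `semantics` field records
#' what the mask means: `"tissue"` (tissue vs background), `"footprint"`
#' (the lung section footprint), `"exclusion"` (bronchi/vessels to remove)
#' or `"inclusion"` (the final analysis domain).
#'
#' @param pixels integer/numeric matrix; any nonzero value is coerced to 1.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param semantics one of `"tissue"`, `"footprint"`, `"exclusion"`,
#'   `"inclusion"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size_um,
                        semantics = c("tissue", "footprint", "exclusion",
                                      "inclusion")) {
  semantics <- match.arg(semantics)
  stopifnot(is.matrix(pixels))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (anyNA(pixels)) stop("mask must not contain NA")
  m <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  structure(
    list(pixels = m, pixel_size_um = as.numeric(pixel_size_um),
         semantics = semantics),
    class = "binary_mask")
}

#' Construct a tissue fraction image
#'
#' A per-pixel tissue fraction raster with values in `[0, 1]`, typically the
#' product of block-averaging a native-resolution binary tissue mask down to
#' the analysis pitch.
#'
#' @param pixels numeric matrix with values in `[0, 1]`.
#' @param pixel_size_um micrometres per pixel at the analysis resolution.
#' @return An object of class `fraction_image`.
#' @export
fraction_image <- function(pixels, pixel_size_um) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("fraction values must lie in [0, 1]")
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um)),
    class = "fraction_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("section_image %s: %d x %d px, %.4g um/px (%.3g x %.3g mm)\n",
              if (nzchar(x$label)) dQuote(x$label) else "<unlabelled>",
              d[1L], d[2L], x$pixel_size_um,
              d[1L] * x$pixel_size_um / 1000,
              d[2L] * x$pixel_size_um / 1000))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask [%s]: %d x %d px, %.4g um/px, %d foreground px (%.1f%%)\n",
              x$semantics, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              sum(x$pixels), 100 * mean(x$pixels)))
  invisible(x)
}

#' @export
print.fraction_image <- function(x, ...) {
  cat(sprintf("fraction_image: %d x %d px, %.4g um/px, mean tissue fraction %.4f\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              mean(x$pixels)))
  invisible(x)
}

# shared dimension check
.same_dims <- function(a, b) identical(dim(a)[1:2], dim(b)[1:2])
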