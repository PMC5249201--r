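#' Segmentation parameters
#'
#' Controls how a stained section is separated into tissue and background,
#' and how the section footprint is derived. Masson-trichrome tissue is
#' saturated and dark against a near-white slide background, so segmentation
#' is luminance thresholding (Rec. 601 luma, `0.299 R + 0.587 G + 0.114 B`)
#' with Otsu's method as the automatic default. Regions manually erased from
#' the image (painted pure white in an editor) are recognised as sentinel
#' pixels within `white_sentinel_tolerance` channel units of (255,255,255)
#' and never counted as tissue.
#'
#' @param mode `"binary_native"` (threshold at native resolution, then block
#'   reduce; preferred) or `"soft_analysis"` (continuous per-pixel fraction
#'   at the analysis resolution, for when only reduced images exist).
#' @param luminance_threshold `"auto"` (Otsu on non-sentinel luminance) or a
#'   fixed value in (0, 255).
#' @param white_sentinel_tolerance max channel distance from pure white
#'   treated as an erased pixel.
#' @param footprint_closing_radius_px disk radius (pixels, at the resolution
#'   of the raster handed to [lung_footprint]) for morphological closing of
#'   the tissue mask; sized to bridge alveolar lumens.
#' @param footprint_min_hole_px interior holes smaller than this (pixels)
#'   are filled into the footprint.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(mode = c("binary_native", "soft_analysis"),
                       luminance_threshold = "auto",
                       white_sentinel_tolerance = 2L,
                       footprint_closing_radius_px = 10L,
                       footprint_min_hole_px = 5000L) {
  mode <- match.arg(mode)
  if (!identical(luminance_threshold, "auto")) {
    if (!is.numeric(luminance_threshold) || length(luminance_threshold) != 1L ||
        luminance_threshold <= 0 || luminance_threshold >= 255)
      stop("luminance_threshold must be \"auto\" or a number in (0, 255)")
  }
  stopifnot(white_sentinel_tolerance >= 0, footprint_closing_radius_px >= 0,
            footprint_min_hole_px >= 0)
  structure(list(mode = mode,
                 luminance_threshold = luminance_threshold,
                 white_sentinel_tolerance = as.integer(white_sentinel_tolerance),
                 footprint_closing_radius_px = as.integer(footprint_closing_radius_px),
                 footprint_min_hole_px = as.integer(footprint_min_hole_px)),
            class = "seg_params")
}

# luminance in 0..255 and the sentinel (erased / pure-white) pixel mask
.luma_and_sentinel <- function(image, params) {
  px <- image$pixels
  luma <- 0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
  tol <- params$white_sentinel_tolerance
  sentinel <- (px[, , 1L] >= 255 - tol) & (px[, , 2L] >= 255 - tol) &
    (px[, , 3L] >= 255 - tol)
  list(luma = luma, sentinel = sentinel)
}

.resolve_threshold <- function(luma, sentinel, params) {
  if (!identical(params$luminance_threshold, "auto"))
    return(params$luminance_threshold)
  keep <- luma[!sentinel]
  if (length(keep) == 0L)
    stop("degenerate input: every pixel is a white sentinel")
  255 * EBImage::otsu(matrix(keep / 255, nrow = 1L), range = c(0, 1))
}

#' Segment tissue from background
#'
#' A pixel is tissue iff its luminance is below the threshold and it is not
#' a white sentinel (erased) pixel. With `luminance_threshold = "auto"` the
#' threshold is Otsu's method computed on the luminance of non-sentinel
#' pixels.
#'
#' @param image a [section_image].
#' @param params a [seg_params].
#' @return A [binary_mask] with tissue semantics. The resolved threshold is
#'   attached as attribute `"threshold"`.
#' @export
segment_tissue <- function(image, params = seg_params()) {
  stopifnot(inherits(image, "section_image"))
  ls <- .luma_and_sentinel(image, params)
  thr <- .resolve_threshold(ls$luma, ls$sentinel, params)
  m <- binary_mask((ls$luma < thr) & !ls$sentinel, image$pixel_size_um,
                   semantics = "tissue")
  attr(m, "threshold") <- thr
  m
}

#' Continuous per-pixel tissue fraction
#'
#' Fallback segmentation for images that exist only at the analysis
#' resolution, where a single pixel already mixes tissue and lumen: the
#' fraction is a linear ramp in luminance,
#' `clamp((threshold - luminance) / threshold, 0, 1)`, and 0 for white
#' sentinel pixels.
#'
#' @inheritParams segment_tissue
#' @return A [fraction_image] at the image's pitch, with attribute
#'   `"threshold"`.
#' @export
soft_tissue_fraction <- function(image, params = seg_params(mode = "soft_analysis")) {
  stopifnot(inherits(image, "section_image"))
  ls <- .luma_and_sentinel(image, params)
  thr <- .resolve_threshold(ls$luma, ls$sentinel, params)
  f <- pmin(pmax((thr - ls$luma) / thr, 0), 1)
  f[ls$sentinel] <- 0
  out <- fraction_image(f, image$pixel_size_um)
  attr(out, "threshold") <- thr
  out
}

#' Derive the lung section footprint
#'
#' The micro-tile grid must cover the section, including alveolar lumens,
#' but not empty slide. The footprint is the tissue mask after morphological
#' closing with a disk of radius `footprint_closing_radius_px`, filling of
#' interior holes smaller than `footprint_min_hole_px`, and removal of
#' connected components smaller than 0.1% of the image area (debris floor).
#'
#' @param tissue a [binary_mask] (tissue) or [fraction_image] (binarised at
#'   fraction > 0 first).
#' @param params a [seg_params].
#' @return A [binary_mask] with footprint semantics.
#' @export
lung_footprint <- function(tissue, params = seg_params()) {
  if (inherits(tissue, "fraction_image")) {
    tissue <- binary_mask(tissue$pixels > 0, tissue$pixel_size_um, "tissue")
  }
  stopifnot(inherits(tissue, "binary_mask"))
  px <- tissue$pixels
  if (sum(px) == 0L) stop("degenerate input: empty tissue raster")
  r <- params$footprint_closing_radius_px
  if (r > 0L) {
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    px <- EBImage::closing(px, brush)
  }
  px <- .fill_small_holes(px, params$footprint_min_hole_px)
  px <- .drop_small_components(px, floor_frac = 0.001)
  binary_mask(px, tissue$pixel_size_um, semantics = "footprint")
}

# fill background components not touching the border and smaller than max_px
.fill_small_holes <- function(px, max_px) {
  if (max_px <= 0L) return(px)
  bg <- EBImage::bwlabel(1L - px)
  n <- max(bg)
  if (n == 0L) return(px)
  border_labels <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  sizes <- tabulate(bg[bg > 0], nbins = n)
  fill <- setdiff(which(sizes < max_px), border_labels)
  if (length(fill)) px[bg %in% fill] <- 1L
  px
}

.drop_small_components <- function(px, floor_frac) {
  lab <- EBImage::bwlabel(px)
  n <- max(lab)
  if (n == 0L) return(px)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  floor_px <- floor_frac * length(px)
  drop <- which(sizes < floor_px)
  if (length(drop)) px[lab %in% drop] <- 0L
  px
}

#' Combine footprint and exclusion into the inclusion domain
#'
#' Bronchi and vessels with diameter over 200 um (and their peri-structural
#' collagen) are marked in an exclusion mask and removed from the analysis
#' domain: `inclusion = footprint AND NOT exclusion`. With no exclusion
#' mask the inclusion domain is the footprint itself.
#'
#' @param footprint a [binary_mask] with footprint semantics.
#' @param exclusion a [binary_mask] with exclusion semantics, or `NULL`.
#' @return A [binary_mask] with inclusion semantics.
#' @export
inclusion_mask <- function(footprint, exclusion = NULL) {
  stopifnot(inherits(footprint, "binary_mask"))
  if (is.null(exclusion)) {
    return(binary_mask(footprint$pixels, footprint$pixel_size_um, "inclusion"))
  }
  stopifnot(inherits(exclusion, "binary_mask"))
  if (!.same_dims(footprint$pixels, exclusion$pixels))
    stop("footprint and exclusion mask dimensions differ")
  binary_mask(footprint$pixels & !exclusion$pixels,
              footprint$pixel_size_um, "inclusion")
}
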