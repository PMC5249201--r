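#' Quantify a single section end to end
#'
#' The full per-section workflow: segment tissue from the stained image,
#' block-average the binary mask down to the analysis pitch (or take the
#' soft per-pixel fraction when the image is already at analysis
#' resolution), derive the lung footprint, subtract the exclusion mask
#' (bronchi/vessels), lay the micro-tile grid, and compute per-tile
#' densities, the 20-class histogram and the Dm index.
#'
#' @param image a [section_image] (native resolution for
#'   `mode = "binary_native"`).
#' @param exclusion optional [binary_mask] with exclusion semantics, at the
#'   image's resolution.
#' @param params a [seg_params]; its `mode` selects the segmentation route.
#' @param reduce_factor native-to-analysis block reduction factor (ignored
#'   in soft mode); default 8 (x20 -> x2.5). The synthetic generator uses 4.
#' @param tile_side_px micro-tile side in analysis pixels.
#' @param min_inclusion minimum in-domain pixel fraction for a tile to be
#'   included.
#' @return A list of class `section_quantification`: `map`
#'   ([tile_density_map]), `hist` ([density_histogram]), `Dm`, `fractions`
#'   ([fraction_image] at analysis pitch), `inclusion`, `threshold`
#'   (resolved segmentation threshold), `label`.
#' @export
quantify_section <- function(image, exclusion = NULL, params = seg_params(),
                             reduce_factor = 8L, tile_side_px = 10L,
                             min_inclusion = 1) {
  stopifnot(inherits(image, "section_image"))
  if (params$mode == "binary_native") {
    tissue <- segment_tissue(image, params)
    thr <- attr(tissue, "threshold")
    frac <- block_reduce_fraction(tissue, reduce_factor)
    excl_red <- if (is.null(exclusion)) NULL else {
      er <- block_reduce_fraction(exclusion, reduce_factor)
      binary_mask(er$pixels > 0, er$pixel_size_um, "exclusion")
    }
  } else {
    frac <- soft_tissue_fraction(image, params)
    thr <- attr(frac, "threshold")
    excl_red <- exclusion
  }
  if (!is.null(excl_red) && !.same_dims(frac$pixels, excl_red$pixels))
    stop("exclusion mask does not align with the analysis raster for section ",
         dQuote(image$label))
  footprint <- lung_footprint(frac, params)
  incl <- inclusion_mask(footprint, excl_red)
  grid <- make_grid(nrow(frac$pixels), ncol(frac$pixels), tile_side_px,
                    frac$pixel_size_um)
  map <- tile_densities(frac, grid, incl, min_inclusion = min_inclusion)
  structure(list(map = map, hist = density_histogram(map, label = image$label),
                 Dm = mean_density(map), fractions = frac, inclusion = incl,
                 threshold = thr, label = image$label),
            class = "section_quantification")
}

#' @export
print.section_quantification <- function(x, ...) {
  cat(sprintf(paste0("section_quantification %s: %d tiles, Dm = %.4f ",
                     "(segmentation threshold %.1f)\n"),
              dQuote(x$label), x$map$n_included, x$Dm, x$threshold))
  invisible(x)
}

#' Per-section histogram row for CSV export
#'
#' Flattens a quantified section into one row: label, tile count, the 20
#' class frequencies, Dm and (when a threshold is supplied) HDFm.
#'
#' @param q a `section_quantification`.
#' @param threshold_class optional calibrated HDFm threshold.
#' @return one-row data.frame `label, n_tiles, f1..f20, Dm[, HDFm]`.
#' @export
section_summary_row <- function(q, threshold_class = NULL) {
  stopifnot(inherits(q, "section_quantification"))
  row <- data.frame(label = q$label, n_tiles = q$hist$n_tiles)
  for (k in 1:20) row[[paste0("f", k)]] <- q$hist$freq[k]
  row$Dm <- q$Dm
  if (!is.null(threshold_class)) {
    row$HDFm <- hdf(q$hist, threshold_class)
    row$threshold_class <- as.integer(threshold_class)
  }
  row
}
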