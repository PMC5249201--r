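#' Grade a tissue density into one of 20 classes
#'
#' Densities in `[0, 1]` are graded in 20 classes of increasing values in
#' increments of 0.05, lower-inclusive: class `k` covers
#' `[(k-1) * 0.05, k * 0.05)`, with class 20 closed at 1 (`[0.95, 1]`).
#' Vectorised.
#'
#' @param density numeric vector of densities in `[0, 1]`.
#' @return integer vector of classes in 1..20.
#' @export
density_class <- function(density) {
  if (anyNA(density) || any(density < 0 | density > 1))
    stop("density must lie in [0, 1]")
  # the 1e-9 guard keeps exact boundary densities (k * 0.05, common for
  # rational tile densities) in the class they open despite IEEE rounding
  pmin(as.integer(floor(density / 0.05 + 1e-9)) + 1L, 20L)
}

#' Class interval midpoints
#'
#' Midpoint of each density class, `(k - 0.5) * 0.05`; used to link Dm to
#' its histogram.
#'
#' @param k integer class vector (default all 20 classes).
#' @return numeric vector of midpoints.
#' @export
class_midpoints <- function(k = 1:20) (k - 0.5) * 0.05

#' Tissue density frequency distribution
#'
#' The frequency of tissue density per class: the number of included tiles
#' whose density falls in class `k`, divided by the total number of included
#' tiles, for `k = 1..20`. Frequencies sum to 1.
#'
#' @param map a [tile_density_map].
#' @param label free-text identifier carried into downstream tables.
#' @return An object of class `density_histogram`: `freq` (length-20
#'   numeric), `n_tiles`, `label`.
#' @export
density_histogram <- function(map, label = "") {
  stopifnot(inherits(map, "tile_density_map"))
  if (map$n_included < 1L) stop("degenerate input: empty tile map")
  k <- density_class(map$density[map$included])
  freq <- tabulate(k, nbins = 20L) / map$n_included
  structure(list(freq = freq, n_tiles = map$n_included,
                 label = as.character(label)),
            class = "density_histogram")
}

#' @export
print.density_histogram <- function(x, ...) {
  cat(sprintf("density_histogram %s: %d tiles\n",
              if (nzchar(x$label)) dQuote(x$label) else "", x$n_tiles))
  cat("  freq:", paste(sprintf("%.3f", x$freq), collapse = " "), "\n")
  invisible(x)
}

#' Calibrate the HDFm threshold class from a control group
#'
#' The range of classes allocated to the high tissue density frequency is
#' established from the saline-treated control group, where fibrotic
#' alterations are absent: the threshold is the smallest class `c` such that
#' the mean control frequency of every class `k >= c` falls below `cutoff`
#' (1% by default). The supra-threshold range is required to be contiguous
#' up to class 20 (the scan runs from the top); isolated sub-cutoff classes
#' below the threshold do not extend the range.
#'
#' @param controls a list of [density_histogram] objects from control
#'   sections/animals (at least one).
#' @param cutoff frequency cutoff in (0, 1); default 0.01.
#' @param method `"mean"` (default): per-class mean frequency over control
#'   histograms; `"pooled"`: tile-weighted pooled frequency (all control
#'   tiles as one histogram).
#' @return An object of class `calibration_result`: `threshold_class`,
#'   `cutoff`, `control_mean_freq` (length-20 numeric).
#' @export
calibrate_threshold <- function(controls, cutoff = 0.01,
                                method = c("mean", "pooled")) {
  method <- match.arg(method)
  if (inherits(controls, "density_histogram")) controls <- list(controls)
  stopifnot(length(controls) >= 1L,
            all(vapply(controls, inherits, TRUE, "density_histogram")),
            cutoff > 0, cutoff < 1)
  fmat <- vapply(controls, function(h) h$freq, numeric(20L))
  mean_freq <- if (method == "mean") {
    rowMeans(fmat)
  } else {
    w <- vapply(controls, function(h) h$n_tiles, numeric(1L))
    as.vector(fmat %*% w) / sum(w)
  }
  below <- mean_freq < cutoff
  if (!below[20L])
    stop("calibration failure: control frequency of class 20 is not below ",
         "the cutoff (", signif(mean_freq[20L], 3), " >= ", cutoff, ")")
  # longest all-below suffix, scanned from the top
  thr <- 20L
  while (thr > 1L && below[thr - 1L]) thr <- thr - 1L
  structure(list(threshold_class = thr, cutoff = cutoff,
                 control_mean_freq = mean_freq),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0("calibration_result: threshold class %d (cutoff %.3g; ",
                     "max supra-threshold control frequency %.4g)\n"),
              x$threshold_class, x$cutoff,
              max(x$control_mean_freq[x$threshold_class:20L])))
  invisible(x)
}

#' High tissue density frequency (HDFm)
#'
#' The fibrosis-specific index: the sum of class frequencies from the
#' control-calibrated threshold class up to class 20. In lesion-free control
#' lungs those classes hold only residual noise (stray collagen fibres,
#' erythrocytes), so HDFm quantifies fibrotic alterations specifically.
#'
#' @param hist a [density_histogram].
#' @param threshold_class integer in 1..20, typically
#'   `calibrate_threshold(...)$threshold_class`.
#' @return HDFm, a number in `[0, 1]`.
#' @export
hdf <- function(hist, threshold_class) {
  stopifnot(inherits(hist, "density_histogram"))
  threshold_class <- as.integer(threshold_class)
  if (is.na(threshold_class) || threshold_class < 1L || threshold_class > 20L)
    stop("threshold_class must be an integer in 1..20")
  sum(hist$freq[threshold_class:20L])
}
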