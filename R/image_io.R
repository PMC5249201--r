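#' Read a stained section image from PNG or TIFF
#'
#' Decodes an RGB (or grayscale, promoted to RGB) raster and attaches the
#' physical pixel pitch, which scanners rarely embed reliably and is
#' therefore a required argument.
#'
#' @param path path to a PNG or TIFF file.
#' @param pixel_size_um physical pixel pitch in micrometres per pixel.
#' @param label optional identifier; defaults to the file name.
#' @return A [section_image].
#' @export
read_section <- function(path, pixel_size_um, label = basename(path)) {
  arr <- .read_raster(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  if (dim(arr)[3L] == 4L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(arr)[3L] != 3L)
    stop("expected a 1-, 3- or 4-channel image: ", path)
  section_image(round(arr * 255), pixel_size_um, label = label)
}

#' Write a section image to PNG or TIFF
#'
#' Lossless output; the format is chosen from the file extension.
#'
#' @param image a [section_image].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_section <- function(image, path) {
  stopifnot(inherits(image, "section_image"))
  .write_raster(image$pixels / 255, path)
  invisible(path)
}

#' Read a binary mask from PNG or TIFF
#'
#' Any nonzero value is foreground. Multi-channel input is accepted only when
#' all channels agree pixel-wise.
#'
#' @param path path to a single-channel PNG or TIFF file.
#' @param pixel_size_um micrometres per pixel.
#' @param semantics mask meaning; see [binary_mask].
#' @return A [binary_mask].
#' @export
read_mask <- function(path, pixel_size_um,
                      semantics = c("tissue", "footprint", "exclusion",
                                    "inclusion")) {
  arr <- .read_raster(path)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] == 4L) arr <- arr[, , 1:3, drop = FALSE]
    for (ch in seq_len(dim(arr)[3L])[-1L])
      if (!identical(arr[, , 1L] != 0, arr[, , ch] != 0))
        stop("multi-channel mask with disagreeing channels: ", path)
    arr <- arr[, , 1L]
  }
  binary_mask(arr != 0, pixel_size_um, semantics = match.arg(semantics))
}

#' Write a binary mask to PNG or TIFF
#'
#' Foreground is written as white (255), background as black.
#'
#' @param mask a [binary_mask].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  .write_raster(matrix(as.numeric(mask$pixels), nrow(mask$pixels)), path)
  invisible(path)
}

#' Block-average a binary tissue mask to the analysis resolution
#'
#' Reduces a native-resolution tissue mask to a per-pixel tissue fraction at
#' a coarser pitch: each output pixel is the mean of a `factor x factor`
#' block of binary values, so the scanned x20 image is reduced to the x2.5
#' analysis scale (factor 8) without losing tissue mass. Trailing partial
#' blocks (when dimensions do not divide evenly) are averaged over their
#' actual pixel count rather than zero-padded, so border tissue is not
#' diluted.
#'
#' @param mask a [binary_mask] with tissue semantics.
#' @param factor integer reduction factor (>= 1); default 8, matching an
#'   x20 to x2.5 magnification reduction.
#' @return A [fraction_image] with `pixel_size_um` equal to the input pitch
#'   times `factor`. When dimensions divide evenly the global mean tissue
#'   fraction is conserved exactly.
#' @export
block_reduce_fraction <- function(mask, factor = 8L) {
  stopifnot(inherits(mask, "binary_mask") || inherits(mask, "fraction_image"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  px <- mask$pixels
  if (factor == 1L) {
    return(fraction_image(matrix(as.numeric(px), nrow(px)),
                          mask$pixel_size_um))
  }
  h <- nrow(px); w <- ncol(px)
  rg <- (seq_len(h) - 1L) %/% factor + 1L
  cg <- (seq_len(w) - 1L) %/% factor + 1L
  sums <- t(rowsum(t(rowsum(px + 0, rg)), cg))
  dimnames(sums) <- NULL
  counts <- tabulate(rg) %o% tabulate(cg)
  fraction_image(sums / counts, mask$pixel_size_um * factor)
}

# ---- internal raster codecs -------------------------------------------------

.raster_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") "png"
  else if (ext %in% c("tif", "tiff")) "tiff"
  else stop("unsupported raster format (use .png/.tif/.tiff): ", path)
}

.read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  switch(.raster_format(path),
         png  = png::readPNG(path),
         tiff = tiff::readTIFF(path))
}

.write_raster <- function(arr01, path) {
  switch(.raster_format(path),
         png  = png::writePNG(arr01, path),
         tiff = tiff::writeTIFF(arr01, path, bits.per.sample = 8L,
                                compression = "none"))
  invisible(path)
}
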