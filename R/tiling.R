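#' Lay a regular micro-tile grid over a raster
#'
#' Non-overlapping square tiles anchored at the top-left corner (0,0).
#' Trailing partial tiles (when a dimension does not divide evenly) are kept
#' in the grid but flagged and excluded downstream, so the density
#' denominator is always the full tile area.
#'
#' @param image_height_px,image_width_px raster extent in pixels.
#' @param tile_side_px tile side in pixels; default 2, which at the default
#'   3.632 um/px analysis pitch gives a tile area of 52.8 um^2.
#' @param pixel_size_um micrometres per pixel of the raster being tiled.
#' @return An object of class `tile_grid` with fields `tile_side_px`,
#'   `n_rows`, `n_cols`, `pixel_size_um`.
#' @export
make_grid <- function(image_height_px, image_width_px, tile_side_px = 2L,
                      pixel_size_um) {
  stopifnot(image_height_px >= 1, image_width_px >= 1, pixel_size_um > 0)
  tile_side_px <- as.integer(tile_side_px)
  if (is.na(tile_side_px) || tile_side_px < 1L)
    stop("tile_side_px must be a positive integer")
  if (tile_side_px > image_height_px && tile_side_px > image_width_px)
    stop("tile side exceeds both image dimensions")
  structure(list(
    tile_side_px = tile_side_px,
    n_rows = as.integer(ceiling(image_height_px / tile_side_px)),
    n_cols = as.integer(ceiling(image_width_px / tile_side_px)),
    pixel_size_um = as.numeric(pixel_size_um)),
    class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  side_um <- x$tile_side_px * x$pixel_size_um
  cat(sprintf("tile_grid: %d x %d tiles of %d px (%.3g um side, %.3g um^2)\n",
              x$n_rows, x$n_cols, x$tile_side_px, side_um, side_um^2))
  invisible(x)
}

#' Per-tile pulmonary tissue density
#'
#' The density `d` of a micro-tile is the ratio of the tissue area inside
#' the tile to the total tile area: the mean of the tissue fraction raster
#' over all pixels of the tile, with the full tile as denominator even where
#' the inclusion domain only partially covers the tile. A tile enters the
#' analysis iff it is a full (non-partial) tile and at least `min_inclusion`
#' of its pixels lie inside the inclusion domain.
#'
#' @param fractions a [fraction_image] or binary tissue [binary_mask] at the
#'   analysis resolution.
#' @param grid a [tile_grid] matching the raster dimensions.
#' @param inclusion a [binary_mask] with inclusion semantics, same
#'   dimensions, or `NULL` to include every full tile.
#' @param min_inclusion minimum fraction of tile pixels inside the inclusion
#'   domain, in (0, 1]; default 1 (the whole tile must be inside).
#' @return An object of class `tile_density_map`: fields `grid`, `density`
#'   (`n_rows x n_cols` matrix, `NA` where not included), `included`
#'   (logical matrix), `n_included`.
#' @export
tile_densities <- function(fractions, grid, inclusion = NULL,
                           min_inclusion = 1) {
  px <- if (inherits(fractions, "binary_mask")) fractions$pixels + 0
        else if (inherits(fractions, "fraction_image")) fractions$pixels
        else stop("fractions must be a fraction_image or binary_mask")
  stopifnot(inherits(grid, "tile_grid"),
            min_inclusion > 0, min_inclusion <= 1)
  h <- nrow(px); w <- ncol(px); s <- grid$tile_side_px
  if (ceiling(h / s) != grid$n_rows || ceiling(w / s) != grid$n_cols)
    stop("grid does not match raster dimensions")
  if (!is.null(inclusion)) {
    stopifnot(inherits(inclusion, "binary_mask"))
    if (!.same_dims(px, inclusion$pixels))
      stop("inclusion mask dimensions differ from raster")
  }

  full_rows <- grid$n_rows - (h %% s != 0L)
  full_cols <- grid$n_cols - (w %% s != 0L)
  dens <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  incl <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (full_rows >= 1L && full_cols >= 1L) {
    sub <- px[seq_len(full_rows * s), seq_len(full_cols * s), drop = FALSE]
    dens[seq_len(full_rows), seq_len(full_cols)] <- .tile_sums(sub, s) / s^2
    if (is.null(inclusion)) {
      cover <- matrix(1, full_rows, full_cols)
    } else {
      isub <- inclusion$pixels[seq_len(full_rows * s), seq_len(full_cols * s),
                               drop = FALSE]
      cover <- .tile_sums(isub + 0, s) / s^2
    }
    incl[seq_len(full_rows), seq_len(full_cols)] <- cover >= min_inclusion
  }
  dens[!incl] <- NA_real_
  n_inc <- sum(incl)
  if (n_inc == 0L)
    stop("degenerate input: no included tile (empty section?)")
  structure(list(grid = grid, density = dens, included = incl,
                 n_included = n_inc),
            class = "tile_density_map")
}

# sum of values in each s x s block of a matrix whose dims divide by s
.tile_sums <- function(px, s) {
  rg <- (seq_len(nrow(px)) - 1L) %/% s + 1L
  cg <- (seq_len(ncol(px)) - 1L) %/% s + 1L
  t(rowsum(t(rowsum(px, rg)), cg))
}

#' @export
print.tile_density_map <- function(x, ...) {
  cat(sprintf("tile_density_map: %d x %d grid, %d included tiles, Dm = %.4f\n",
              x$grid$n_rows, x$grid$n_cols, x$n_included, mean_density(x)))
  invisible(x)
}

#' Mean tissue density (Dm)
#'
#' The arithmetic mean of the densities of all included micro-tiles of a
#' section: the global index of morphological change. Dm can be expressed
#' per section, per animal (see [aggregate_indexes]) or per group.
#'
#' @param map a [tile_density_map].
#' @return Dm, a number in `[0, 1]`.
#' @export
mean_density <- function(map) {
  stopifnot(inherits(map, "tile_density_map"))
  if (map$n_included < 1L) stop("degenerate input: empty tile map")
  mean(map$density[map$included])
}

#' Export a tile density map as a data frame
#'
#' One row per tile with 0-based grid coordinates, for CSV export.
#'
#' @param x a [tile_density_map].
#' @param row.names,optional,... ignored; standard [as.data.frame] arguments.
#' @return data.frame with columns `tile_row`, `tile_col`, `density`,
#'   `included`.
#' @export
as.data.frame.tile_density_map <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(
    tile_row = rep(seq_len(x$grid$n_rows), times = x$grid$n_cols) - 1L,
    tile_col = rep(seq_len(x$grid$n_cols), each = x$grid$n_rows) - 1L,
    density = as.vector(x$density),
    included = as.vector(x$included))
}
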