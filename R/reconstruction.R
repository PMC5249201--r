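#' Pseudocolor scale for density classes
#'
#' An ordered palette of 20 RGB triplets, one per density class, running
#' from light blue (low densities) to yellow (high densities) by linear
#' interpolation in RGB, plus a background colour for excluded tiles. The
#' endpoints are a documented convention, overridable per call or via a
#' palette file (see [read_palette]).
#'
#' @param low,high RGB endpoint triplets (0--255) for class 1 and class 20.
#' @param background RGB triplet for excluded / out-of-footprint tiles.
#' @return An object of class `color_scale`: `colors` (20 x 3 integer
#'   matrix), `background` (length-3 integer).
#' @export
density_palette <- function(low = c(173, 216, 230), high = c(255, 255, 0),
                            background = c(255, 255, 255)) {
  stopifnot(length(low) == 3L, length(high) == 3L, length(background) == 3L,
            all(c(low, high, background) >= 0), all(c(low, high, background) <= 255))
  t <- (0:19) / 19
  cols <- round(outer(1 - t, low) + outer(t, high))
  structure(list(colors = matrix(as.integer(cols), 20L, 3L),
                 background = as.integer(background)),
            class = "color_scale")
}

#' Read a palette file
#'
#' Plain-text palette: 20 lines `class,R,G,B` (classes 1..20, any order).
#'
#' @param path palette file path.
#' @param background RGB triplet for excluded tiles.
#' @return A `color_scale`.
#' @export
read_palette <- function(path, background = c(255, 255, 255)) {
  tab <- utils::read.csv(path, header = FALSE,
                         col.names = c("class", "R", "G", "B"))
  if (nrow(tab) != 20L || !setequal(tab$class, 1:20))
    stop("palette file must define classes 1..20 exactly once each")
  tab <- tab[order(tab$class), ]
  sc <- density_palette(background = background)
  sc$colors <- matrix(as.integer(as.matrix(tab[, c("R", "G", "B")])), 20L, 3L)
  sc
}

#' Render the pseudocolor 2D density reconstruction
#'
#' Composes the reconstructed image of a section from its per-tile density
#' classes: every pixel of an included tile is painted with the colour of
#' that tile's class, excluded tiles with the background colour. The output
#' raster is at the analysis pixel pitch and spans the full grid extent.
#' Rendering is a pure function of the map and scale.
#'
#' @param map a [tile_density_map].
#' @param scale a `color_scale`; default [density_palette()].
#' @return A [section_image] of size
#'   `(n_rows * tile_side) x (n_cols * tile_side)`.
#' @export
render_density_map <- function(map, scale = density_palette()) {
  stopifnot(inherits(map, "tile_density_map"), inherits(scale, "color_scale"))
  if (map$n_included < 1L) stop("degenerate input: empty tile map")
  s <- map$grid$tile_side_px
  # per-tile colour index: 0 = background, k = class k
  idx <- matrix(0L, map$grid$n_rows, map$grid$n_cols)
  idx[map$included] <- density_class(map$density[map$included])
  lut <- rbind(scale$background, scale$colors)  # row 1 = background
  big <- idx[rep(seq_len(nrow(idx)), each = s),
             rep(seq_len(ncol(idx)), each = s), drop = FALSE]
  h <- nrow(big); w <- ncol(big)
  px <- array(0L, c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- matrix(lut[big + 1L, ch], h, w)
  section_image(px, map$grid$pixel_size_um, label = "2D reconstruction")
}

#' Legend for a pseudocolor reconstruction
#'
#' Maps each class to its density interval and colour, for CSV export next
#' to a rendered image.
#'
#' @param scale a `color_scale`.
#' @return data.frame with columns `class`, `lower`, `upper`, `R`, `G`, `B`.
#' @export
palette_legend <- function(scale = density_palette()) {
  data.frame(class = 1:20,
             lower = (0:19) * 0.05,
             upper = (1:20) * 0.05,
             R = scale$colors[, 1L], G = scale$colors[, 2L],
             B = scale$colors[, 3L])
}
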