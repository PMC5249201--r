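# shared fixtures and independent oracles

# uniform RGB section image from a single colour
flat_section <- function(h, w, rgb, pitch = 3.632) {
  px <- array(0, c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  section_image(px, pitch)
}

rand_mask <- function(h, w, p = 0.5, pitch = 0.908,
                      semantics = "tissue") {
  binary_mask(matrix(stats::rbinom(h * w, 1L, p), h, w), pitch, semantics)
}

# per-pixel double-loop oracle for block averaging (partial trailing blocks
# averaged over their true pixel count)
oracle_block_reduce <- function(px, f) {
  nr <- ceiling(nrow(px) / f); nc <- ceiling(ncol(px) / f)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rows <- ((i - 1) * f + 1):min(i * f, nrow(px))
    cols <- ((j - 1) * f + 1):min(j * f, ncol(px))
    acc <- 0
    for (r in rows) for (cc in cols) acc <- acc + px[r, cc]
    out[i, j] <- acc / (length(rows) * length(cols))
  }
  out
}

# per-pixel double-loop oracle for full-tile densities (no inclusion gating)
oracle_tile_densities <- function(px, s) {
  nr <- nrow(px) %/% s; nc <- ncol(px) %/% s
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (r in ((i - 1) * s + 1):(i * s))
      for (cc in ((j - 1) * s + 1):(j * s)) acc <- acc + px[r, cc]
    out[i, j] <- acc / s^2
  }
  out
}

# tile map built directly from a density matrix (for renderer tests)
manual_map <- function(density, included, tile_side_px = 2L,
                       pixel_size_um = 3.632) {
  grid <- make_grid(nrow(density) * tile_side_px,
                    ncol(density) * tile_side_px,
                    tile_side_px, pixel_size_um)
  density[!included] <- NA_real_
  structure(list(grid = grid, density = density, included = included,
                 n_included = sum(included)),
            class = "tile_density_map")
}

# histogram built directly from a frequency vector
manual_hist <- function(freq, n_tiles = 1000L, label = "") {
  structure(list(freq = freq, n_tiles = n_tiles, label = label),
            class = "density_histogram")
}

# small fast generator settings for study-level tests
small_section <- function(...) {
  args <- list(width_um = 400, height_um = 400, lesion_radius_um = 25,
               n_vessels = 0L)
  over <- list(...)
  args[names(over)] <- over
  do.call(section_params, args)
}

# the default study conditions (computed once, shared across test files)
.study_cache <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(.study_cache$study))
    .study_cache$study <- simulate_study(study_params(master_seed = 1))
  .study_cache$study
}

group_means <- function(table, col) {
  ord <- c("control", "0.25 mg/kg", "0.5 mg/kg", "0.75 mg/kg", "1 mg/kg")
  agg <- stats::aggregate(table[[col]], by = list(group = table$group),
                          FUN = mean)
  agg$x[match(ord[ord %in% agg$group], agg$group)]
}
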