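#' Parameters of a synthetic lung section
#'
#' The generator emulates the morphology the quantification pipeline is
#' built for: a thin septal alveolar network at a controlled areal tissue
#' fraction, dose-dependent fibrotic foci of high tissue fraction, and
#' ring-shaped vessels (diameter above the 200 um exclusion criterion)
#' recorded in an exclusion mask. Septa are drawn as the uniform-thickness
#' band around the zero contours of a smoothed Gaussian random field
#' (distance-to-contour thresholded at the quantile that hits the requested
#' areal fraction), which gives septa of realistic thickness (~10 um at the
#' defaults) separating lumens of `alveole_scale_um` characteristic size.
#'
#' @param width_um,height_um physical extent of the section, micrometres.
#' @param native_pitch_um native scan pitch, um/pixel; default 0.908 so a
#'   reduction factor of 4 lands exactly on the 3.632 um analysis pitch.
#' @param baseline_septal_fraction areal tissue fraction of the lesion-free
#'   septal network, in (0, 1).
#' @param alveole_scale_um characteristic alveolar lumen size (contour
#'   spacing of the random field), micrometres.
#' @param lesion_coverage fraction of the non-excluded section area covered
#'   by fibrotic foci, in [0, 1).
#' @param lesion_density tissue fraction inside foci, in (0, 1].
#' @param lesion_radius_um characteristic focus radius (jittered per focus).
#' @param n_vessels number of vessel rings to draw.
#' @param vessel_diameter_um outer vessel diameter; default 250 um, above
#'   the 200 um manual-exclusion criterion.
#' @param noise_sd Gaussian channel noise of the rendered image, in 0--255
#'   units.
#' @param seed integer seed; a fixed seed makes the section fully
#'   reproducible.
#' @return An object of class `section_params`.
#' @export
section_params <- function(width_um = 1200, height_um = 1200,
                           native_pitch_um = 0.908,
                           baseline_septal_fraction = 0.25,
                           alveole_scale_um = 40,
                           lesion_coverage = 0,
                           lesion_density = 0.9,
                           lesion_radius_um = 80,
                           n_vessels = 2L,
                           vessel_diameter_um = 250,
                           noise_sd = 8,
                           seed = 1L) {
  stopifnot(width_um > 0, height_um > 0, native_pitch_um > 0,
            baseline_septal_fraction > 0, baseline_septal_fraction < 1,
            alveole_scale_um > 0,
            lesion_coverage >= 0, lesion_coverage < 1,
            lesion_density > 0, lesion_density <= 1,
            lesion_radius_um > 0, n_vessels >= 0,
            vessel_diameter_um > 0, noise_sd >= 0)
  structure(as.list(environment()), class = "section_params")
}

# Masson-trichrome-like rendering hues (R, G, B)
.hues <- list(background = c(245, 242, 243),
              septa      = c(150,  85, 135),
              lesion     = c(110, 100, 175),
              vessel     = c(155,  75, 115))

#' Simulate a stained lung section with ground truth
#'
#' Builds the ground-truth tissue mask first (septal network, then fibrotic
#' foci placed as random discs until the requested coverage is reached, then
#' vessel rings), records vessels in an exclusion mask, derives the per-tile
#' true densities with the package's own tiling definition, and finally
#' renders an RGB image in Masson-like hues with Gaussian channel noise.
#' Everything is driven by `params$seed`: the same seed gives bit-identical
#' outputs.
#'
#' @param params a [section_params].
#' @param reduce_factor block-reduction factor from native to analysis pitch
#'   used for the true density map; default 4 (0.908 -> 3.632 um/px).
#' @param tile_side_px micro-tile side at the analysis pitch for the true
#'   density map.
#' @param render_rgb set to `FALSE` to skip the RGB rendering (truth-only
#'   simulations); the truth masks and densities are unaffected.
#' @param label identifier stamped on the outputs.
#' @return A list of class `synthetic_section`: `image` ([section_image] or
#'   `NULL`), `exclusion` and `truth` ([binary_mask]s at native pitch),
#'   `truth_map` ([tile_density_map] of true densities), `coverage_achieved`,
#'   `params`.
#' @export
simulate_section <- function(params = section_params(), reduce_factor = 4L,
                             tile_side_px = 10L, render_rgb = TRUE,
                             label = sprintf("synthetic-%d", params$seed)) {
  stopifnot(inherits(params, "section_params"))
  set.seed(params$seed)
  p <- params$native_pitch_um
  h <- max(2L, round(params$height_um / p))
  w <- max(2L, round(params$width_um / p))

  septa <- .septal_network(h, w, params$baseline_septal_fraction,
                           sigma_px = params$alveole_scale_um / pi / p)

  excl <- matrix(FALSE, h, w)
  vessel <- matrix(FALSE, h, w)
  if (params$n_vessels > 0L)
    for (i in seq_len(params$n_vessels)) {
      v <- .draw_vessel(h, w, params$vessel_diameter_um / 2 / p,
                        wall_px = 15 / p, margin_px = 10 / p)
      vessel <- vessel | v$ring
      excl <- excl | v$disc
    }

  lesion <- .place_lesions(h, w, excl, params$lesion_coverage,
                           params$lesion_radius_um / p)
  cov_achieved <- sum(lesion & !excl) / sum(!excl)

  truth <- septa
  idx <- which(lesion & !excl)
  if (length(idx))
    truth[idx] <- stats::rbinom(length(idx), 1L, params$lesion_density) > 0
  truth <- truth | vessel

  truth_mask <- binary_mask(truth, p, semantics = "tissue")
  excl_mask <- binary_mask(excl, p, semantics = "exclusion")

  frac <- block_reduce_fraction(truth_mask, reduce_factor)
  excl_red <- block_reduce_fraction(excl_mask, reduce_factor)
  incl <- binary_mask(excl_red$pixels == 0, frac$pixel_size_um, "inclusion")
  grid <- make_grid(nrow(frac$pixels), ncol(frac$pixels), tile_side_px,
                    frac$pixel_size_um)
  truth_map <- tile_densities(frac, grid, incl)

  image <- NULL
  if (render_rgb) {
    px <- array(0, c(h, w, 3L))
    lesion_px <- lesion & truth & !vessel
    septa_px <- truth & !lesion_px & !vessel
    for (ch in 1:3) {
      m <- matrix(.hues$background[ch], h, w)
      m[septa_px] <- .hues$septa[ch]
      m[lesion_px] <- .hues$lesion[ch]
      m[vessel] <- .hues$vessel[ch]
      if (params$noise_sd > 0)
        m <- m + stats::rnorm(h * w, 0, params$noise_sd)
      px[, , ch] <- pmin(pmax(round(m), 0), 255)
    }
    image <- section_image(px, p, label = label)
  }

  structure(list(image = image, exclusion = excl_mask, truth = truth_mask,
                 truth_map = truth_map, coverage_achieved = cov_achieved,
                 params = params, label = label),
            class = "synthetic_section")
}

# uniform-thickness band network: distance-to-zero-contour of a smoothed
# Gaussian field, thresholded at the quantile hitting the target fraction
.septal_network <- function(h, w, fraction, sigma_px) {
  f <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w), sigma = sigma_px)
  f <- f / stats::sd(f)
  gx <- (cbind(f[, -1], f[, w]) - cbind(f[, 1], f[, -w])) / 2
  gy <- (rbind(f[-1, ], f[h, ]) - rbind(f[1, ], f[-h, ])) / 2
  score <- abs(f) / (sqrt(gx^2 + gy^2) + 1e-9)
  score < stats::quantile(score, fraction)
}

.disc_window <- function(h, w, ci, cj, r) {
  i <- max(1L, floor(ci - r)):min(h, ceiling(ci + r))
  j <- max(1L, floor(cj - r)):min(w, ceiling(cj + r))
  d2 <- outer((i - ci)^2, (j - cj)^2, `+`)
  list(i = i, j = j, inside = d2 <= r^2)
}

.draw_vessel <- function(h, w, r_px, wall_px, margin_px) {
  rex <- r_px + margin_px
  if (2 * rex >= min(h, w))
    stop("vessel of diameter ", round(2 * r_px), " px does not fit the section")
  ci <- stats::runif(1, rex + 1, h - rex)
  cj <- stats::runif(1, rex + 1, w - rex)
  ring <- matrix(FALSE, h, w); disc <- matrix(FALSE, h, w)
  ring <- .paint_disc(ring, h, w, ci, cj, r_px, TRUE)
  ring <- .paint_disc(ring, h, w, ci, cj, max(r_px - wall_px, 1), FALSE)  # lumen
  disc <- .paint_disc(disc, h, w, ci, cj, rex, TRUE)
  list(ring = ring, disc = disc)
}

.paint_disc <- function(m, h, w, ci, cj, r, value) {
  wd <- .disc_window(h, w, ci, cj, r)
  sub <- m[wd$i, wd$j, drop = FALSE]
  sub[wd$inside] <- value
  m[wd$i, wd$j] <- sub
  m
}

.place_lesions <- function(h, w, excl, coverage, radius_px, max_iter = 5000L) {
  lesion <- matrix(FALSE, h, w)
  if (coverage <= 0) return(lesion)
  n_eligible <- sum(!excl)
  target <- coverage * n_eligible
  it <- 0L
  while (sum(lesion & !excl) < target) {
    it <- it + 1L
    if (it > max_iter)
      stop("generation error: lesion coverage ", coverage,
           " not reachable with radius ", round(radius_px), " px")
    r <- radius_px * stats::runif(1, 0.7, 1.3)
    ci <- stats::runif(1, 1, h); cj <- stats::runif(1, 1, w)
    lesion <- .paint_disc(lesion, h, w, ci, cj, r, TRUE)
  }
  lesion
}

#' @export
print.synthetic_section <- function(x, ...) {
  cat(sprintf(paste0("synthetic_section %s: %d x %d native px, lesion ",
                     "coverage %.3f (target %.3f), truth Dm %.3f\n"),
              dQuote(x$label), nrow(x$truth$pixels), ncol(x$truth$pixels),
              x$coverage_achieved, x$params$lesion_coverage,
              mean_density(x$truth_map)))
  invisible(x)
}

#' Parameters of a synthetic dose-response study
#'
#' Emulates the intratracheal bleomycin design: one saline control group and
#' several dose groups, lesion coverage a strictly increasing function of
#' dose, and covariates (Ashcroft score, micro-CT HU peak, dynamic
#' compliance, forced vital capacity, organ/body weights) generated as
#' saturating logistic functions of each animal's achieved lesion coverage
#' plus noise.
#'
#' @param n_control,n_per_dose group sizes; defaults 6 and 12.
#' @param doses dose labels, mg/kg; default `c(0.25, 0.5, 0.75, 1)`.
#' @param dose_to_coverage strictly increasing function dose -> lesion
#'   coverage; default `0.16 * dose^0.6`.
#' @param covariate_noise named list of noise scales: `ashcroft` (score
#'   units), `microct` (HU), `cdyn` (mL/cmH2O), `fvc` (mL), `lww` (g),
#'   `bw` (g).
#' @param section a [section_params] template; its `lesion_coverage` and
#'   `seed` are overridden per animal.
#' @param cutoff calibration cutoff for the HDFm threshold (see
#'   [calibrate_threshold]).
#' @param master_seed integer; per-animal seeds are derived as
#'   `master_seed * 1000 + animal index` (keep it below ~2e6).
#' @return An object of class `study_params`.
#' @export
study_params <- function(n_control = 6L, n_per_dose = 12L,
                         doses = c(0.25, 0.5, 0.75, 1),
                         dose_to_coverage = function(dose) 0.16 * dose^0.6,
                         covariate_noise = list(ashcroft = 0.5, microct = 15,
                                                cdyn = 0.0012, fvc = 0.04,
                                                lww = 0.01, bw = 0.8),
                         section = section_params(),
                         cutoff = 0.01,
                         master_seed = 1L) {
  stopifnot(n_control >= 1L, n_per_dose >= 1L, length(doses) >= 1L,
            is.function(dose_to_coverage), inherits(section, "section_params"),
            cutoff > 0, cutoff < 1)
  cov <- vapply(doses, dose_to_coverage, numeric(1L))
  if (any(!is.finite(cov)) || any(cov < 0) || any(cov >= 1) ||
      (length(cov) > 1L && any(diff(cov) <= 0)))
    stop("dose_to_coverage must map doses to strictly increasing coverages in [0, 1)")
  rm(cov)
  structure(as.list(environment()), class = "study_params")
}

# saturating severity link shared by all covariates
.severity <- function(coverage) stats::plogis((coverage - 0.08) / 0.03)

#' Simulate a full dose-response study
#'
#' One section per animal. Per-animal Dm is computed from the section's tile
#' densities; the HDFm threshold is calibrated from the control group's
#' density histograms at the study's cutoff, and HDFm computed for every
#' animal at that threshold. With `quantify = "truth"` (default) densities
#' come from the ground-truth tissue masks (fast, exact); with
#' `quantify = "pipeline"` each section is rendered to RGB and pushed
#' through segmentation, reduction and tiling via [quantify_section].
#'
#' @param params a [study_params].
#' @param quantify `"truth"` or `"pipeline"`.
#' @param reduce_factor,tile_side_px analysis geometry (see
#'   [simulate_section]).
#' @param keep_sections keep the per-animal `synthetic_section` bundles in
#'   the result (memory-heavy; default `FALSE`).
#' @return A list of class `synthetic_study`: `table` (per-animal
#'   data.frame: animal, group, dose, coverage, Dm, HDFm and covariates),
#'   `calibration` ([calibrate_threshold] result), `histograms` (per-animal
#'   [density_histogram]s), optionally `sections`.
#' @export
simulate_study <- function(params = study_params(),
                           quantify = c("truth", "pipeline"),
                           reduce_factor = 4L, tile_side_px = 10L,
                           keep_sections = FALSE) {
  stopifnot(inherits(params, "study_params"))
  quantify <- match.arg(quantify)
  groups <- c("control", sprintf("%g mg/kg", params$doses))
  n_per <- c(params$n_control, rep(params$n_per_dose, length(params$doses)))
  coverages <- c(0, vapply(params$doses, params$dose_to_coverage, numeric(1L)))
  dose_vals <- c(0, params$doses)

  rows <- list(); hists <- list(); sections <- list()
  a <- 0L
  for (gi in seq_along(groups)) {
    for (k in seq_len(n_per[gi])) {
      a <- a + 1L
      sp <- params$section
      sp$lesion_coverage <- coverages[gi]
      sp$seed <- (params$master_seed %% 2000000L) * 1000L + a
      id <- sprintf("animal_%02d", a)
      sec <- simulate_section(sp, reduce_factor = reduce_factor,
                              tile_side_px = tile_side_px,
                              render_rgb = (quantify == "pipeline"),
                              label = id)
      if (quantify == "pipeline") {
        q <- quantify_section(sec$image, exclusion = sec$exclusion,
                              reduce_factor = reduce_factor,
                              tile_side_px = tile_side_px)
        map <- q$map
      } else {
        map <- sec$truth_map
      }
      hists[[id]] <- density_histogram(map, label = id)
      rows[[id]] <- data.frame(animal = id, group = groups[gi],
                               dose = dose_vals[gi],
                               coverage = sec$coverage_achieved,
                               Dm = mean_density(map))
      if (keep_sections) sections[[id]] <- sec
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  calibration <- calibrate_threshold(hists[table$animal[table$group == "control"]],
                                     cutoff = params$cutoff)
  table$HDFm <- vapply(table$animal,
                       function(id) hdf(hists[[id]], calibration$threshold_class),
                       numeric(1L))

  # covariates: logistic in achieved coverage, plus seeded noise
  set.seed((params$master_seed %% 2000000L) * 1000L + 999L)
  g <- .severity(table$coverage)
  ns <- params$covariate_noise
  n <- nrow(table)
  table$ashcroft_score <- pmin(pmax(round(8 * g + stats::rnorm(n, 0, ns$ashcroft)), 0), 8)
  table$microct_hu_peak <- -610 + 320 * g + stats::rnorm(n, 0, ns$microct)
  table$cdyn <- 0.030 - 0.014 * g + stats::rnorm(n, 0, ns$cdyn)
  table$fvc <- 1.15 - 0.45 * g + stats::rnorm(n, 0, ns$fvc)
  table$lung_wet_weight <- 0.15 + 0.12 * g + stats::rnorm(n, 0, ns$lww)
  table$body_weight <- 24 - 2 * g + stats::rnorm(n, 0, ns$bw)

  out <- list(table = table, calibration = calibration, histograms = hists,
              params = params, quantify = quantify)
  if (keep_sections) out$sections <- sections
  structure(out, class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study (%s route): %d animals, threshold class %d\n",
              x$quantify, nrow(x$table), x$calibration$threshold_class))
  agg <- stats::aggregate(x$table[, c("Dm", "HDFm")],
                          by = list(group = x$table$group), FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
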