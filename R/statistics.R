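#' Aggregate per-section indexes to per-animal rows
#'
#' Dm and HDFm can be expressed per lung section, per animal or per group;
#' the study table works per animal, averaging over each animal's sections.
#'
#' @param per_section data.frame with one row per section: column `animal`
#'   plus numeric index columns (typically `Dm`, `HDFm`) and optional
#'   constant-per-animal metadata columns (e.g. `group`, `dose`), which are
#'   carried through.
#' @param index_cols names of the numeric columns to average; default all
#'   numeric columns except `dose`.
#' @return data.frame with one row per animal (no duplicated ids), section
#'   counts in `n_sections`.
#' @export
aggregate_indexes <- function(per_section, index_cols = NULL) {
  stopifnot(is.data.frame(per_section), "animal" %in% names(per_section),
            nrow(per_section) >= 1L)
  if (is.null(index_cols)) {
    index_cols <- setdiff(names(per_section)[vapply(per_section, is.numeric,
                                                    TRUE)], "dose")
  }
  meta_cols <- setdiff(names(per_section), c("animal", index_cols))
  ids <- unique(per_section$animal)
  rows <- lapply(ids, function(id) {
    sec <- per_section[per_section$animal == id, , drop = FALSE]
    out <- data.frame(animal = id, n_sections = nrow(sec))
    for (mc in meta_cols) {
      v <- unique(sec[[mc]])
      if (length(v) != 1L)
        stop("metadata column ", dQuote(mc), " varies within animal ", id)
      out[[mc]] <- v
    }
    for (ic in index_cols) out[[ic]] <- mean(sec[[ic]])
    out
  })
  do.call(rbind, rows)
}

.stars <- function(p) {
  ifelse(p < 0.0001, "****",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Dose-response comparison of each group against control
#'
#' Parametric readouts are tested by one-way ANOVA followed by Dunnett's
#' multiple comparison test of every dose group against the control group
#' (multivariate-t critical values); nonparametric readouts (ordinal scores
#' such as Ashcroft) by the Kruskal-Wallis test followed by Dunn's multiple
#' comparison test, with Bonferroni adjustment over the control contrasts
#' only. Significance stars follow the usual thresholds
#' (`* < 0.05`, `** < 0.01`, `*** < 0.001`, `**** < 0.0001`).
#'
#' @param table per-animal data.frame (see [aggregate_indexes]) with a
#'   `group` column.
#' @param column name of the readout column to test.
#' @param control level of `group` that is the control; default `"control"`.
#' @param parametric `TRUE` for ANOVA + Dunnett, `FALSE` for
#'   Kruskal-Wallis + Dunn.
#' @return An object of class `dose_response_result`: data.frame `contrasts`
#'   (group, estimate, p, stars), `omnibus_p`, `test`.
#' @export
dose_response <- function(table, column, control = "control",
                          parametric = TRUE) {
  stopifnot(is.data.frame(table), "group" %in% names(table),
            column %in% names(table))
  g <- as.character(table$group)
  if (!control %in% g) stop("control group ", dQuote(control), " not found")
  y <- table[[column]]
  keep <- !is.na(y)
  y <- y[keep]; g <- g[keep]
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need at least two groups")
  if (any(sizes < 2L))
    stop("every group needs at least 2 observations")
  others <- setdiff(names(sizes), control)
  gf <- factor(g, levels = c(control, sort(others)))

  if (stats::var(y) == 0) {
    warning("constant readout ", dQuote(column), " across all groups; p = 1")
    contrasts <- data.frame(group = levels(gf)[-1L], estimate = 0,
                            p = 1, stars = "ns")
    res <- list(contrasts = contrasts, omnibus_p = 1,
                test = if (parametric) "anova_dunnett" else "kruskal_dunn",
                column = column)
    return(structure(res, class = "dose_response_result"))
  }

  if (parametric) {
    fit <- stats::aov(y ~ gf)
    omnibus_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    dn <- multcomp::glht(fit, linfct = multcomp::mcp(gf = "Dunnett"))
    sm <- summary(dn)
    contrasts <- data.frame(group = levels(gf)[-1L],
                            estimate = as.numeric(sm$test$coefficients),
                            p = as.numeric(sm$test$pvalues))
    test <- "anova_dunnett"
  } else {
    omnibus_p <- stats::kruskal.test(y, gf)$p.value
    dn <- .dunn_vs_control(y, gf)
    contrasts <- data.frame(group = levels(gf)[-1L],
                            estimate = dn$estimate, p = dn$p)
    test <- "kruskal_dunn"
  }
  contrasts$stars <- .stars(contrasts$p)
  structure(list(contrasts = contrasts, omnibus_p = omnibus_p, test = test,
                 column = column),
            class = "dose_response_result")
}

# Dunn's z contrasts of each non-control level against the first level of gf,
# with tie correction and Bonferroni adjustment over the control contrasts.
.dunn_vs_control <- function(y, gf) {
  N <- length(y)
  r <- rank(y)
  ties <- table(y)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(r, gf, mean)
  n <- tapply(r, gf, length)
  k <- nlevels(gf) - 1L
  est <- rbar[-1L] - rbar[1L]
  z <- est / sqrt(v0 * (1 / n[-1L] + 1 / n[1L]))
  p <- pmin(1, k * 2 * stats::pnorm(-abs(z)))
  list(estimate = as.numeric(est), p = as.numeric(p))
}

#' @export
print.dose_response_result <- function(x, ...) {
  cat(sprintf("dose_response_result [%s] on %s: omnibus p = %.3g\n",
              x$test, x$column, x$omnibus_p))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Correlate an index with an external readout
#'
#' Spearman rank correlation (tie-corrected asymptotic p-value) between two
#' study-table columns, with the ordinary least-squares slope and intercept
#' of `y ~ x` for plotting the regression line. The regression p-value is
#' reported alongside since the rank and linear analyses answer slightly
#' different questions.
#'
#' @param table per-animal data.frame.
#' @param x,y column names. Missing pairs are dropped pairwise.
#' @return An object of class `correlation_result`: `r` (Spearman), `p`,
#'   `slope`, `intercept`, `lm_p`, `n`, `x`, `y`.
#' @export
correlate <- function(table, x, y) {
  stopifnot(is.data.frame(table), x %in% names(table), y %in% names(table))
  xv <- table[[x]]; yv <- table[[y]]
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3L) stop("need at least 3 paired non-missing values")
  if (stats::var(xv) == 0 || stats::var(yv) == 0)
    stop("undefined correlation: zero-variance column")
  ct <- suppressWarnings(stats::cor.test(xv, yv, method = "spearman",
                                         exact = FALSE))
  fit <- stats::lm(yv ~ xv)
  # suppress the "essentially perfect fit" note for exactly collinear input
  lm_p <- suppressWarnings(summary(fit)$coefficients[2L, 4L])
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 lm_p = lm_p, n = length(xv), x = x, y = y),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result %s ~ %s: Spearman r = %.3f (p = %.3g), n = %d\n",
              x$y, x$x, x$r, x$p, x$n))
  cat(sprintf("  linear fit: slope %.4g, intercept %.4g (p = %.3g)\n",
              x$slope, x$intercept, x$lm_p))
  invisible(x)
}

#' Percent change of a treated group mean over the control mean
#'
#' `100 * (treated - control) / control`; the scale on which the two indexes
#' are compared as discriminators of fibrosis.
#'
#' @param control_mean control group mean (> 0).
#' @param treated_mean treated group mean.
#' @return percent change (may be negative).
#' @export
percent_change <- function(control_mean, treated_mean) {
  if (any(control_mean <= 0)) stop("control_mean must be positive")
  100 * (treated_mean - control_mean) / control_mean
}
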