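test_that("per-animal aggregation averages sections and keeps metadata", {
  ps <- data.frame(animal = c("a1", "a1"), group = "control",
                   Dm = c(0.30, 0.34), HDFm = c(0.01, 0.02))
  agg <- aggregate_indexes(ps)
  expect_equal(agg$Dm, 0.32)
  expect_equal(agg$HDFm, 0.015)
  expect_identical(agg$n_sections, 2L)

  single <- aggregate_indexes(data.frame(animal = "b", Dm = 0.4))
  expect_equal(single$Dm, 0.4)

  # 3 animals x 3 sections against a loop oracle
  set.seed(61)
  ps3 <- data.frame(animal = rep(c("x", "y", "z"), each = 3),
                    Dm = runif(9), HDFm = runif(9, 0, 0.2))
  agg3 <- aggregate_indexes(ps3)
  for (id in c("x", "y", "z")) {
    acc <- 0; n <- 0
    for (i in seq_len(nrow(ps3))) if (ps3$animal[i] == id) {
      acc <- acc + ps3$Dm[i]; n <- n + 1
    }
    expect_equal(agg3$Dm[agg3$animal == id], acc / n)
  }

  expect_error(aggregate_indexes(data.frame(animal = c("a", "a"),
                                            group = c("g1", "g2"),
                                            Dm = c(1, 1))),
               "varies within animal")
})

test_that("Dunnett contrasts flag an overwhelming dose effect", {
  set.seed(62)
  tab <- data.frame(
    animal = sprintf("a%02d", 1:24),
    group = rep(c("control", "dose"), each = 12),
    Dm = c(rnorm(12, 0.25, 0.01), rnorm(12, 0.40, 0.01)))
  dr <- dose_response(tab, "Dm")
  expect_lt(dr$contrasts$p, 0.0001)
  expect_identical(dr$contrasts$stars, "****")
  expect_lt(dr$omnibus_p, 0.0001)

  # permutation oracle: the observed mean difference is never matched under
  # label shuffling
  obs <- diff(tapply(tab$Dm, tab$group, mean))
  perm <- replicate(2000, {
    g <- sample(tab$group)
    abs(diff(tapply(tab$Dm, g, mean)))
  })
  expect_true(all(perm < abs(obs)))
})

test_that("identical and constant groups yield null results", {
  vals <- rep(c(0.2, 0.25, 0.3, 0.35), 2)
  tab <- data.frame(animal = sprintf("a%d", 1:8),
                    group = rep(c("control", "d1"), each = 4),
                    Dm = c(vals[1:4], vals[1:4]))
  dr <- dose_response(tab, "Dm")
  expect_gt(dr$contrasts$p, 0.9)
  expect_identical(dr$contrasts$stars, "ns")

  const <- data.frame(animal = sprintf("a%d", 1:8),
                      group = rep(c("control", "d1"), each = 4), Dm = 0.3)
  expect_warning(drc <- dose_response(const, "Dm"), "constant")
  expect_equal(drc$contrasts$p, 1)

  expect_error(dose_response(tab[c(1:4, 5), ], "Dm"), "at least 2")
  expect_error(dose_response(tab, "Dm", control = "saline"), "not found")
})

test_that("Dunn contrasts agree with a direct rank-statistic computation", {
  set.seed(63)
  tab <- data.frame(
    animal = sprintf("a%02d", 1:30),
    group = rep(c("control", "d1", "d2"), each = 10),
    score = c(sample(0:2, 10, TRUE), sample(2:5, 10, TRUE),
              sample(5:8, 10, TRUE)))
  dr <- dose_response(tab, "score", parametric = FALSE)
  expect_identical(dr$test, "kruskal_dunn")

  # from-scratch oracle: pooled ranks, tie-corrected variance, Bonferroni x2
  r <- rank(tab$score)
  N <- 30
  ties <- table(tab$score)
  v0 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  for (gi in c("d1", "d2")) {
    z <- (mean(r[tab$group == gi]) - mean(r[tab$group == "control"])) /
      sqrt(v0 * (1 / 10 + 1 / 10))
    p <- min(1, 2 * 2 * pnorm(-abs(z)))
    expect_equal(dr$contrasts$p[dr$contrasts$group == gi], p)
  }

  # adjusted p-values never undercut the unadjusted pairwise p-value
  for (gi in c("d1", "d2")) {
    z <- (mean(r[tab$group == gi]) - mean(r[tab$group == "control"])) /
      sqrt(v0 * (1 / 10 + 1 / 10))
    expect_gte(dr$contrasts$p[dr$contrasts$group == gi],
               2 * pnorm(-abs(z)) - 1e-12)
  }
})

test_that("family-wise error of Dunnett contrasts is controlled under the null", {
  set.seed(64)
  any_sig <- replicate(1000, {
    tab <- data.frame(animal = 1:15,
                      group = rep(c("control", "d1", "d2"), each = 5),
                      y = rnorm(15))
    min(dose_response(tab, "y")$contrasts$p) < 0.05
  })
  expect_lte(mean(any_sig), 0.07)
})

test_that("Spearman correlation matches the rank-formula oracle", {
  tab <- data.frame(x = 1:10, y = 1:10)
  expect_equal(correlate(tab, "x", "y")$r, 1.0)
  expect_equal(correlate(data.frame(x = 1:10, y = -(1:10)), "x", "y")$r, -1.0)

  set.seed(65)
  n <- 54
  x <- sample(seq_len(n))           # tie-free
  y <- sample(seq_len(n))
  res <- correlate(data.frame(x = x, y = y), "x", "y")
  d <- rank(x) - rank(y)
  rs <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
  expect_equal(res$r, rs, tolerance = 1e-12)

  # invariance under strictly monotone transforms
  tr <- correlate(data.frame(x = exp(x / 10), y = y^3), "x", "y")
  expect_equal(tr$r, rs, tolerance = 1e-12)

  # OLS slope/intercept come from the standard normal equations
  fit <- stats::lm(y ~ x)
  expect_equal(res$slope, unname(coef(fit)[2]))
  expect_equal(res$intercept, unname(coef(fit)[1]))

  expect_error(correlate(data.frame(x = 1:2, y = 1:2), "x", "y"), "at least 3")
  expect_error(correlate(data.frame(x = rep(1, 5), y = 1:5), "x", "y"),
               "zero-variance")
})

test_that("percent change is plain arithmetic on group means", {
  expect_equal(percent_change(0.25, 0.25), 0)
  expect_equal(percent_change(0.20, 0.28), 40)
  expect_equal(percent_change(0.04, 0.48), 1100)
  expect_error(percent_change(0, 1), "positive")
})
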