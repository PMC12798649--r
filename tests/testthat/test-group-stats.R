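test_that("medians by grouping match order statistics", {
  ft <- data.frame(region_id = sprintf("r%d", 1:7),
                   domain_id = c("a", "a", "b", "b", "c", "c", "c"),
                   category = "x",
                   lobe = "frontal", hemisphere = "L",
                   r2 = c(0.2, 0.8, 0.5, 0.5, 0.1, 0.9, 0.5),
                   stringsAsFactors = FALSE)
  med <- median_by(ft, "domain", n_boot = 50, seed = 1)
  expect_equal(med$median[med$domain == "a"], 0.5)
  expect_equal(med$median[med$domain == "c"], 0.5)
  expect_true(all(med$boot_se >= 0))
  single <- median_by(ft[3, ], "domain", n_boot = 10)
  expect_equal(single$median, 0.5)
  expect_error(median_by(ft, "nope"))
})

test_that("arcsine-sqrt transform maps [0,1] to [0, pi/2] monotonically", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.25), pi / 6, tolerance = 1e-12)
  x <- withr::with_seed(41, sort(runif(50)))
  expect_true(all(diff(arcsine_sqrt(x)) > 0))
  expect_error(arcsine_sqrt(1.1), "outside")
})

test_that("one-way ANOVA reproduces the hand decomposition", {
  res <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$ss_between, 13.5)
  expect_equal(res$ss_within, 4)
  expect_equal(res$f_stat, 13.5)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  expect_equal(res$eta_squared, 13.5 / 17.5, tolerance = 1e-12)

  flat <- one_way_anova(rep(c(1, 2), 4), rep(c("a", "b"), each = 4))
  expect_equal(flat$f_stat, 0)
  expect_equal(flat$eta_squared, 0)

  expect_error(one_way_anova(1:3, c("a", "a", "b")), "at least 2")
})

test_that("sum-of-squares identity and eta-squared identity hold on random data", {
  for (s in 1:10) {
    withr::with_seed(500 + s, {
      g <- sample(letters[1:5], 60, replace = TRUE)
      y <- rnorm(60) + as.integer(factor(g)) * 0.3
    })
    if (any(table(g) < 2)) next
    res <- one_way_anova(y, g)
    sst <- sum((y - mean(y))^2)
    expect_equal(res$ss_between + res$ss_within, sst, tolerance = 1e-8)
    expect_equal(res$eta_squared,
                 eta_squared_from_f(res$f_stat, res$df_between,
                                    res$df_within),
                 tolerance = 1e-10)
    expect_true(res$eta_squared >= 0 && res$eta_squared <= 1)
  }
})

test_that("pairwise t-tests cover all pairs with pooled-variance effect sizes", {
  vals <- c(1, 2, 3, 2, 3, 4)
  grp <- rep(c("a", "b"), each = 3)
  ct <- pairwise_t_tests(vals, grp)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$cohen_d, -1)
  expect_equal(ct$t_stat, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(ct$df, 4)

  # identical groups: t = 0, d = 0, p = 1
  same <- pairwise_t_tests(c(1, 2, 3, 1, 2, 3), grp)
  expect_equal(same$t_stat, 0)
  expect_equal(same$cohen_d, 0)
  expect_equal(same$p_raw, 1)

  # seven categories emit all 21 contrasts
  withr::with_seed(61, {
    g7 <- rep(paste0("c", 1:7), each = 5)
    v7 <- rnorm(35)
  })
  ct7 <- pairwise_t_tests(v7, g7)
  expect_equal(nrow(ct7), choose(7, 2))
  expect_true(all(ct7$p_holm >= ct7$p_raw))

  # Welch variant reports fractional df
  w <- pairwise_t_tests(c(vals, 10), c(grp, "b"), var_equal = FALSE)
  expect_equal(w$test_kind, "independent")
})

test_that("Holm adjustment is the step-down with running maximum", {
  expect_equal(holm_adjust(0.02), 0.02)
  expect_equal(holm_adjust(c(0.001, 0.02, 0.04)), c(0.003, 0.04, 0.04))
  p <- withr::with_seed(71, runif(15))
  h <- holm_adjust(p)
  # monotone in raw rank, dominated by Bonferroni, capped at 1
  expect_true(all(h[order(p)] == cummax(h[order(p)])))
  expect_true(all(h <= pmin(1, p * length(p)) + 1e-15))
  expect_true(all(h <= 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("laterality tests pair homologous regions across hemispheres", {
  parc <- toy_parcellation(rep(5, 8))   # 8 homolog pairs of 5 vertices
  m <- sum(parc$region_meta$modeled) / 2
  base <- withr::with_seed(81, runif(m, 0.3, 0.9))

  # antisymmetric LH-RH differences: mean difference exactly 0 -> t = 0
  delta <- c(0.05, -0.05, 0.02, -0.02, 0.04, -0.04, 0, 0)
  ft <- data.frame(
    region_id = c(sprintf("L%02d", 1:m), sprintf("R%02d", 1:m)),
    domain_id = "domain_01",
    category = "language", lobe = "frontal",
    hemisphere = rep(c("L", "R"), each = m),
    r2 = c(base + delta, base),
    stringsAsFactors = FALSE)
  ft$r2_transformed <- ft$r2    # compare on the raw scale for the oracle
  lat <- laterality_tests(ft, "domain_01", parc, value = "r2")
  expect_equal(lat$t_stat, 0, tolerance = 1e-12)
  expect_equal(lat$p_raw, 1, tolerance = 1e-12)
  expect_equal(lat$df, m - 1)
  expect_equal(lat$n_pairs, m)

  # constant LH-RH shift: zero-variance difference is an explicit error
  ft_shift <- ft
  ft_shift$r2 <- c(base + 0.1, base)
  expect_error(laterality_tests(ft_shift, "domain_01", parc, value = "r2"),
               "zero-variance difference")

  expect_error(laterality_tests(ft, "missing_domain", parc), "unknown domain")
})

test_that("full-design laterality uses 41 homolog pairs hence df = 40", {
  parc <- make_parcellation(synthetic_config(n_vertices = 890))
  m <- 41
  withr::with_seed(91, {
    lh <- runif(m, 0.4, 0.95)
    rh <- lh + rnorm(m, sd = 0.05)
  })
  ft <- data.frame(
    region_id = c(sprintf("L%02d", 1:m), sprintf("R%02d", 1:m)),
    domain_id = "language",
    category = "language", lobe = "frontal",
    hemisphere = rep(c("L", "R"), each = m),
    r2 = pmin(pmax(c(lh, rh), 0), 1), stringsAsFactors = FALSE)
  ft$r2_transformed <- arcsine_sqrt(ft$r2)
  lat <- laterality_tests(ft, "language", parc)
  expect_equal(lat$df, 40)
  expect_equal(lat$test_kind, "paired")
})

test_that("a planted hemispheric gap is detected with near-certain power", {
  # gap 0.1 with diff SD 0.1 over 41 pairs: noncentral-t power > 0.99
  m <- 41
  ncp <- 0.1 / (0.1 / sqrt(m))
  crit <- qt(0.975, df = m - 1)
  power <- 1 - pt(crit, df = m - 1, ncp = ncp) +
    pt(-crit, df = m - 1, ncp = ncp)
  expect_gt(power, 0.99)

  parc <- make_parcellation(synthetic_config(n_vertices = 890))
  rejections <- vapply(1:20, function(s) {
    withr::with_seed(900 + s, {
      rh <- runif(m, 0.3, 0.6)
      lh <- rh + rnorm(m, mean = 0.1, sd = 0.1)
    })
    ft <- data.frame(
      region_id = c(sprintf("L%02d", 1:m), sprintf("R%02d", 1:m)),
      domain_id = "reading", category = "language", lobe = "frontal",
      hemisphere = rep(c("L", "R"), each = m),
      r2 = pmin(pmax(c(lh, rh), 0), 1), stringsAsFactors = FALSE)
    ft$r2_transformed <- ft$r2
    laterality_tests(ft, "reading", parc, value = "r2")$p_raw < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})
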