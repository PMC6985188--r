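test_that("star tiers follow the figure-legend convention", {
  expect_identical(significance_tier(c(0.2, 0.049, 0.009, 0.0049, 0.0009)),
                   c("n.s.", "*", "**", "***", "****"))
  expect_identical(significance_tier(0.05), "n.s.")
})

test_that("ANOVA degenerate and algebraic identities hold", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- one_way_anova_tukey(g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  # two groups: F equals the square of the pooled two-sample t statistic
  set.seed(3)
  a <- rnorm(12, 10, 2); b <- rnorm(9, 11, 2)
  res2 <- one_way_anova_tukey(list(a = a, b = b))
  t2 <- two_sample_t(a, b)
  expect_equal(res2$F, t2$t^2, tolerance = 1e-12)
  expect_equal(res2$p, t2$p, tolerance = 1e-12)

  expect_error(one_way_anova_tukey(list(a = 1, b = c(2, 3))), "at least 2")
  expect_error(one_way_anova_tukey(list(a = c(1, 1), b = c(1, 1))),
               "zero residual variance")
})

test_that("ANOVA and Tukey match an independent sums-of-squares oracle", {
  set.seed(11)
  for (rep in 1:5) {
    groups <- list(g1 = rnorm(sample(4:12, 1), 10, 2),
                   g2 = rnorm(sample(4:12, 1), 12, 2),
                   g3 = rnorm(sample(4:12, 1), 9, 2),
                   g4 = rnorm(sample(4:12, 1), 10, 2))
    mine <- one_way_anova_tukey(groups)
    oracle <- anova_tukey_oracle(groups)
    expect_equal(mine$F, oracle$F, tolerance = 1e-6)
    expect_equal(mine$p, oracle$p, tolerance = 1e-6)
    ord <- match(mine$tukey$comparison, names(oracle$tukey))
    expect_false(any(is.na(ord)))
    expect_equal(mine$tukey$p_adj, unname(oracle$tukey[ord]),
                 tolerance = 1e-6)
  }
})

test_that("Tukey adjustment is never anti-conservative", {
  set.seed(21)
  for (rep in 1:10) {
    groups <- lapply(1:4, function(i) rnorm(sample(3:10, 1), i / 2, 1.5))
    names(groups) <- paste0("g", 1:4)
    res <- one_way_anova_tukey(groups)
    # unadjusted pairwise p on the same pooled error as the Tukey procedure
    ns <- lengths(groups); N <- sum(ns); k <- length(groups)
    msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                      numeric(1))) / (N - k)
    for (cmp in seq_len(nrow(res$tukey))) {
      gs <- strsplit(res$tukey$comparison[cmp], "-")[[1]]
      se <- sqrt(msw * (1 / ns[[gs[1]]] + 1 / ns[[gs[2]]]))
      tstat <- abs(mean(groups[[gs[1]]]) - mean(groups[[gs[2]]])) / se
      raw <- 2 * pt(tstat, N - k, lower.tail = FALSE)
      expect_gte(res$tukey$p_adj[cmp] + 1e-12, raw)
    }
  }
})

test_that("the t test is symmetric and guards degenerate input", {
  a <- c(1, 2, 3, 4)
  res <- two_sample_t(a, a)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  b <- c(2, 3, 5, 6)
  r1 <- two_sample_t(a, b); r2 <- two_sample_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero variance")
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
  # Welch variant exposed
  rw <- two_sample_t(a, c(b, 20), var_equal = FALSE)
  expect_true(is.finite(rw$p))
})

test_that("t test matches stats::t.test to numerical precision", {
  set.seed(8)
  a <- rnorm(15, 5, 1); b <- rnorm(11, 5.8, 1.4)
  mine <- two_sample_t(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
})

test_that("modality consistency separates constant from nonlinear ratios", {
  x <- seq(50, 140, length.out = 20)
  res <- modality_consistency(x, 0.5 * x)
  expect_equal(res$slope, 0.5, tolerance = 1e-12)
  expect_equal(res$ratio_cv, 0)
  expect_identical(res$verdict, "consistent")

  nl <- modality_consistency(x, x^2)
  expect_identical(nl$verdict, "inconsistent")

  expect_warning(res2 <- modality_consistency(c(x, -5), c(0.5 * x, 1)),
                 "dropping")
  expect_identical(res2$n_dropped, 1L)
  expect_error(suppressWarnings(modality_consistency(rep(-1, 12), rep(1, 12))),
               "all pairs dropped")
})

test_that("the modality control recovers the configured gain on 150 cells", {
  sp <- synthetic_well_spec(well_diameter = 300, n_cells = 150,
                            control_density = 0, min_separation_frac = 1.15,
                            noise_sd = 0, seed = 19)
  pair <- render_modality_pair(sp, gain = 0.5, extra_noise_sd = 1.5)
  px <- sp$pixel_size
  d1 <- subtract_background(pair$image1$channels$dapi, "flat_percentile", 25)
  rois <- segment_nuclei(d1, px)
  m1 <- nuclear_intensities(
    subtract_background(pair$image1$channels$tf1, "flat_percentile", 25), rois)
  m2 <- nuclear_intensities(
    subtract_background(pair$image2$channels$tf1, "flat_percentile", 25), rois)
  expect_identical(length(m1), 150L)
  rep <- modality_consistency(m1, m2)
  expect_lt(abs(rep$slope - 0.5) / 0.5, 0.05)
  expect_identical(rep$verdict, "consistent")
})

test_that("the scale-up arithmetic reproduces the per-patient culture area", {
  expect_equal(required_culture_area(6e5, 1000), 600)
  expect_error(required_culture_area(6e5, 0), "clusters_per_cm2")
})
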