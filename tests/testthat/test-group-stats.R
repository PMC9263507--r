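test_that("covariate residualization behaves like OLS and catches collinearity", {
  withr::with_seed(12, {
    cov <- random_covariates(30)
    # values uncorrelated with covariates: residuals ~ demeaned values
    v <- rnorm(30)
    r <- adjust_covariates(v, NULL)
    expect_equal(r, v - mean(v))
    # perfect linear dependence on age leaves nothing
    r2 <- adjust_covariates(2 * cov$age, cov)
    expect_true(all(abs(r2) < 1e-10))
    # residuals are orthogonal to the design
    v3 <- rnorm(30) + 0.5 * cov$age
    r3 <- adjust_covariates(v3, cov)
    expect_lt(abs(sum(r3 * cov$age)), 1e-8)
    # duplicated covariate column is rank-deficient and named
    bad <- data.frame(age = cov$age, age2 = cov$age)
    expect_error(adjust_covariates(v3, bad), "age2")
  })
})

test_that("pooled t-test matches hand-computed values and flips sign on swap", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  # pooled SD 1, se = sqrt(2/3), diff -3
  expect_equal(r$t, -3 / sqrt(2 / 3))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-abs(r$t), 4))

  # identical samples: degenerate convention
  r0 <- two_sample_t(c(1, 1, 1), c(1, 1, 1))
  expect_true(r0$degenerate)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  withr::with_seed(9, {
    a <- rnorm(10); b <- rnorm(12, 0.5)
    rf <- two_sample_t(a, b)
    rb <- two_sample_t(b, a)
    expect_equal(rb$t, -rf$t)
    expect_equal(rb$p, rf$p)
  })
})

test_that("covariate adjustment preserves the group contrast", {
  # planted model: value = group_effect + 0.5*age + noise; the adjusted
  # t should track the t of the noise-only model
  withr::with_seed(77, {
    diffs <- replicate(50, {
      cov <- random_covariates(48)
      eff <- c(rep(0.8, 24), rep(0, 24))
      noise <- rnorm(48)
      y <- eff + 0.5 * cov$age + noise
      t_adj <- compare_values(y[1:24], y[25:48],
                              cov[1:24, ], cov[25:48, ])$t
      t_oracle <- two_sample_t(eff[1:24] + noise[1:24],
                               eff[25:48] + noise[25:48])$t
      t_adj - t_oracle
    })
    expect_lt(mean(abs(diffs)), 0.2)
  })
})

test_that("Bonferroni correction is order-invariant, idempotent and bounded", {
  withr::with_seed(2, {
    p <- runif(20, 0, 0.2)
    m <- 90
    pb <- pmin(1, m * p)
    expect_true(all(pb >= p))
    expect_equal(pmin(1, 1 * pb), pb)          # idempotent at m = 1 re-pass
    perm <- sample(20)
    expect_equal(pmin(1, m * p[perm]), pb[perm])
    expect_equal(pmin(1, 90 * 0.01), 0.9)      # raw 0.01 is not corrected-significant
  })
})

test_that("nodal comparison detects planted deficits and requires covariates", {
  withr::with_seed(303, {
    co <- generate_cohort(cohort_config(
      seed = 303,
      effect_nodes = data.frame(node = 43, delta = -0.12, group = "HIV")))
    ga <- cohort_group(co, "HIV")
    gb <- cohort_group(co, "HC")
    tab <- nodal_comparison(ga$matrices[1:12], gb$matrices[1:12],
                            ga$covariates[1:12, ], gb$covariates[1:12, ],
                            metrics = c("ne", "bc"), atlas = aal90_atlas())
    hit <- tab[tab$metric == "ne" & tab$node == 43, ]
    expect_true(hit$significant_raw)
    expect_equal(hit$direction, "decreased")
    expect_equal(hit$label, "CAL.L")
    # Bonferroni family is the node count within a metric
    expect_equal(tab$p_bonf, pmin(1, 90 * tab$p))
    expect_error(nodal_comparison(ga$matrices[1:5], gb$matrices[1:5],
                                  NULL, NULL), "covariates")
  })
})

test_that("edge comparison flags planted shifts with the right direction and skips dead edges", {
  withr::with_seed(42, {
    eff <- data.frame(i = c(73, 67), j = c(74, 68),
                      delta = c(0.1, -0.1), group = c("HIV", "HIV"))
    co <- generate_cohort(cohort_config(seed = 42, effect_edges = eff))
    ga <- cohort_group(co, "HIV")
    gb <- cohort_group(co, "HC")
    pairs <- data.frame(i = c(73, 67, 1), j = c(74, 68, 90))
    # force a dead pair: zero the (1, 90) edge everywhere
    za <- lapply(ga$matrices, function(m) {
      w <- unclass(m); w[1, 90] <- w[90, 1] <- 0; connectivity_matrix(w)
    })
    zb <- lapply(gb$matrices, function(m) {
      w <- unclass(m); w[1, 90] <- w[90, 1] <- 0; connectivity_matrix(w)
    })
    tab <- edge_comparison(za, zb, pairs, ga$covariates, gb$covariates)
    expect_equal(tab$direction[1], "increased")
    expect_true(tab$significant_raw[1])
    expect_equal(tab$direction[2], "decreased")
    expect_true(tab$significant_raw[2])
    expect_true(tab$skipped[3])
    expect_true(is.na(tab$t[3]))
  })
})

test_that("the ANI classification rule counts impaired domains with an inclusive boundary", {
  means <- setNames(rep(50, 6), c("verbal_fluency", "attention_wm",
                                  "executive", "learning_recall", "speed",
                                  "fine_motor"))
  sds <- setNames(rep(10, 6), names(means))

  two_low <- means; two_low[c("speed", "fine_motor")] <- 50 - 12
  expect_equal(classify_ani(two_low, means, sds), "ANI_pattern")

  one_very_low <- means; one_very_low["speed"] <- 50 - 30
  expect_equal(classify_ani(one_very_low, means, sds), "normal")

  # boundary: all domains exactly at mean - 1 SD counts as impaired
  all_boundary <- means - 10
  expect_equal(classify_ani(all_boundary, means, sds), "ANI_pattern")

  # daily-living flag is an input, not computed
  expect_equal(classify_ani(two_low, means, sds,
                            daily_living_intact = FALSE), "normal")

  expect_error(classify_ani(two_low[-1], means, sds), "missing")
})

test_that("partial correlation residualizes covariates and reduces to Pearson without them", {
  withr::with_seed(5, {
    x <- rnorm(50); y <- 0.6 * x + rnorm(50, 0, 0.5)
    pc <- partial_correlation(x, y)
    expect_equal(pc$r, cor(x, y), tolerance = 1e-12)

    # y = x exactly: r = 1 whatever the covariates
    cov <- random_covariates(50)
    expect_equal(partial_correlation(x, x, cov)$r, 1)

    # shared covariate signal is removed
    age <- rnorm(500, 40, 10)
    x2 <- 2 * age + rnorm(500, 0, 1e-8)
    y2 <- rnorm(500)
    pc2 <- partial_correlation(x2, y2, data.frame(age = age))
    expect_lt(abs(pc2$r), 0.1)

    # known partial correlation is recovered at large n
    errs <- replicate(30, {
      n <- 1000
      cv <- data.frame(a = rnorm(n), b = rnorm(n))
      z <- rnorm(n)
      x3 <- z + rnorm(n) + 0.7 * cv$a
      y3 <- z + rnorm(n) - 0.4 * cv$b
      partial_correlation(x3, y3, cv)$r - 0.5
    })
    expect_lt(mean(abs(errs)), 0.06)

    expect_true(partial_correlation(rep(1, 20), rnorm(20))$degenerate)
  })
})
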