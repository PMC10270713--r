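# Covariate-adjusted contrasts, subgroup definitions and partial
# correlations.

test_that("residualization absorbs covariate effects and constants", {
  tab <- toy_table(n_per_group = 30, seed = 2)
  # values that are exactly 2*age leave ~zero residuals
  res <- adjust_for_covariates(2 * tab$age, tab)
  expect_lt(max(abs(res)), 1e-10)
  # adding a constant leaves residuals unchanged (intercept absorbs it)
  r1 <- adjust_for_covariates(tab$global_coupling, tab)
  r2 <- adjust_for_covariates(tab$global_coupling + 5, tab)
  expect_equal(as.numeric(r1), as.numeric(r2), tolerance = 1e-10)
  # zero-slope simulation: adjusted and unadjusted t statistics agree closely
  set.seed(4)
  tab$score0 <- rnorm(nrow(tab))
  t_adj <- pairwise_t(tab, "score0", c("NC", "AD"))$statistic
  t_raw <- pairwise_t(tab, "score0", c("NC", "AD"), covariates = NULL)$statistic
  expect_equal(t_adj, t_raw, tolerance = 0.15)
  expect_error(adjust_for_covariates(rnorm(3), tab[1:3, ]), "complete cases")
})

test_that("rank-deficient covariate designs are rejected", {
  tab <- toy_table(n_per_group = 10)
  tab$flat <- 1
  expect_error(adjust_for_covariates(tab$global_coupling, tab,
                                     c("age", "flat")), "rank-deficient")
  tab$mmse <- rnorm(nrow(tab))
  expect_error(clinical_correlations(tab, measures = "mmse",
                                     covariates = c("age", "flat")),
               "rank-deficient")
})

test_that("pairwise t equals a hand-computed pooled-variance t on a small fixture", {
  x1 <- c(0.71, 0.74, 0.69, 0.72, 0.73)
  x2 <- c(0.66, 0.70, 0.68, 0.65, 0.69)
  tab <- data.frame(group = rep(c("NC", "AD"), each = 5),
                    global_coupling = c(x1, x2))
  got <- pairwise_t(tab, groups = c("NC", "AD"), covariates = NULL)
  # oracle on centred values (residualization with no covariates centres)
  y1 <- x1 - mean(c(x1, x2)); y2 <- x2 - mean(c(x1, x2))
  sp2 <- (4 * var(y1) + 4 * var(y2)) / 8
  t_hand <- (mean(y1) - mean(y2)) / sqrt(sp2 * (2 / 5))
  expect_equal(got$statistic, t_hand, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_hand), 8), tolerance = 1e-12)
  # antisymmetry
  rev_ <- pairwise_t(tab, groups = c("AD", "NC"), covariates = NULL)
  expect_equal(rev_$statistic, -got$statistic)
  expect_equal(rev_$p, got$p)
  # identical groups give t = 0, p = 1
  same <- data.frame(group = rep(c("A", "B"), each = 5),
                     global_coupling = rep(x1, 2))
  eq <- pairwise_t(same, groups = c("A", "B"), covariates = NULL)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
})

test_that("ANOVA is order-invariant and calibrated under the null", {
  tab <- toy_table(n_per_group = 25, seed = 9)
  a1 <- group_anova(tab)
  a2 <- group_anova(tab[sample(nrow(tab)), ])
  expect_equal(a1$statistic, a2$statistic, tolerance = 1e-10)
  # type-I calibration at alpha = 0.05 over 200 null replicates
  set.seed(31)
  rej <- replicate(200, {
    tb <- data.frame(group = rep(c("NC", "MCI", "AD"), each = 20),
                     global_coupling = rnorm(60))
    group_anova(tb, covariates = NULL)$p < 0.05
  })
  ci <- qbinom(c(0.025, 0.975), 200, 0.05)
  expect_true(sum(rej) >= ci[1] && sum(rej) <= ci[2])
})

test_that("the study-condition group means separate at n = 60 per group", {
  # power simulation: means 0.72/0.71/0.68, sd 0.04
  set.seed(55)
  hits <- replicate(100, {
    tb <- toy_table(n_per_group = 60,
                    means = c(NC = 0.72, MCI = 0.71, AD = 0.68), sd = 0.04,
                    seed = sample.int(1e6, 1))
    group_anova(tb)$p < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("region-wise contrast flags by the Bonferroni threshold and recovers planted effects", {
  # threshold arithmetic
  set.seed(71)
  n <- 40
  tab <- data.frame(group = rep(c("NC", "AD"), each = n),
                    age = rnorm(2 * n, 73, 7),
                    sex = sample(c("M", "F"), 2 * n, replace = TRUE))
  for (k in 1:246) tab[[paste0("local_", k)]] <- rnorm(2 * n)
  lc <- local_contrast(tab, c("NC", "AD"))
  expect_equal(lc$p_threshold, 0.05 / 246)
  expect_equal(lc$regions$significant, lc$regions$p < 2.0325e-4 +
                 .Machine$double.eps)
  expect_equal(nrow(lc$regions), 246)
  # vectorized t matches the scalar pairwise_t path per region
  t3 <- pairwise_t(tab, "local_3", c("NC", "AD"))$statistic
  expect_equal(lc$regions$t[3], t3, tolerance = 1e-10)
  # planted effects in 5 regions rank in the top 10 by |t|
  set.seed(72)
  hit <- replicate(20, {
    n2 <- 100
    tb <- data.frame(group = rep(c("NC", "AD"), each = n2),
                     age = rnorm(2 * n2, 73, 7),
                     sex = sample(c("M", "F"), 2 * n2, replace = TRUE))
    for (k in 1:60) tb[[paste0("local_", k)]] <- rnorm(2 * n2)
    for (k in 1:5)
      tb[[paste0("local_", k)]] <- tb[[paste0("local_", k)]] +
        1.2 * (tb$group == "NC")
    r <- local_contrast(tb, c("NC", "AD"))$regions
    top10 <- r$region[order(-abs(r$t))][1:10]
    all(as.character(1:5) %in% top10)
  })
  expect_gte(mean(hit), 0.90)
})

test_that("family-wise error under Bonferroni stays at or below alpha in null simulations", {
  set.seed(81)
  fwer_hits <- replicate(200, {
    n <- 25
    tb <- data.frame(group = rep(c("NC", "AD"), each = n))
    for (k in 1:246) tb[[paste0("local_", k)]] <- rnorm(2 * n)
    any(local_contrast(tb, c("NC", "AD"), covariates = NULL)$regions$significant)
  })
  # binomial 95% upper band around 0.05
  expect_lte(mean(fwer_hits), qbinom(0.975, 200, 0.05) / 200)
})

test_that("biomarker subgroup statuses follow the strict CSF thresholds", {
  tab <- data.frame(csf_abeta = c(900, 980, 1100, NA),
                    csf_tau = c(245, 246, 100, NA))
  out <- biomarker_subgroups(tab)
  expect_equal(out$abeta_status, c("positive", "negative", "negative", NA))
  expect_equal(out$tau_status, c("negative", "positive", "negative", NA))
  expect_error(biomarker_subgroups(data.frame(csf_abeta = -5)), "negative")
})

test_that("partial correlations recover planted clinical slopes and stay calibrated under the null", {
  set.seed(91)
  n <- 500
  tab <- data.frame(age = rnorm(n, 73, 7),
                    sex = sample(c("M", "F"), n, replace = TRUE),
                    global_coupling = rnorm(n, 0.71, 0.04))
  tab$mmse <- 27 + 40 * (tab$global_coupling - 0.7) + rnorm(n, 0, 5.5)
  cors <- clinical_correlations(tab, measures = "mmse")
  expect_gt(cors$r, 0)
  expect_true(cors$significant)   # thresholded at 0.05/1 here
  expect_equal(attr(cors, "p_threshold"), 0.05)
  # null calibration of the flag rate at the 9-measure Bonferroni threshold
  set.seed(92)
  flags <- replicate(200, {
    tb <- data.frame(age = rnorm(80, 73, 7),
                     sex = sample(c("M", "F"), 80, replace = TRUE),
                     global_coupling = rnorm(80),
                     mmse = rnorm(80))
    clinical_correlations(tb, measures = "mmse")$p < 0.05 / 9
  })
  expect_lte(mean(flags), qbinom(0.995, 200, 0.05 / 9) / 200)
  expect_error(clinical_correlations(tab[1:3, ], measures = "mmse"),
               "complete cases|fewer than 4")
})

test_that("missing measure values are dropped listwise per analysis", {
  set.seed(93)
  n <- 60
  tab <- data.frame(age = rnorm(n, 73, 7),
                    sex = sample(c("M", "F"), n, replace = TRUE),
                    global_coupling = rnorm(n, 0.7, 0.04),
                    mmse = rnorm(n, 27, 2))
  tab$mmse[1:10] <- NA
  cors <- clinical_correlations(tab, measures = "mmse")
  expect_equal(cors$n, 50)
})
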