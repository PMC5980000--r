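test_that("Bonferroni thresholds truncate to four decimals", {
  expect_equal(as.numeric(bonferroni_threshold(0.05, 36)), 0.0013)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 14)), 0.0035)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 1)), 0.05)
  expect_equal(attr(bonferroni_threshold(0.05, 36), "raw"), 0.05 / 36)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("the normality gate routes to the right test branch", {
  # deterministic Gaussian-quantile groups pass the gate -> parametric
  g1 <- gaussian_quantile_sample(40, 0, 1)
  g2 <- gaussian_quantile_sample(40, 0.5, 1)
  expect_match(choose_test(c(g1, g2), rep(c("a", "b"), each = 40)),
               "t-test|welch-t")
  g3 <- gaussian_quantile_sample(40, 1, 1)
  expect_equal(choose_test(c(g1, g2, g3), rep(c("a", "b", "c"), each = 40)),
               "anova")
  # unequal variances on normal data -> Welch
  g2w <- gaussian_quantile_sample(40, 0, 6)
  expect_equal(choose_test(c(g1, g2w), rep(c("a", "b"), each = 40)),
               "welch-t")
  # continuous target -> regression
  expect_equal(choose_test(rnorm(50), seq_len(50) + 0.5),
               "linear-regression")
  expect_error(choose_test(rnorm(5), c("a", "a", "a", "b", "b")),
               "insufficient")
})

test_that("uniform data at n=200 is routed non-parametrically", {
  set.seed(42)
  nonpar <- 0
  for (i in 1:100) {
    v <- stats::runif(400)
    g <- rep(c("a", "b"), each = 200)
    if (choose_test(v, g) == "mann-whitney") nonpar <- nonpar + 1
  }
  expect_gte(nonpar, 95)
})

test_that("screening assigns tiers and flags degenerate features", {
  set.seed(7)
  n <- 120
  X <- cbind(strong = c(rnorm(n / 2), rnorm(n / 2, 1.5)),
             null = rnorm(n),
             flat = rep(1, n))
  g <- factor(rep(c("a", "b"), each = n / 2))
  res <- screen_features(X, target = "grp", target_values = g)
  expect_equal(res$tier[res$feature == "strong"], "***")
  expect_true(res$degenerate[res$feature == "flat"])
  expect_equal(res$p_value[res$feature == "flat"], 1)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(attr(res, "bonferroni"), floor(0.05 / 3 * 1e4) / 1e4)
})

test_that("tiers never strengthen as the family grows", {
  set.seed(11)
  n <- 80
  x <- c(rnorm(n / 2), rnorm(n / 2, 0.9))
  g <- factor(rep(c("a", "b"), each = n / 2))
  ranks <- c(none = 0, `*` = 1, `**` = 2, `***` = 3)
  tier_m <- function(m) {
    X <- cbind(x, matrix(rnorm(n * (m - 1)), n))
    colnames(X) <- paste0("f", seq_len(m))
    res <- screen_features(X, target = "g", target_values = g)
    ranks[[res$tier[1]]]
  }
  expect_true(tier_m(1) >= tier_m(12))
  expect_true(tier_m(12) >= tier_m(36))
})

test_that("ANCOVA leaves clean effects alone and kills confounded ones", {
  set.seed(3)
  ok <- 0
  for (i in 1:50) {
    n <- 150
    g <- factor(rep(c("a", "b"), each = n / 2))
    cov <- data.frame(age = rnorm(n), psa = rnorm(n), wt = rnorm(n))
    y <- 0.6 * (g == "b") + rnorm(n)
    p_adj <- ancova_adjust(y, g, cov)
    p_raw <- stats::t.test(y ~ g, var.equal = TRUE)$p.value
    if (abs(log10(p_adj) - log10(p_raw)) < 0.5) ok <- ok + 1
  }
  expect_gte(ok, 40)

  killed <- 0
  for (i in 1:50) {
    n <- 150
    g <- factor(rep(c("a", "b"), each = n / 2))
    conf <- 1.5 * (g == "b") + rnorm(n, 0, 0.5)  # covariate tracks group
    y <- conf + rnorm(n, 0, 0.5)                 # feature driven by covariate
    cov <- data.frame(age = conf, psa = rnorm(n), wt = rnorm(n))
    p_adj <- ancova_adjust(y, g, cov)
    p_raw <- stats::t.test(y ~ g, var.equal = TRUE)$p.value
    if (p_adj > 0.05 && p_raw < 0.05) killed <- killed + 1
  }
  expect_gte(killed, 40)

  expect_error(ancova_adjust(rnorm(20), rep(c("a", "b"), 10),
                             data.frame(a = 1:20, b = (1:20) * 2)),
               "collinear")
})

test_that("ANCOVA p-values are uniform under the null", {
  set.seed(5)
  ps <- sapply(1:300, function(i) {
    n <- 60
    g <- factor(rep(c("a", "b"), each = n / 2))
    ancova_adjust(rnorm(n), g, data.frame(age = rnorm(n), psa = rnorm(n)))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the mixed-model check collapses to the ordinary test when unclustered", {
  set.seed(8)
  n <- 40
  y <- rnorm(n)
  g <- factor(rep(c("a", "b"), each = n / 2))
  pid <- sprintf("P%02d", seq_len(n))
  p_mixed <- repeated_measures_check(y, g, pid)
  p_lm <- stats::anova(stats::lm(y ~ g))[1, "Pr(>F)"]
  expect_equal(as.numeric(p_mixed), p_lm, tolerance = 1e-6)
  expect_equal(attr(p_mixed, "method"), "aggregated")
})

test_that("duplicating every sample fools the naive test but not the mixed model", {
  set.seed(12)
  n <- 30
  y <- rnorm(n, mean = rep(c(0, 0.5), each = n / 2))
  g <- factor(rep(c("a", "b"), each = n / 2))
  pid <- sprintf("P%02d", seq_len(n))
  p0 <- stats::anova(stats::lm(y ~ g))[1, "Pr(>F)"]
  idx <- rep(seq_len(n), each = 3)
  p_mix <- repeated_measures_check(y[idx], g[idx], pid[idx])
  p_naive <- stats::anova(stats::lm(y[idx] ~ g[idx]))[1, "Pr(>F)"]
  expect_lt(abs(as.numeric(p_mix) - p0), 0.02)
  expect_lt(p_naive, p0)
})

test_that("strong patient clustering inflates the naive test only", {
  set.seed(19)
  naive_fp <- mixed_fp <- 0
  n_pat <- 16
  for (i in 1:100) {
    b <- rnorm(n_pat, 0, 1.5)                  # patient intercepts
    pid <- rep(sprintf("P%02d", 1:n_pat), each = 4)
    g <- factor(rep(rep(c("a", "b"), each = n_pat / 2), each = 4))
    y <- b[rep(1:n_pat, each = 4)] + rnorm(n_pat * 4, 0, 0.5)
    if (stats::anova(stats::lm(y ~ g))[1, "Pr(>F)"] < 0.05)
      naive_fp <- naive_fp + 1
    if (as.numeric(repeated_measures_check(y, g, pid)) < 0.05)
      mixed_fp <- mixed_fp + 1
  }
  expect_gt(naive_fp, mixed_fp)
  expect_lte(mixed_fp, 15)
})

test_that("screen target derivation covers the study contrasts", {
  coh <- generate_cohort(n_patients = 40, seed = 6, render = FALSE)
  rec <- coh$records
  expect_s3_class(derive_target(rec, "pgg_group"), "factor")
  agg <- derive_target(rec, "aggressiveness")
  expect_true(all(is.na(agg[rec$pgg %in% c(4, 5)])))
  expect_error(derive_target(rec, "nonsense"), "valid targets")
})
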