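test_that("the cohort is a pure function of configuration and seed", {
  a <- generate_cohort(n_patients = 20, seed = 9, render = FALSE)
  b <- generate_cohort(n_patients = 20, seed = 9, render = FALSE)
  expect_identical(a$records, b$records)
  expect_identical(a$intensities, b$intensities)
  c <- generate_cohort(n_patients = 4, seed = 9)
  d <- generate_cohort(n_patients = 4, seed = 9)
  expect_identical(c$spectra[[1]]$intensity, d$spectra[[1]]$intensity)
})

test_that("generated records satisfy the metadata invariants", {
  coh <- generate_cohort(n_patients = 60, seed = 2, render = FALSE)
  rec <- coh$records
  vol <- rec$vol_pct_benign_epithelium + rec$vol_pct_cancer +
    rec$vol_pct_stroma
  expect_true(all(abs(vol - 100) <= 0.1))
  expect_true(all(rec$vol_pct_cancer[rec$tissue_class == "Hb"] == 0))
  expect_true(all(!is.na(rec$bcr_months) == (rec$bcr != "none")))
  # cohort assignment and outcomes constant within patient
  split_ok <- tapply(rec$cohort, rec$patient_id,
                     function(x) length(unique(x)) == 1)
  expect_true(all(split_ok))
  expect_true(all(rec$pgg %in% 1:5))
  expect_true(all(rec$psa > 0 & rec$psa <= 20))
})

test_that("a null generator plants no group differences", {
  hits <- 0
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    coh <- generate_cohort(n_patients = 200, samples_per_patient = 1,
                           effects = null_effect_config(), seed = 1000 + s,
                           render = FALSE)
    g <- coh$records$pgg >= 3
    x <- coh$intensities[, "3.60"]
    delta <- mean(x[g]) - mean(x[!g])
    se <- sqrt(stats::var(x[g]) / sum(g) + stats::var(x[!g]) / sum(!g))
    if (abs(delta) < 3 * se) hits <- hits + 1
  }
  expect_gte(hits, 0.93 * n_rep)
})

test_that("a planted one-SD effect is recovered at the configured size", {
  tab <- default_region_table()
  sd360 <- effect_config()$baseline_sd[["3.60"]]
  eff <- effect_config(effects = data.frame(contrast = "pgg_high",
                                            region = "3.60",
                                            delta = 1.0 * sd360),
                       patient_sd = 1e-9)
  deltas <- sapply(1:20, function(s) {
    coh <- generate_cohort(n_patients = 200, samples_per_patient = 1,
                           effects = eff, seed = 300 + s, render = FALSE)
    g <- coh$records$pgg >= 3
    x <- coh$intensities[, "3.60"]
    (mean(x[g]) - mean(x[!g])) / sd360
  })
  expect_lt(abs(mean(deltas) - 1.0), 0.15)
})

test_that("outcome generation respects the hazard link", {
  # null link: event status carries no information about the score
  covered <- 0
  for (s in 1:100) {
    coh <- generate_cohort(n_patients = 100, samples_per_patient = 1,
                           effects = effect_config(hazard_link = 0),
                           seed = 500 + s, render = FALSE)
    rec <- coh$records
    sc <- coh$score[rec$patient_id]
    y <- as.integer(rec$bcr == "event")
    fit <- suppressWarnings(stats::glm(y ~ sc, family = stats::binomial()))
    ci <- suppressMessages(suppressWarnings(stats::confint(fit, "sc")))
    if (ci[1] < 0 && ci[2] > 0) covered <- covered + 1
  }
  expect_gte(covered, 88)

  # positive link: among events, higher scores recur earlier
  taus <- sapply(1:50, function(s) {
    coh <- generate_cohort(n_patients = 120, samples_per_patient = 1,
                           seed = 700 + s, render = FALSE)
    rec <- coh$records
    ev <- rec$bcr == "event"
    stats::cor(coh$score[rec$patient_id[ev]], rec$bcr_months[ev],
               method = "kendall")
  })
  expect_lt(mean(taus), 0)
  expect_gte(mean(taus < 0), 0.9)
})

test_that("the planted score separates recurrence near its design ceiling", {
  aucs <- sapply(1:20, function(s) {
    coh <- generate_cohort(n_patients = 160, seed = 900 + s, render = FALSE)
    rec <- coh$records
    p <- !duplicated(rec$patient_id)
    lab <- factor(rec$bcr[p], levels = c("free", "event"))
    roc_summary(coh$score[rec$patient_id[p]], lab)$auc
  })
  expect_gt(mean(aucs), 0.72)
  expect_lt(mean(aucs), 0.88)
})

test_that("a zero censoring window yields zero events", {
  coh <- generate_cohort(n_patients = 30, seed = 3, render = FALSE,
                         effects = effect_config(censor_months = 0))
  expect_true(all(coh$records$bcr == "free"))
  expect_error(generate_outcomes(coh$records, coh$score,
                                 censor_months = -5), ">= 0")
})

test_that("patient clustering rises with the random-intercept SD", {
  icc_of <- function(psd) {
    coh <- generate_cohort(n_patients = 120,
                           samples_per_patient = 3,
                           effects = null_effect_config(patient_sd = psd),
                           seed = 77, render = FALSE)
    x <- coh$intensities[, "2.63"]
    pid <- coh$records$patient_id
    a <- stats::anova(stats::lm(x ~ pid))
    msb <- a["pid", "Mean Sq"]; msw <- a["Residuals", "Mean Sq"]
    (msb - msw) / (msb + 2 * msw)
  }
  iccs <- c(icc_of(1e-9), icc_of(0.7), icc_of(2))
  expect_true(all(diff(iccs) > 0))
})

test_that("round trip through rendering and quantification is faithful", {
  coh <- generate_cohort(n_patients = 6, seed = 21)
  X <- quantify_cohort(coh$spectra)
  err <- abs(X[, colnames(coh$intensities)] - coh$intensities)
  expect_lt(median(err), 0.02)
})
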