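test_that("correlation PCA has orthonormal, deterministic loadings", {
  set.seed(1)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  m <- fit_pca(X, 4)
  G <- t(m$loadings) %*% m$loadings
  expect_equal(G, diag(4), ignore_attr = TRUE, tolerance = 1e-8)
  expect_true(all(diff(m$var_explained) <= 1e-12))
  expect_lte(sum(m$var_explained), 1 + 1e-12)
  # sign convention: largest-|entry| positive
  for (j in 1:4)
    expect_gt(m$loadings[which.max(abs(m$loadings[, j])), j], 0)
  # two perfectly correlated columns -> PC1 explains everything
  Y <- cbind(a = X[, 1], b = 3 * X[, 1] + 2)
  m2 <- fit_pca(Y, 2)
  expect_equal(m2$var_explained[1], 1, tolerance = 1e-12)
})

test_that("loadings match an independent eigendecomposition oracle", {
  toy <- matrix(c(1.0, 2.1, 0.5, 3.2,
                  0.9, 1.8, 0.7, 2.9,
                  1.4, 2.6, 0.2, 3.8,
                  0.8, 1.5, 0.9, 2.5,
                  1.2, 2.2, 0.4, 3.1), 5, 4, byrow = TRUE,
                dimnames = list(NULL, c("r1", "r2", "r3", "r4")))
  m <- fit_pca(toy, 4)
  eig <- eigen(stats::cor(toy))
  for (j in 1:4) {
    cs <- abs(sum(m$loadings[, j] * eig$vectors[, j]))
    expect_equal(cs, 1, tolerance = 1e-8)
  }
  expect_equal(m$var_explained, eig$values / sum(eig$values),
               tolerance = 1e-8)
})

test_that("frozen projection reproduces training scores and centers the mean", {
  set.seed(2)
  X <- matrix(rnorm(600, 5, 2), 100, 6,
              dimnames = list(NULL, paste0("r", 1:6)))
  m <- fit_pca(X, 6)
  expect_lt(max(abs(apply_pca(m, X) - m$scores)), 1e-10)
  mean_row <- matrix(m$mean, 1, dimnames = list("mu", names(m$mean)))
  expect_lt(max(abs(apply_pca(m, mean_row))), 1e-12)
  expect_error(apply_pca(m, X[, 1:5]), "missing region")
})

test_that("hand-computed projection of a single row matches", {
  mu <- c(r1 = 1, r2 = 2, r3 = 3, r4 = 4)
  sd <- c(r1 = 1, r2 = 2, r3 = 0.5, r4 = 4)
  L <- matrix(c(0.5, 0.5, 0.5, 0.5,
                0.5, -0.5, 0.5, -0.5), 4, 2,
              dimnames = list(names(mu), c("PC1", "PC2")))
  m <- structure(list(regions = names(mu), mean = mu, sd = sd, loadings = L),
                 class = "profile_model")
  x <- matrix(c(2, 1, 3.5, 0), 1, dimnames = list("s", names(mu)))
  z <- (x[1, ] - mu) / sd
  expect_equal(drop(apply_pca(m, x)), drop(z %*% L), tolerance = 1e-12)
})

test_that("with all components kept the standardized matrix is reconstructed", {
  set.seed(3)
  X <- matrix(rnorm(300, 10, 3), 50, 6,
              dimnames = list(NULL, paste0("r", 1:6)))
  m <- fit_pca(X, 6)
  Z <- sweep(sweep(X, 2, m$mean), 2, m$sd, "/")
  expect_lt(max(abs(m$scores %*% t(m$loadings) - Z)), 1e-8)
})

test_that("PC selection picks the smallest t-test p-values with stable ties", {
  set.seed(4)
  n <- 60
  lab <- factor(rep(c("x", "y"), each = n / 2))
  S <- cbind(PC1 = rnorm(n),
             PC2 = rnorm(n, mean = as.numeric(lab == "y") * 2),
             PC3 = rnorm(n, mean = as.numeric(lab == "y") * 1))
  sel <- select_pcs(S, lab, 2)
  expect_equal(sort(sel), c(2L, 3L))
  expect_equal(as.integer(select_pcs(S, lab, 3)), 1:3)
  expect_error(select_pcs(S, lab, 4), "exceeds")
  # planted single separating PC found nearly always
  hit <- 0
  for (i in 1:100) {
    S2 <- matrix(rnorm(40 * 6), 40, 6)
    S2[, 4] <- S2[, 4] + as.numeric(rep(c(0, 1.6), each = 20))
    if (identical(as.integer(select_pcs(S2, rep(c("x", "y"), each = 20), 1)),
                  4L))
      hit <- hit + 1
  }
  expect_gte(hit, 95)
})

test_that("canonical discriminant matches the closed form and conventions", {
  # 2-D hand oracle
  X1 <- matrix(c(1, 1, 2, 2, 3, 0, 1.5, 1), 4, 2, byrow = TRUE)
  X0 <- matrix(c(0, 0, 1, -1, -1, 0.5, 0, 0.5), 4, 2, byrow = TRUE)
  lab <- factor(rep(c("ctl", "evt"), each = 4), levels = c("ctl", "evt"))
  cf <- fit_canonical(rbind(X0, X1), lab)
  Sp <- (3 * stats::cov(X1) + 3 * stats::cov(X0)) / 6
  d <- colMeans(X1) - colMeans(X0)
  w0 <- solve(Sp, d)
  w0 <- w0 / sqrt(drop(t(w0) %*% Sp %*% w0))
  expect_equal(unname(cf$weights), unname(w0), tolerance = 1e-10)
  # unit pooled within-class variance
  sc <- rbind(X0, X1) %*% cf$weights
  s1 <- stats::var(sc[lab == "evt"]); s0 <- stats::var(sc[lab == "ctl"])
  expect_equal(drop((3 * s1 + 3 * s0) / 6), 1, tolerance = 1e-8)
  # event class sits higher; grand mean centered at 0
  expect_gt(mean(sc[lab == "evt"]), mean(sc[lab == "ctl"]))
  expect_equal(mean(sc + cf$offset), 0, tolerance = 1e-12)
  # 1-D orientation
  set.seed(5)
  one <- c(rnorm(30), rnorm(30, 1))
  l1 <- factor(rep(c("a", "b"), each = 30))
  expect_gt(fit_canonical(matrix(one, ncol = 1), l1)$weights[1], 0)
  # degenerate classes
  same <- rbind(X0, X0)
  expect_error(fit_canonical(same, lab), "degenerate")
})

test_that("the fitted direction agrees with an independent LDA", {
  skip_if_not_installed("MASS")
  set.seed(6)
  n <- 500
  mu <- c(1, -0.5, 0.25)
  X <- rbind(matrix(rnorm(n * 3), n, 3),
             sweep(matrix(rnorm(n * 3), n, 3), 2, mu, "+"))
  lab <- factor(rep(c("a", "b"), each = n))
  cf <- fit_canonical(X, lab)
  ld <- MASS::lda(X, lab)$scaling[, 1]
  cs <- abs(sum(cf$weights * ld)) /
    sqrt(sum(cf$weights^2) * sum(ld^2))
  expect_gt(cs, 0.999)
  # known optimal direction (identity covariance): recovery cosine >= 0.95
  cs_true <- sum(cf$weights * mu) / sqrt(sum(cf$weights^2) * sum(mu^2))
  expect_gte(cs_true, 0.95)
})

test_that("composed region coefficients reproduce canonical scores", {
  set.seed(7)
  coh <- generate_cohort(n_patients = 80, seed = 13, render = FALSE)
  X <- coh$intensities[, default_region_table()$name]
  lab <- factor(ifelse(seq_len(nrow(X)) %% 2 == 0, "evt", "ctl"),
                levels = c("ctl", "evt"))
  model <- train_profile(X, lab, n_components = 10, k = 4)
  via_pcs <- canonical_scores(model, X)
  via_coef <- drop(sweep(X, 2, model$mean) %*% model$region_coefficients) +
    model$canonical_offset
  expect_lt(max(abs(via_pcs - via_coef)), 1e-8)
  # zero canonical weights -> all-zero coefficients
  m2 <- model
  m2$canonical_weights[] <- 0
  expect_true(all(compose_region_coefficients(m2) == 0))
})

test_that("the mean-minus-SD threshold flags strictly below M-SD", {
  res <- msd_threshold(c(0, 2, 4))
  expect_equal(res$threshold, 0)
  expect_false(any(res$flags))
  # translation invariance
  r1 <- msd_threshold(c(0, 2, 4), c(-1, 1, 5))
  r2 <- msd_threshold(c(0, 2, 4) + 10, c(-1, 1, 5) + 10)
  expect_identical(r1$flags, r2$flags)
  expect_warning(res0 <- msd_threshold(c(3, 3, 3)), "constant")
  expect_false(any(res0$flags))
  expect_error(msd_threshold(1), ">= 2")
})

test_that("M-SD flags a planted low-score subpopulation, not the bulk", {
  set.seed(8)
  hits <- fps <- numeric(20)
  for (i in 1:20) {
    n_low <- 20
    bulk <- rnorm(110, 0, 0.5)
    low <- rnorm(n_low, -1.5, 0.3)
    vals <- c(bulk, low)
    res <- msd_threshold(vals)
    hits[i] <- mean(res$flags[111:130])
    fps[i] <- mean(res$flags[1:110])
  }
  expect_gte(mean(hits), 0.7)
  expect_lte(mean(fps), 0.1)
})

test_that("combining with PSA follows the documented conventions", {
  set.seed(9)
  n <- 60
  lab <- factor(rep(c("ctl", "evt"), each = n / 2), levels = c("ctl", "evt"))
  sc <- rnorm(n, mean = as.numeric(lab == "evt"))
  # uninformative PSA leaves the AUC essentially unchanged
  diffs <- sapply(1:100, function(i) {
    s <- rnorm(n, mean = as.numeric(lab == "evt"))
    psa <- rnorm(n, 6, 2)
    a0 <- roc_summary(s, lab)$auc
    a1 <- roc_summary(combine_with_psa(s, psa, lab)$combined_scores, lab)$auc
    a1 - a0
  })
  expect_lt(abs(mean(diffs)), 0.03)
  # perfectly separating PSA dominates
  psa_sep <- ifelse(lab == "evt", 10, 1)
  comb <- combine_with_psa(sc, psa_sep, lab)
  expect_equal(roc_summary(comb$combined_scores, lab)$auc, 1.0)
  # combining the score with its own copy preserves the ranking
  comb2 <- combine_with_psa(sc, sc, lab)
  expect_equal(order(comb2$combined_scores), order(sc))
})

test_that("applying a frozen model to test data never mutates it", {
  coh <- generate_cohort(n_patients = 60, seed = 17, render = FALSE)
  X <- coh$intensities[, default_region_table()$name]
  lab <- factor(rep_len(c("ctl", "evt"), nrow(X)), levels = c("ctl", "evt"))
  model <- train_profile(X[1:80, ], lab[1:80], n_components = 8, k = 3)
  before <- serialize(model, NULL)
  invisible(apply_pca(model, X[81:120, ]))
  invisible(canonical_scores(model, X[81:120, ]))
  invisible(msd_threshold(X[81:120, "3.60"]))
  expect_identical(serialize(model, NULL), before)
})

test_that("profile JSON serialization round-trips the frozen model", {
  coh <- generate_cohort(n_patients = 50, seed = 19, render = FALSE)
  X <- coh$intensities[, default_region_table()$name]
  lab <- factor(rep_len(c("ctl", "evt"), nrow(X)), levels = c("ctl", "evt"))
  model <- train_profile(X, lab, n_components = 6, k = 3,
                         msd_reference = X[, "3.60"])
  path <- tempfile(fileext = ".json")
  write_profile(model, path)
  back <- read_profile(path)
  expect_equal(canonical_scores(back, X), canonical_scores(model, X),
               tolerance = 1e-12)
  expect_equal(back$km_threshold, model$km_threshold)
  expect_equal(back$msd_threshold_value, model$msd_threshold_value)
})
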