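# Distribution-gated univariate screening over spectral regions / PCs with
# Bonferroni control, ANCOVA confounder elimination, and a repeated-measures
# (patient random intercept) confirmation.

#' Bonferroni per-test threshold
#'
#' `alpha / m`, with the reported value truncated (floored, not rounded) to
#' four decimal places; the untruncated value is kept in the `"raw"`
#' attribute. Truncation makes 0.05/36 report as 0.0013 and 0.05/14 as
#' 0.0035.
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of tests in the family (>= 1).
#' @return Numeric threshold (truncated), with attribute `raw`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (length(m) != 1L || is.na(m) || m < 1) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  raw <- alpha / m
  structure(floor(raw * 1e4) / 1e4, raw = raw)
}

# Shapiro-Wilk normality gate for one group (TRUE = treat as normal).
# shapiro.test needs 3..5000 observations; larger groups are subsampled
# deterministically (every k-th order statistic), which preserves shape.
sw_normal <- function(x, gate = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("insufficient data: group with < 3 observations")
  if (stats::sd(x) == 0) return(FALSE)
  if (length(x) > 5000L) x <- sort(x)[round(seq(1, length(x), length.out = 5000))]
  stats::shapiro.test(x)$p.value >= gate
}

#' Choose the univariate test for a feature/target pair
#'
#' Encodes the gated test ladder: continuous target -> linear regression;
#' categorical target with > 2 levels -> ANOVA when every group passes the
#' Shapiro-Wilk gate, else Kruskal-Wallis; binary target -> Student t
#' (pooled when Levene accepts equal variances, Welch otherwise) when both
#' groups pass the gate, else Mann-Whitney-Wilcoxon. Deterministic given
#' the data and gate levels.
#'
#' @param values Numeric feature vector.
#' @param grouping Target: numeric (continuous) or factor/character.
#' @param gate Shapiro-Wilk gate level per group.
#' @param var_gate Levene gate level for pooled-vs-Welch t.
#' @return Character scalar: one of `"linear-regression"`, `"anova"`,
#'   `"kruskal-wallis"`, `"t-test"`, `"welch-t"`, `"mann-whitney"`.
#' @export
choose_test <- function(values, grouping, gate = 0.05, var_gate = 0.05) {
  keep <- is.finite(values) & !is.na(grouping)
  values <- values[keep]
  grouping <- grouping[keep]
  if (is.numeric(grouping) && length(unique(grouping)) > 5L)
    return("linear-regression")
  g <- factor(grouping)
  if (nlevels(g) < 2L) stop("grouping has a single level")
  sizes <- table(g)
  if (any(sizes < 3L))
    stop("insufficient data: group '", names(sizes)[which.min(sizes)],
         "' has ", min(sizes), " observations (< 3)")
  normal <- all(vapply(levels(g), function(l)
    sw_normal(values[g == l], gate), logical(1)))
  if (nlevels(g) > 2L) return(if (normal) "anova" else "kruskal-wallis")
  if (!normal) return("mann-whitney")
  lev_p <- car::leveneTest(values ~ g)[1, "Pr(>F)"]
  if (is.finite(lev_p) && lev_p < var_gate) "welch-t" else "t-test"
}

run_test <- function(values, grouping, test) {
  switch(test,
    "linear-regression" = {
      fit <- stats::lm(values ~ grouping)
      stats::coef(summary(fit))[2, "Pr(>|t|)"]
    },
    "anova" = {
      g <- factor(grouping)
      stats::anova(stats::lm(values ~ g))[1, "Pr(>F)"]
    },
    "kruskal-wallis" = stats::kruskal.test(values, factor(grouping))$p.value,
    "t-test" = stats::t.test(values ~ factor(grouping),
                             var.equal = TRUE)$p.value,
    "welch-t" = stats::t.test(values ~ factor(grouping),
                              var.equal = FALSE)$p.value,
    "mann-whitney" = stats::wilcox.test(values ~ factor(grouping),
                                        exact = FALSE)$p.value,
    stop("unknown test '", test, "'"))
}

tier_for <- function(p, bonf) {
  if (!is.finite(p)) return("none")
  if (p < bonf) "***" else if (p < 0.005) "**" else if (p < 0.05) "*"
  else "none"
}

#' Derive an analysis target variable from sample records
#'
#' Built-in contrasts: `pgg_group` (PGG 1&2 vs 3&4, PGG 5 excluded to
#' mirror the 1&2-vs-3&4 grade comparison), `pgg_high` (PGG 1-2 vs 3-5),
#' `pt_binary` (IIab vs IIc; III excluded), `pt_stage` (three levels),
#' `aggressiveness` (low = PGG 1&2 and pT II; high = PGG 3 or pT III;
#' PGG 4&5 excluded), `bcr` (event vs free), `pni`, plus any numeric
#' column name in `records` (continuous target).
#'
#' @param records Sample-record data.frame.
#' @param target Target name.
#' @return Vector aligned with `records` rows; `NA` marks rows excluded
#'   from the contrast.
#' @export
derive_target <- function(records, target) {
  valid <- c("pgg_group", "pgg_high", "pt_binary", "pt_stage",
             "aggressiveness", "bcr", "pni",
             names(records)[vapply(records, is.numeric, logical(1))])
  switch(target,
    pgg_group = {
      out <- ifelse(records$pgg %in% c(1, 2), "PGG1&2",
                    ifelse(records$pgg %in% c(3, 4), "PGG3&4", NA))
      factor(out, levels = c("PGG1&2", "PGG3&4"))
    },
    pgg_high = factor(ifelse(records$pgg %in% c(1, 2), "low", "high"),
                      levels = c("low", "high")),
    pt_binary = factor(ifelse(records$pt_stage == "III", NA,
                              records$pt_stage),
                       levels = c("IIab", "IIc")),
    pt_stage = factor(records$pt_stage, levels = c("IIab", "IIc", "III")),
    aggressiveness = {
      low <- records$pgg %in% c(1, 2) & records$pt_stage != "III"
      high <- (records$pgg == 3) | (records$pt_stage == "III" &
                                      records$pgg %in% c(1, 2, 3))
      out <- ifelse(records$pgg %in% c(4, 5), NA,
                    ifelse(high, "high", ifelse(low, "low", NA)))
      factor(out, levels = c("low", "high"))
    },
    bcr = factor(ifelse(records$bcr == "none", NA, records$bcr),
                 levels = c("free", "event")),
    pni = factor(ifelse(records$pni == "none", NA, records$pni),
                 levels = c("negative", "positive")),
    {
      if (!target %in% names(records))
        stop("unknown target '", target, "'; valid targets: ",
             paste(unique(valid), collapse = ", "))
      records[[target]]
    })
}

#' Screen every feature against one target variable
#'
#' Runs the gated univariate test of [choose_test()] for each column of the
#' feature matrix (spectral regions or PC scores) and assigns significance
#' tiers: `*` p < 0.05, `**` p < 0.005, `***` past the Bonferroni threshold
#' `alpha_family / m` where `m` is the number of features. Constant
#' features are reported with p = 1 and flagged degenerate. Rows with a
#' missing target are dropped per test (listwise deletion).
#'
#' @param matrix Numeric matrix, rows = samples, columns = features.
#' @param records Sample records aligned with `matrix` rows (or `NULL` when
#'   `target_values` is given).
#' @param target Target name for [derive_target()].
#' @param alpha_family Family-wise level for the `***` tier.
#' @param target_values Optional explicit target vector overriding
#'   `derive_target`.
#' @return data.frame with columns `feature`, `target`, `test`, `p_value`,
#'   `tier`, `n`, `degenerate`.
#' @export
screen_features <- function(matrix, records = NULL, target,
                            alpha_family = 0.05, target_values = NULL) {
  if (is.null(target_values)) target_values <- derive_target(records, target)
  if (length(target_values) != nrow(matrix))
    stop("matrix rows do not align with records")
  m <- ncol(matrix)
  bonf <- bonferroni_threshold(alpha_family, m)
  res <- vector("list", m)
  for (j in seq_len(m)) {
    v <- matrix[, j]
    keep <- !is.na(target_values) & is.finite(v)
    vj <- v[keep]
    tj <- target_values[keep]
    if (length(vj) == 0 || stats::sd(vj) == 0) {
      res[[j]] <- data.frame(feature = colnames(matrix)[j], target = target,
                             test = "degenerate", p_value = 1, tier = "none",
                             n = length(vj), degenerate = TRUE,
                             stringsAsFactors = FALSE)
      next
    }
    test <- choose_test(vj, tj)
    p <- run_test(vj, tj, test)
    res[[j]] <- data.frame(feature = colnames(matrix)[j], target = target,
                           test = test, p_value = p,
                           tier = tier_for(p, bonf), n = length(vj),
                           degenerate = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "bonferroni") <- as.numeric(bonf)
  out
}

#' ANCOVA adjustment of a group effect for clinical confounders
#'
#' F-test p-value for the group factor in
#' `feature ~ group + covariates` (type-II style: full model versus the
#' model without the group term), after listwise deletion. Used to verify
#' that significant regions/PCs are not explained by age, pre-surgical PSA
#' or prostate weight.
#'
#' @param feature Numeric vector.
#' @param group Factor (2 or more levels).
#' @param covariates data.frame of numeric covariates.
#' @return Adjusted p-value for the group factor.
#' @export
ancova_adjust <- function(feature, group, covariates) {
  covariates <- as.data.frame(covariates)
  if (!all(vapply(covariates, is.numeric, logical(1))))
    stop("covariates must be numeric")
  dat <- data.frame(.y = feature, .g = factor(group), covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  X <- as.matrix(dat[, -(1:2), drop = FALSE])
  if (kappa(cbind(1, scale(X, scale = FALSE))) > 1e10)
    stop("collinear covariates (condition number > 1e10)")
  full <- stats::lm(.y ~ ., data = dat)
  reduced <- stats::lm(.y ~ . - .g, data = dat)
  stats::anova(reduced, full)[2, "Pr(>F)"]
}

#' Repeated-measures confirmation with a patient random intercept
#'
#' Fits `feature ~ group + (1 | patient)` and returns the group-effect
#' p-value (Satterthwaite F). When the patient variance component is
#' estimated at zero (or every patient contributes one sample), falls back
#' to aggregating samples to patient means and testing those — which is the
#' ordinary test when there is one sample per patient.
#'
#' @param feature Numeric vector (one value per sample).
#' @param group Factor aligned with samples, constant within patient.
#' @param patient_ids Patient identifier per sample.
#' @return Group-effect p-value, with attribute `method` ("mixed" or
#'   "aggregated").
#' @export
repeated_measures_check <- function(feature, group, patient_ids) {
  keep <- is.finite(feature) & !is.na(group) & !is.na(patient_ids)
  feature <- feature[keep]; group <- factor(group[keep])
  patient_ids <- as.character(patient_ids[keep])
  if (length(unique(patient_ids)) < 2L)
    stop("all samples come from a single patient")
  per_group <- tapply(patient_ids, group, function(p) length(unique(p)))
  if (any(per_group < 2L)) stop("need >= 2 patients per group")

  aggregated_p <- function() {
    dat <- stats::aggregate(feature, list(pid = patient_ids, g = group), mean)
    stats::anova(stats::lm(x ~ g, data = dat))[1, "Pr(>F)"]
  }
  if (!any(duplicated(patient_ids)))
    return(structure(aggregated_p(), method = "aggregated"))
  dat <- data.frame(y = feature, g = group, pid = patient_ids)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(y ~ g + (1 | pid), data = dat)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  if (vc$vcov[vc$grp == "pid"] <= 1e-10)
    return(structure(aggregated_p(), method = "aggregated"))
  an <- suppressMessages(stats::anova(fit))
  structure(an["g", "Pr(>F)"], method = "mixed")
}
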