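# Endpoint evaluation: Kaplan-Meier recurrence curves, log-rank
# comparison, ROC / overall accuracy, and score-vs-survival regression.

#' Kaplan-Meier product-limit estimate
#'
#' Wraps the product-limit estimator (events processed before censorings at
#' tied times) and returns the curve with at-risk counts, censoring marks
#' and Greenwood standard errors.
#'
#' @param times Follow-up times in months (>= 0).
#' @param events Logical (TRUE = event) aligned with `times`.
#' @return Object of class `km_curve`: list with `time`, `surv`, `n_risk`,
#'   `n_event`, `n_censor`, `std_err` (Greenwood, on the survival scale).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  if (length(times) != length(events)) stop("times and events lengths differ")
  if (any(times < 0)) stop("negative times")
  sf <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, n_censor = sf$n.censor,
                 std_err = sf$std.err * sf$surv),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d time points, %d events\n",
              length(x$time), sum(x$n_event)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param times,events As in [km_estimate()].
#' @param group Two-level factor/vector aligned with `times`.
#' @return List with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
logrank <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("log-rank comparison needs exactly two non-empty groups")
  sd <- survival::survdiff(
    survival::Surv(times, as.integer(events)) ~ group)
  stat <- sd$chisq
  list(statistic = as.numeric(stat),
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' ROC summary with rank-based AUC and best overall accuracy
#'
#' AUC by the rank (Mann-Whitney) formulation with midrank tie correction;
#' higher scores are taken to indicate the positive (second-level / TRUE)
#' class. `overall_accuracy` is the maximum of (TP + TN)/n over all score
#' thresholds (predict positive when score >= threshold, including the
#' all-positive and all-negative extremes).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (second level / TRUE = positive class).
#' @return Object of class `roc_summary`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `overall_accuracy`.
#' @export
roc_summary <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("need both classes present")
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)                      # midranks handle ties
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- spec <- acc <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    sens[i] <- sum(pred & pos) / n1
    spec[i] <- sum(!pred & !pos) / n0
    acc[i] <- (sum(pred & pos) + sum(!pred & !pos)) / length(scores)
  }
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, overall_accuracy = max(acc)),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary> AUC %.3f, overall accuracy %.1f%%\n",
              x$auc, 100 * x$overall_accuracy))
  invisible(x)
}

#' Linear regression of survival time on discriminant score
#'
#' Ordinary least squares of survival months on score among deceased
#' patients, with the Pearson correlation and its two-sided p-value.
#'
#' @param scores Discriminant scores (deceased patients).
#' @param survival_months Survival times aligned with `scores`.
#' @return List with `slope`, `intercept`, `correlation`, `p_value`, `n`.
#' @export
score_survival_regression <- function(scores, survival_months) {
  keep <- is.finite(scores) & is.finite(survival_months)
  scores <- scores[keep]; survival_months <- survival_months[keep]
  if (length(scores) < 3L) stop("need >= 3 points")
  fit <- stats::lm(survival_months ~ scores)
  ct <- stats::cor.test(scores, survival_months)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       correlation = unname(ct$estimate),
       p_value = ct$p.value,
       n = length(scores))
}
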