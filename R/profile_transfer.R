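# Training-cohort metabolomic profile (standardization, PCA, PC-subset
# canonical discriminant, thresholds) applied frozen to a testing cohort.

#' Fit correlation-based PCA on the training intensity matrix
#'
#' Columns are z-scored with the training mean and SD (so the
#' decomposition is of the correlation structure), then decomposed by SVD.
#' Constant columns are dropped with a warning. Each loading column is
#' oriented so its largest-magnitude entry is positive — a deterministic
#' sign convention.
#'
#' @param training Numeric matrix (samples x regions), e.g. an
#'   `intensity_matrix`.
#' @param n_components Components to retain (<= number of usable regions).
#' @return A `profile_model` holding `regions`, `mean`, `sd`, `loadings`
#'   (regions x components, orthonormal), `var_explained` (fractions, all
#'   components), `n_components` and the training `scores`.
#' @export
fit_pca <- function(training, n_components = 14L) {
  X <- as.matrix(training)
  if (nrow(X) < 2L) stop("need >= 2 training samples")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant region(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (n_components > ncol(X))
    stop("n_components (", n_components, ") exceeds region count (",
         ncol(X), ")")
  mu <- colMeans(X)
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  sv <- svd(Z)
  load_all <- sv$v
  # deterministic sign: largest-|entry| of each column made positive
  for (j in seq_len(ncol(load_all))) {
    i <- which.max(abs(load_all[, j]))
    if (load_all[i, j] < 0) load_all[, j] <- -load_all[, j]
  }
  ev <- sv$d^2
  ve <- ev / sum(ev)
  loadings <- load_all[, seq_len(n_components), drop = FALSE]
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- paste0("PC", seq_len(n_components))
  scores <- Z %*% loadings
  structure(list(
    regions = colnames(X), mean = mu, sd = sds,
    loadings = loadings, var_explained = ve,
    n_components = as.integer(n_components),
    scores = scores,
    selected_pcs = NULL, canonical_weights = NULL,
    canonical_offset = NULL, region_coefficients = NULL,
    msd_threshold_value = NULL, km_threshold = NULL),
    class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model> %d regions, %d PCs (%.1f%% variance)\n",
              length(x$regions), x$n_components,
              100 * sum(x$var_explained[seq_len(x$n_components)])))
  if (!is.null(x$selected_pcs))
    cat("  selected PCs:", paste(x$selected_pcs, collapse = ", "), "\n")
  invisible(x)
}

#' Project a cohort onto a frozen profile model
#'
#' Z-scores each region with the *training* mean/SD stored in the model and
#' projects onto the stored loadings. Columns are matched by region name;
#' a missing region is an error. Applying the model to its own training
#' matrix reproduces the stored fit scores exactly.
#'
#' @param model A `profile_model`.
#' @param matrix Intensity matrix with (at least) the model's regions.
#' @return Score matrix (samples x retained components).
#' @export
apply_pca <- function(model, matrix) {
  stopifnot(inherits(model, "profile_model"))
  X <- as.matrix(matrix)
  missing <- setdiff(model$regions, colnames(X))
  if (length(missing))
    stop("matrix is missing region column(s): ",
         paste(missing, collapse = ", "))
  X <- X[, model$regions, drop = FALSE]
  Z <- sweep(sweep(X, 2, model$mean), 2, model$sd, "/")
  Z %*% model$loadings
}

#' Select the k principal components most associated with a binary label
#'
#' Ranks components by the two-sided Student t-test p-value comparing the
#' two label classes and returns the indices of the `k` smallest; ties are
#' broken toward the lower component index. Returned indices are sorted
#' ascending.
#'
#' @param scores PC score matrix.
#' @param labels Binary factor/logical aligned with rows.
#' @param k Number of components to select.
#' @return Integer vector of column indices, with attribute `p_values`
#'   (all components).
#' @export
select_pcs <- function(scores, labels, k) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes")
  if (k > ncol(scores)) stop("k exceeds the number of components")
  p <- vapply(seq_len(ncol(scores)), function(j)
    stats::t.test(scores[, j] ~ labels, var.equal = TRUE)$p.value,
    numeric(1))
  sel <- sort(order(p, seq_along(p))[seq_len(k)])
  structure(as.integer(sel), p_values = p)
}

#' Fit a two-class canonical (linear) discriminant
#'
#' Direction proportional to `pooled-covariance^-1 %*% (mean difference)`,
#' scaled so the pooled within-class variance of the resulting scores is 1,
#' oriented so the event (second-level / TRUE) class has the higher mean
#' score, and offset so the grand mean score over all samples is 0. A small
#' ridge (1e-8 of the mean diagonal) is added when the pooled covariance is
#' numerically singular, with a message.
#'
#' @param scores Numeric matrix of selected-PC scores (or any features).
#' @param labels Binary factor/logical; the second level (or TRUE) is the
#'   event class.
#' @return List with `weights`, `offset`, `event_level`.
#' @export
fit_canonical <- function(scores, labels) {
  X <- as.matrix(scores)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes")
  if (any(table(labels) < 2L)) stop("need >= 2 samples per class")
  ev <- levels(labels)[2]
  X1 <- X[labels == ev, , drop = FALSE]
  X0 <- X[labels != ev, , drop = FALSE]
  d <- colMeans(X1) - colMeans(X0)
  n1 <- nrow(X1); n0 <- nrow(X0)
  Sp <- ((n1 - 1) * stats::cov(X1) + (n0 - 1) * stats::cov(X0)) /
    (n1 + n0 - 2)
  Sp <- as.matrix(Sp)
  if (all(abs(d) < 1e-12)) stop("degenerate discriminant: identical class means")
  scale0 <- mean(diag(Sp)) + 1e-300
  if (rcond(Sp) < 1e-10) {
    # rank-deficient pooled covariance (few cases relative to features):
    # escalate a relative ridge until well conditioned
    for (lambda in c(1e-8, 1e-6, 1e-4, 1e-2, 1)) {
      Sp <- Sp + diag(lambda * scale0, ncol(Sp))
      if (rcond(Sp) >= 1e-10) {
        message("pooled covariance singular; ridge ",
                signif(lambda * scale0, 3), " added")
        break
      }
    }
  }
  w <- solve(Sp, d)
  s2 <- drop(t(w) %*% Sp %*% w)
  if (s2 <= 0) stop("degenerate discriminant: zero within-class variance")
  w <- w / sqrt(s2)
  if (sum(w * d) < 0) w <- -w          # event class scores higher
  offset <- -mean(X %*% w)
  list(weights = stats::setNames(as.numeric(w), colnames(X)),
       offset = as.numeric(offset), event_level = ev)
}

#' Canonical scores under a (possibly composed) model
#'
#' @param model A `profile_model` with canonical parts present.
#' @param matrix Intensity matrix.
#' @return Numeric vector of canonical scores.
#' @export
canonical_scores <- function(model, matrix) {
  if (is.null(model$canonical_weights)) stop("model has no canonical part")
  pcs <- apply_pca(model, matrix)[, model$selected_pcs, drop = FALSE]
  drop(pcs %*% model$canonical_weights) + model$canonical_offset
}

#' Compose per-region overall coefficients
#'
#' Folds standardization, loadings and canonical weights into one
#' coefficient per region:
#' `coef_r = sum_k w_k * loading_(r,k) / sd_r` over the selected
#' components, so that
#' `score = sum_r coef_r * (x_r - mean_r) + offset` reproduces the
#' PCA-then-canonical scores exactly. These are the coefficients
#' transferred to a testing cohort.
#'
#' @param model A `profile_model` with PCA and canonical parts.
#' @return Named numeric vector of per-region coefficients.
#' @export
compose_region_coefficients <- function(model) {
  if (is.null(model$canonical_weights))
    stop("model has no canonical part yet")
  L <- model$loadings[, model$selected_pcs, drop = FALSE]
  drop(L %*% model$canonical_weights) / model$sd
}

#' Mean-minus-SD threshold flagging
#'
#' Threshold at one sample standard deviation below the mean of a reference
#' set; a queried value is flagged iff strictly below the threshold. With a
#' constant reference the threshold falls back to the mean and nothing is
#' flagged (with a warning).
#'
#' @param reference Numeric reference values (>= 2).
#' @param values Values to flag (defaults to `reference`).
#' @return List with `threshold` and logical `flags`.
#' @export
msd_threshold <- function(reference, values = reference) {
  reference <- reference[is.finite(reference)]
  if (length(reference) < 2L) stop("need >= 2 reference values")
  s <- stats::sd(reference)
  m <- mean(reference)
  if (s == 0) {
    warning("constant reference; threshold set to the mean, nothing flagged")
    return(list(threshold = m, flags = rep(FALSE, length(values))))
  }
  thr <- m - s
  list(threshold = thr, flags = values < thr)
}

#' Combine a canonical score with PSA into one discriminant
#'
#' Fits a two-feature linear discriminant ([fit_canonical()]) on the
#' (score, PSA) matrix with the same scaling and orientation conventions.
#'
#' @param scores Canonical score vector.
#' @param psa PSA values aligned with `scores`.
#' @param labels Binary labels (second level / TRUE = event).
#' @return List as [fit_canonical()] plus `combined_scores`.
#' @export
combine_with_psa <- function(scores, psa, labels) {
  if (length(scores) != length(psa)) stop("scores and psa lengths differ")
  M <- cbind(score = scores, psa = psa)
  cf <- fit_canonical(M, labels)
  cf$combined_scores <- drop(M %*% cf$weights) + cf$offset
  cf
}

#' Train the full metabolomic profile on a training cohort
#'
#' PCA with `n_components` retained, PC subset selection against the event
#' labels, canonical discriminant on the selected PCs, composed per-region
#' coefficients, the mean-minus-SD threshold from the reference rows, and
#' the frozen Kaplan-Meier split threshold (the mean canonical score of the
#' training rows used for the discriminant).
#'
#' @param training Intensity matrix of the training cohort.
#' @param labels Binary event labels aligned with `training` rows
#'   (NA rows excluded from discriminant fitting, kept for PCA).
#' @param n_components PCs retained.
#' @param k PCs selected for the discriminant.
#' @param msd_reference Optional numeric vector (e.g. a region's values in
#'   the reference group) from which to freeze the M-SD threshold.
#' @return A complete `profile_model`.
#' @export
train_profile <- function(training, labels, n_components = 14L, k = 5L,
                          msd_reference = NULL) {
  model <- fit_pca(training, n_components)
  keep <- !is.na(labels)
  sc <- model$scores[keep, , drop = FALSE]
  lab <- factor(labels[keep])
  if (k > nrow(sc) - 2L) {
    k <- max(1L, nrow(sc) - 2L)
    message("too few labeled cases for requested PC count; using k = ", k)
  }
  model$selected_pcs <- select_pcs(sc, lab, k)
  cf <- fit_canonical(sc[, model$selected_pcs, drop = FALSE], lab)
  model$canonical_weights <- cf$weights
  model$canonical_offset <- cf$offset
  model$event_level <- cf$event_level
  model$region_coefficients <- compose_region_coefficients(model)
  model$km_threshold <- mean(drop(sc[, model$selected_pcs, drop = FALSE] %*%
                                    cf$weights) + cf$offset)
  if (!is.null(msd_reference))
    model$msd_threshold_value <- msd_threshold(msd_reference)$threshold
  model
}

#' Serialize / deserialize a profile model as JSON
#'
#' A versioned, plain-JSON schema so a training run is exactly reusable on
#' any testing matrix.
#'
#' @param model A `profile_model`.
#' @param path File path.
#' @return `write_profile` invisibly returns `path`; `read_profile` returns
#'   the `profile_model`.
#' @export
write_profile <- function(model, path) {
  obj <- list(
    schema = "tissuemrs-profile/1",
    regions = model$regions,
    mean = as.numeric(model$mean), sd = as.numeric(model$sd),
    loadings = unclass(model$loadings),
    var_explained = model$var_explained,
    n_components = model$n_components,
    selected_pcs = model$selected_pcs,
    canonical_weights = as.numeric(model$canonical_weights),
    canonical_offset = model$canonical_offset,
    event_level = model$event_level,
    region_coefficients = as.numeric(model$region_coefficients),
    msd_threshold_value = model$msd_threshold_value,
    km_threshold = model$km_threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "tissuemrs-profile/1"))
    stop("unrecognized profile schema")
  loadings <- as.matrix(obj$loadings)
  rownames(loadings) <- obj$regions
  model <- structure(list(
    regions = obj$regions,
    mean = stats::setNames(obj$mean, obj$regions),
    sd = stats::setNames(obj$sd, obj$regions),
    loadings = loadings,
    var_explained = obj$var_explained,
    n_components = as.integer(obj$n_components),
    scores = NULL,
    selected_pcs = as.integer(obj$selected_pcs),
    canonical_weights = stats::setNames(
      obj$canonical_weights, colnames(loadings)[obj$selected_pcs]),
    canonical_offset = obj$canonical_offset,
    event_level = obj$event_level,
    region_coefficients = stats::setNames(obj$region_coefficients,
                                          obj$regions),
    msd_threshold_value = obj$msd_threshold_value,
    km_threshold = obj$km_threshold),
    class = "profile_model")
  model
}
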