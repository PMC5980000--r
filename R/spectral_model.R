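# Spectrum / peak data model, pseudo-Voigt lineshape, synthesis and fitting.

#' Construct a one-dimensional NMR spectrum
#'
#' A spectrum is a chemical-shift grid (ppm) with one intensity per grid
#' point. The ppm axis is stored strictly ascending; display on the
#' conventional descending NMR axis is a presentation concern only.
#'
#' @param ppm Numeric vector of chemical shifts (ppm). Must be finite and,
#'   after sorting, strictly increasing (no duplicated shifts).
#' @param intensity Numeric vector of signal intensities (arbitrary units),
#'   same length as `ppm`; must be finite.
#' @param sample_id Character scalar identifying the tissue sample.
#' @return An object of class `mrs_spectrum`: a list with elements
#'   `sample_id`, `ppm` (ascending) and `intensity`.
#' @examples
#' sp <- mrs_spectrum(seq(0.4, 4.6, by = 0.01), rnorm(421, 1), "ex1")
#' range(sp$ppm)
#' @export
mrs_spectrum <- function(ppm, intensity, sample_id = "sample") {
  if (length(ppm) == 0L) stop("spectrum grid is empty")
  if (length(ppm) != length(intensity))
    stop("ppm and intensity lengths differ (", length(ppm), " vs ",
         length(intensity), ")")
  if (!all(is.finite(ppm))) stop("non-finite ppm values")
  if (!all(is.finite(intensity))) stop("non-finite intensity values")
  ord <- order(ppm)
  ppm <- ppm[ord]
  intensity <- intensity[ord]
  if (any(diff(ppm) <= 0)) stop("duplicated ppm values in grid")
  structure(list(sample_id = as.character(sample_id),
                 ppm = as.numeric(ppm),
                 intensity = as.numeric(intensity)),
            class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %s: %d points, %.3f-%.3f ppm\n",
              x$sample_id, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Construct a pseudo-Voigt peak model
#'
#' One spectral line parameterized by center (ppm), height, full width at
#' half maximum (ppm) and the Gaussian fraction `eta` of the additive
#' Gaussian-Lorentzian mixture.
#'
#' @param center Peak center (ppm).
#' @param amplitude Peak height, > 0 (arbitrary intensity units).
#' @param fwhm Full width at half maximum (ppm), > 0.
#' @param eta Gaussian fraction in \[0, 1\]; 0 is pure Lorentzian, 1 pure
#'   Gaussian.
#' @return An object of class `peak_model`.
#' @export
peak_model <- function(center, amplitude, fwhm, eta = 0.5) {
  vals <- c(center = center, amplitude = amplitude, fwhm = fwhm, eta = eta)
  if (!all(is.finite(vals))) stop("non-finite peak parameters")
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  structure(list(center = as.numeric(center), amplitude = as.numeric(amplitude),
                 fwhm = as.numeric(fwhm), eta = as.numeric(eta)),
            class = "peak_model")
}

#' Evaluate a pseudo-Voigt lineshape
#'
#' Additive height-normalized mixture: both the Gaussian and the Lorentzian
#' component have unit height at the center and share the FWHM `w`, so
#' `A * (eta * exp(-4 log(2) (x-c)^2 / w^2) + (1-eta) / (1 + 4 (x-c)^2 / w^2))`.
#'
#' @param peak A [peak_model()].
#' @param grid Numeric vector of ppm values at which to evaluate.
#' @return Numeric vector of intensities, one per grid point.
#' @examples
#' pk <- peak_model(3.60, 2, 0.01, 0.5)
#' pseudo_voigt(pk, c(3.60, 3.605))  # height 2 at center, 1 at c + w/2
#' @export
pseudo_voigt <- function(peak, grid) {
  if (!inherits(peak, "peak_model")) peak <- do.call(peak_model, peak)
  if (!all(is.finite(grid))) stop("non-finite grid values")
  pv_eval(grid, peak$center, peak$amplitude, peak$fwhm, peak$eta)
}

# vectorized core used by fitting; no validation
pv_eval <- function(x, c0, a, w, eta) {
  u <- (x - c0) / w
  a * (eta * exp(-4 * log(2) * u^2) + (1 - eta) / (1 + 4 * u^2))
}

#' Analytic area of a pseudo-Voigt peak
#'
#' The Gaussian component integrates to `A*w*(1/2)*sqrt(pi/log(2))` and the
#' Lorentzian component to `A*w*pi/2`; the pseudo-Voigt area is their
#' eta-weighted sum. Integration of fitted spectra uses these closed forms,
#' never numerical quadrature.
#'
#' @param peak A [peak_model()] (or list coercible to one).
#' @return Peak area (intensity x ppm units).
#' @export
peak_area <- function(peak) {
  if (!inherits(peak, "peak_model")) peak <- do.call(peak_model, peak)
  peak$amplitude * peak$fwhm *
    (peak$eta * 0.5 * sqrt(pi / log(2)) + (1 - peak$eta) * pi / 2)
}

#' Synthesize a spectrum from pseudo-Voigt components
#'
#' Sums the given peaks over the grid, adds a constant baseline and i.i.d.
#' Gaussian noise. The same seed always yields the identical spectrum.
#'
#' @param peaks List of [peak_model()] objects (may be empty).
#' @param grid Ascending ppm grid.
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param baseline Constant baseline intensity.
#' @param seed Integer seed for the noise draw (ignored when `noise_sd = 0`).
#' @param sample_id Identifier for the resulting spectrum.
#' @return An [mrs_spectrum()].
#' @export
synthesize_spectrum <- function(peaks, grid, noise_sd = 0, baseline = 0,
                                seed = NULL, sample_id = "synthetic") {
  if (length(grid) == 0L) stop("empty grid")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  y <- rep(baseline, length(grid))
  for (pk in peaks) {
    if (!inherits(pk, "peak_model")) pk <- do.call(peak_model, pk)
    y <- y + pv_eval(grid, pk$center, pk$amplitude, pk$fwhm, pk$eta)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    y <- y + stats::rnorm(length(grid), 0, noise_sd)
  }
  mrs_spectrum(grid, y, sample_id)
}

# local maxima of y, ties among equal heights broken by lower ppm first;
# returns indices sorted by decreasing height
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  idx[order(-y[idx], idx)]
}

#' Fit pseudo-Voigt peaks to a spectral window
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with parameter
#' bounds) of `n_peaks` pseudo-Voigt components over a ppm window. Peak
#' centers are constrained to the window and `eta` to \[0, 1\]. Without
#' explicit starting values, centers are seeded at the `n_peaks` tallest
#' local maxima in the window (ties broken toward lower ppm), widths at
#' 0.01 ppm and `eta` at 0.5.
#'
#' @param spectrum An [mrs_spectrum()].
#' @param window Length-2 numeric, the ppm interval to fit (within the
#'   spectrum's range).
#' @param n_peaks Number of components to fit (>= 1).
#' @param init Optional list of [peak_model()] starting values (length
#'   `n_peaks`).
#' @param max_iter Maximum optimizer iterations.
#' @param baseline Also fit a constant offset over the window? Useful when
#'   slowly-varying tails of distant lines leak into the window; the offset
#'   is reported in the result, never counted in peak areas.
#' @return An object of class `fit_result`: list with `peaks` (sorted by
#'   center), `residual_norm` (RMS residual over the window), `converged`
#'   and `baseline` (0 when not fitted).
#' @export
fit_peaks <- function(spectrum, window, n_peaks = 1L, init = NULL,
                      max_iter = 500L, baseline = FALSE) {
  stopifnot(inherits(spectrum, "mrs_spectrum"), length(window) == 2L)
  window <- sort(as.numeric(window))
  if (window[1] < min(spectrum$ppm) || window[2] > max(spectrum$ppm))
    stop("window outside the spectrum's ppm range")
  if (n_peaks < 1L) stop("n_peaks must be >= 1")
  sel <- spectrum$ppm >= window[1] & spectrum$ppm <= window[2]
  x <- spectrum$ppm[sel]
  y <- spectrum$intensity[sel]
  if (length(x) < 4L * n_peaks)
    stop("window contains too few points for ", n_peaks, " peaks")

  if (is.null(init)) {
    mx <- local_maxima(y)
    if (length(mx) < n_peaks)
      stop("initialization error: only ", length(mx),
           " local maxima in window for ", n_peaks, " peaks")
    mx <- mx[seq_len(n_peaks)]
    init <- lapply(mx, function(i)
      peak_model(x[i], max(y[i], 1e-6), 0.01, 0.5))
  } else {
    if (length(init) != n_peaks) stop("init length must equal n_peaks")
    init <- lapply(init, function(pk)
      if (inherits(pk, "peak_model")) pk else do.call(peak_model, pk))
  }

  p0 <- unlist(lapply(init, function(pk)
    c(pk$center, pk$amplitude, pk$fwhm, pk$eta)))
  width <- window[2] - window[1]
  lower <- rep(c(window[1], 1e-12, 1e-5, 0), n_peaks)
  upper <- rep(c(window[2], Inf, max(width, 0.02), 1), n_peaks)
  if (baseline) {
    p0 <- c(p0, min(y))
    lower <- c(lower, -Inf)
    upper <- c(upper, Inf)
  }
  p0 <- pmin(pmax(p0, lower), upper)

  resid_fn <- function(p) {
    yhat <- if (baseline) rep(p[length(p)], length(x)) else numeric(length(x))
    for (k in seq_len(n_peaks)) {
      j <- (k - 1L) * 4L
      yhat <- yhat + pv_eval(x, p[j + 1], p[j + 2], p[j + 3], p[j + 4])
    }
    yhat - y
  }
  jac_fn <- function(p) {
    J <- matrix(0, length(x), length(p))
    if (baseline) J[, length(p)] <- 1
    for (k in seq_len(n_peaks)) {
      j <- (k - 1L) * 4L
      c0 <- p[j + 1]; a <- p[j + 2]; w <- p[j + 3]; eta <- p[j + 4]
      u <- (x - c0) / w
      g <- exp(-4 * log(2) * u^2)
      l <- 1 / (1 + 4 * u^2)
      shape <- eta * g + (1 - eta) * l
      # d shape / d u, then chain rule for center and width
      dgdu <- -8 * log(2) * u * g
      dldu <- -8 * u * l^2
      dsdu <- eta * dgdu + (1 - eta) * dldu
      J[, j + 1] <- a * dsdu * (-1 / w)
      J[, j + 2] <- shape
      J[, j + 3] <- a * dsdu * (-u / w)
      J[, j + 4] <- a * (g - l)
    }
    J
  }

  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper,
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = as.integer(max_iter), ftol = 1e-10, ptol = 1e-10))

  p <- fit$par
  peaks <- lapply(seq_len(n_peaks), function(k) {
    j <- (k - 1L) * 4L
    peak_model(p[j + 1], max(p[j + 2], 1e-12),
               max(p[j + 3], 1e-12), min(max(p[j + 4], 0), 1))
  })
  peaks <- peaks[order(vapply(peaks, `[[`, numeric(1), "center"))]
  structure(list(
    peaks = peaks,
    residual_norm = sqrt(mean(resid_fn(p)^2)),
    converged = fit$info %in% c(1L, 2L, 3L, 4L),
    baseline = if (baseline) p[length(p)] else 0,
    window = window),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d peak(s), rms residual %.4g, converged: %s\n",
              length(x$peaks), x$residual_norm, x$converged))
  for (pk in x$peaks)
    cat(sprintf("  center %.4f ppm  height %.4g  fwhm %.4g  eta %.3f\n",
                pk$center, pk$amplitude, pk$fwhm, pk$eta))
  invisible(x)
}
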