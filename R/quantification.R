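# Region table and conversion of fitted spectra into the 36-region
# relative-intensity matrix (percent of total 0.5-4.5 ppm fitted intensity).

#' Construct a spectral region table
#'
#' Named ppm intervals inside 0.5-4.5 ppm, each annotated with its likely
#' major contributing metabolites, plus contamination ranges (e.g. biopsy
#' lubricant gel) excluded from both numerator and denominator of every
#' relative intensity. Regions are half-open `[low, high)` so adjacent
#' regions partition cleanly.
#'
#' @param regions data.frame with columns `name`, `low_ppm`, `high_ppm`,
#'   `metabolites`.
#' @param excluded data.frame with columns `low_ppm`, `high_ppm` of excluded
#'   ranges; may be empty.
#' @return Object of class `region_table` (a data.frame with an `excluded`
#'   attribute).
#' @seealso [default_region_table()]
#' @export
region_table <- function(regions, excluded = data.frame(low_ppm = numeric(0),
                                                        high_ppm = numeric(0))) {
  need <- c("name", "low_ppm", "high_ppm", "metabolites")
  if (!all(need %in% names(regions)))
    stop("regions must have columns: ", paste(need, collapse = ", "))
  regions <- regions[order(regions$low_ppm), need]
  if (anyDuplicated(regions$name)) stop("duplicated region names")
  if (any(regions$low_ppm >= regions$high_ppm))
    stop("every region needs low_ppm < high_ppm")
  if (any(regions$low_ppm < 0.5 - 1e-9) || any(regions$high_ppm > 4.5 + 1e-9))
    stop("regions must lie within [0.5, 4.5] ppm")
  if (any(regions$high_ppm[-nrow(regions)] > regions$low_ppm[-1] + 1e-9))
    stop("regions overlap")
  for (i in seq_len(nrow(excluded))) {
    lo <- excluded$low_ppm[i]; hi <- excluded$high_ppm[i]
    if (lo >= hi) stop("excluded range with low >= high")
    if (any(regions$low_ppm < hi - 1e-9 & regions$high_ppm > lo + 1e-9))
      stop("excluded range [", lo, ", ", hi, "] overlaps a region")
  }
  rownames(regions) <- NULL
  structure(regions, excluded = excluded, class = c("region_table",
                                                    "data.frame"))
}

#' Default 36-region table
#'
#' Thirty-six half-open ppm intervals covering the commonly reported tissue
#' metabolite resonances in 0.5-4.5 ppm, with 3.65-3.75 ppm excluded as a
#' lubricant-gel contamination proxy. Region names are ppm labels ("3.60",
#' "0.93-0.96", ...). These bounds are literature-placed stand-ins: any
#' laboratory's own region definitions can be supplied via [region_table()]
#' or [read_region_table()] instead.
#'
#' Key anchored regions: "3.60" and "3.63" (myo-inositol, with GPC, PChol
#' and Val contributions at 3.60) whose sum forms the combined 3.60-3.63
#' super-region, and "0.93-0.96" (mobile lipids, minor Val).
#'
#' @return A `region_table` with exactly 36 regions.
#' @export
default_region_table <- function() {
  r <- data.frame(
    name = c("0.90", "0.93-0.96", "1.01", "1.05", "1.28", "1.33", "1.48",
             "1.59", "1.72", "1.92", "2.05", "2.10", "2.24", "2.35", "2.37",
             "2.45", "2.55", "2.63", "2.80", "3.03", "3.10", "3.20", "3.22",
             "3.23", "3.27", "3.35", "3.42", "3.48", "3.53", "3.56", "3.60",
             "3.63", "3.78", "3.93", "4.06", "4.12"),
    low_ppm = c(0.88, 0.93, 0.99, 1.03, 1.25, 1.31, 1.46, 1.57, 1.70, 1.90,
                2.02, 2.08, 2.22, 2.33, 2.37, 2.43, 2.52, 2.60, 2.78, 3.01,
                3.08, 3.19, 3.21, 3.23, 3.25, 3.33, 3.40, 3.46, 3.51, 3.55,
                3.58, 3.615, 3.76, 3.91, 4.04, 4.10),
    high_ppm = c(0.92, 0.96, 1.03, 1.07, 1.31, 1.35, 1.50, 1.61, 1.74, 1.94,
                 2.08, 2.13, 2.27, 2.37, 2.39, 2.47, 2.58, 2.66, 2.82, 3.05,
                 3.13, 3.21, 3.23, 3.25, 3.29, 3.37, 3.44, 3.50, 3.55, 3.58,
                 3.615, 3.65, 3.80, 3.95, 4.08, 4.14),
    metabolites = c("lipid CH3", "free lipids, Val", "Ile", "Val",
                    "lipid (CH2)n", "Lac", "Ala", "lipid CH2", "Lys, Spm",
                    "acetate", "N-acetyl groups", "Glu", "lipid beta-CH2",
                    "Glu", "Pyr", "Gln", "GSH", "citrate", "Asp", "Cr",
                    "Spm", "Cho", "PChol", "GPC", "Tau, m-Ino",
                    "scyllo-Ino", "Tau, Glc", "Glc, Gln", "m-Ino", "Gly",
                    "m-Ino, GPC, PChol, Val", "m-Ino", "Glu, Ala", "Cr",
                    "m-Ino", "Lac CH"),
    stringsAsFactors = FALSE)
  region_table(r, excluded = data.frame(low_ppm = 3.65, high_ppm = 3.75))
}

#' Names of member regions for combined super-regions
#'
#' The combined 3.60-3.63 ppm region (both myo-inositol triplet components)
#' is reported as the sum of its members' relative intensities.
#' @return Named list mapping combined-region name to member region names.
#' @export
combined_regions <- function() {
  list("3.60-3.63" = c("3.60", "3.63"))
}

#' Integrate fitted peaks over one region
#'
#' Sums the analytic areas of the fitted peaks whose centers fall inside the
#' half-open interval `[low, high)`; a peak centered exactly at the upper
#' edge belongs to the next region.
#'
#' @param fit A converged `fit_result` from [fit_peaks()].
#' @param region Length-2 numeric `(low, high)` in ppm.
#' @param sample_id Used in error messages.
#' @return Summed analytic area (>= 0).
#' @export
integrate_region <- function(fit, region, sample_id = "sample") {
  stopifnot(inherits(fit, "fit_result"), length(region) == 2L)
  if (!isTRUE(fit$converged))
    stop("unconverged fit for sample '", sample_id,
         "'; region integration refused")
  centers <- vapply(fit$peaks, `[[`, numeric(1), "center")
  inside <- centers >= region[1] & centers < region[2]
  if (!any(inside)) return(0)
  sum(vapply(fit$peaks[inside], peak_area, numeric(1)))
}

#' Normalize region intensities to percent of total
#'
#' @param intensities Numeric vector (or matrix row) of region intensities.
#' @param total Total fitted intensity over 0.5-4.5 ppm (> 0).
#' @return `100 * intensities / total`; invariant under global rescaling of
#'   the spectrum.
#' @export
normalize_regions <- function(intensities, total) {
  if (!is.finite(total) || total <= 0)
    stop("degenerate spectrum: total fitted intensity must be > 0")
  100 * intensities / total
}

#' Deconvolve one spectrum into fitted peaks
#'
#' Detects every resolved line in 0.5-4.5 ppm (local maxima above a noise
#' floor), clusters neighboring lines (gap <= `cluster_gap` ppm), and fits
#' each cluster jointly as pseudo-Voigt components plus a constant offset
#' that absorbs tails of distant lines. Overlapping multiplets are thereby
#' modeled together rather than truncated at region boundaries.
#'
#' @param spectrum An [mrs_spectrum()].
#' @param cluster_gap Maximum center-to-center gap (ppm) for two detected
#'   lines to be fitted in one window.
#' @param rel_floor Detection floor as a fraction of the spectrum maximum;
#'   the floor is never below 6x the point-noise estimate.
#' @param max_cluster Largest number of lines fitted jointly (clusters are
#'   split beyond this).
#' @return List with `peaks` (all fitted [peak_model()]s across clusters)
#'   and `ok` (FALSE when any cluster fit failed to converge).
#' @export
deconvolve_spectrum <- function(spectrum, cluster_gap = 0.12,
                                rel_floor = 5e-4, max_cluster = 16L) {
  sel <- spectrum$ppm >= 0.45 & spectrum$ppm <= 4.55
  x <- spectrum$ppm[sel]
  y <- spectrum$intensity[sel]
  noise <- stats::mad(diff(y)) / sqrt(2)
  floor_abs <- max(rel_floor * max(abs(y), 1e-12), 6 * noise)
  mx <- local_maxima(y)
  mx <- mx[y[mx] - stats::median(y) > floor_abs]
  if (length(mx) == 0L) return(list(peaks = list(), ok = TRUE))
  mx <- sort(mx)
  ctr <- x[mx]
  cluster <- cumsum(c(1, diff(ctr) > cluster_gap))
  # split oversized clusters at their widest internal gap(s)
  peaks <- list()
  ok <- TRUE
  for (cl in unique(cluster)) {
    idx <- mx[cluster == cl]
    while (length(idx) > max_cluster) {
      gaps <- diff(x[idx])
      cut <- which.max(gaps)
      part <- idx[seq_len(cut)]
      res <- fit_cluster(spectrum, x, y, part)
      peaks <- c(peaks, res$peaks); ok <- ok && res$ok
      idx <- idx[-seq_len(cut)]
    }
    res <- fit_cluster(spectrum, x, y, idx)
    peaks <- c(peaks, res$peaks); ok <- ok && res$ok
  }
  list(peaks = peaks, ok = ok)
}

fit_cluster <- function(spectrum, x, y, idx, pad = 0.03) {
  lo <- max(min(x[idx]) - pad, min(spectrum$ppm))
  hi <- min(max(x[idx]) + pad, max(spectrum$ppm))
  base0 <- min(y[x >= lo & x <= hi])
  init <- lapply(idx, function(i)
    peak_model(x[i], max(y[i] - base0, 1e-6), 0.01, 0.5))
  fit <- tryCatch(
    fit_peaks(spectrum, c(lo, hi), n_peaks = length(init), init = init,
              baseline = TRUE),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged)
    return(list(peaks = list(), ok = FALSE))
  list(peaks = fit$peaks, ok = TRUE)
}

# region areas for one spectrum from its deconvolved peaks; excluded-range
# peaks contribute to nothing, peaks in gaps between regions only to the
# denominator
spectrum_region_areas <- function(peaks, table) {
  excl <- attr(table, "excluded")
  centers <- vapply(peaks, `[[`, numeric(1), "center")
  areas <- vapply(peaks, peak_area, numeric(1))
  if (length(centers)) {
    drop <- rep(FALSE, length(centers))
    for (i in seq_len(nrow(excl)))
      drop <- drop | (centers >= excl$low_ppm[i] & centers < excl$high_ppm[i])
    drop <- drop | centers < 0.5 | centers >= 4.5
    centers <- centers[!drop]; areas <- areas[!drop]
  }
  reg <- vapply(seq_len(nrow(table)), function(r)
    sum(areas[centers >= table$low_ppm[r] & centers < table$high_ppm[r]]),
    numeric(1))
  list(region_areas = reg, total = sum(areas))
}

#' Quantify a cohort of spectra into the region intensity matrix
#'
#' Fits each region window of each spectrum with pseudo-Voigt components,
#' integrates the fitted peaks analytically, and normalizes each sample by
#' its total fitted intensity over all (non-excluded) regions in
#' 0.5-4.5 ppm. Combined super-regions (see [combined_regions()]) are
#' appended as sums of their members' relative intensities.
#'
#' Samples whose total fitted intensity is zero, or with a non-converging
#' window, are flagged (attribute `flagged`) and the pipeline continues.
#'
#' @param spectra List of [mrs_spectrum()] objects.
#' @param table A `region_table`; default [default_region_table()].
#' @param combined Named list of super-regions; default [combined_regions()]
#'   restricted to members present in `table`.
#' @return An `intensity_matrix`: numeric matrix, rows = samples (rownames =
#'   sample ids), columns = region names plus combined regions, entries =
#'   relative intensities in percent.
#' @export
quantify_cohort <- function(spectra, table = default_region_table(),
                            combined = combined_regions()) {
  stopifnot(inherits(table, "region_table"))
  combined <- Filter(function(m) all(m %in% table$name), combined)
  cn <- c(table$name, names(combined))
  if (length(spectra) == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(cn),
                dimnames = list(NULL, cn))
    return(structure(m, flagged = character(0),
                     class = c("intensity_matrix", class(m))))
  }
  flagged <- character(0)
  rows <- matrix(NA_real_, length(spectra), nrow(table))
  ids <- vapply(spectra, `[[`, character(1), "sample_id")
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    if (min(sp$ppm) > 0.5 || max(sp$ppm) < 4.5)
      stop("spectrum '", sp$sample_id, "' does not cover 0.5-4.5 ppm")
    dec <- deconvolve_spectrum(sp)
    ra <- spectrum_region_areas(dec$peaks, table)
    if (!dec$ok || ra$total <= 0) {
      flagged <- c(flagged, sp$sample_id)
      if (ra$total <= 0) {
        rows[i, ] <- 0
        next
      }
    }
    rows[i, ] <- normalize_regions(ra$region_areas, ra$total)
  }
  dimnames(rows) <- list(ids, table$name)
  for (nm in names(combined)) {
    add <- rowSums(rows[, combined[[nm]], drop = FALSE])
    rows <- cbind(rows, add)
    colnames(rows)[ncol(rows)] <- nm
  }
  structure(rows, flagged = flagged,
            class = c("intensity_matrix", class(rows)))
}
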