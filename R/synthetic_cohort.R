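# Seeded synthetic cohort generator: clinical covariates, planted
# region-level group effects, clustered repeat sampling per patient,
# rendered spectra, and recurrence/survival outcomes.

# default per-region baseline mean relative intensities (percent scale).
# Large mobile-lipid / citrate / taurine pools dominate; anchored regions
# sit near the group means the analysis expects (3.60 ~ 1.5, 3.60+3.63 ~ 6.5,
# 0.93-0.96 ~ 4.7 in the low/reference groups).
default_baseline_means <- function(regions) {
  m <- c("0.90" = 2.0, "0.93-0.96" = 4.7, "1.01" = 1.2, "1.05" = 1.0,
         "1.28" = 9.0, "1.33" = 7.0, "1.48" = 1.5, "1.59" = 1.8,
         "1.72" = 1.5, "1.92" = 1.2, "2.05" = 3.0, "2.10" = 3.0,
         "2.24" = 1.8, "2.35" = 2.5, "2.37" = 1.0, "2.45" = 1.5,
         "2.55" = 1.8, "2.63" = 8.0, "2.80" = 1.0, "3.03" = 4.0,
         "3.10" = 5.0, "3.20" = 2.2, "3.22" = 2.0, "3.23" = 2.5,
         "3.27" = 4.0, "3.35" = 1.0, "3.42" = 2.5, "3.48" = 1.5,
         "3.53" = 2.8, "3.56" = 1.5, "3.60" = 1.5, "3.63" = 5.0,
         "3.78" = 2.0, "3.93" = 3.0, "4.06" = 1.5, "4.12" = 3.0)
  out <- m[regions]
  out[is.na(out)] <- 1.0
  names(out) <- regions
  out
}

#' Effect configuration for the synthetic cohort
#'
#' Region-level generative model for relative intensities: per-region
#' baseline mean and SD, additive group effects keyed by (contrast, region),
#' a shared per-patient random intercept (expressed as a fraction of each
#' region's SD), and the recurrence model (hazard link on a planted
#' per-patient discriminant score, administrative censoring window).
#'
#' Default effects encode the qualitative structure the analysis looks for:
#' elevated 3.60/3.63 ppm (myo-inositol) in high-grade (PGG 3-5) disease,
#' elevated 0.93-0.96 ppm (mobile lipids) in pT = IIc, and a recurrence
#' score loading positively on choline compounds and glutamate and
#' negatively on myo-inositol.
#'
#' Recognized contrast keys: `pgg_high` (PGG in 3-5), `pt_iic`
#' (pT = IIc), `bcr_score` (delta per unit of the planted per-patient
#' score).
#'
#' @param regions Character vector of region names (defaults to the default
#'   region table's names).
#' @param baseline_mean,baseline_sd Named numeric vectors over `regions`.
#' @param effects data.frame with columns `contrast`, `region`, `delta`.
#' @param patient_sd Random-intercept SD as a multiple of each region's SD.
#' @param censor_months Administrative censoring window for recurrence.
#' @param hazard_link Log-hazard coefficient on the planted score.
#' @return Object of class `effect_config`.
#' @export
effect_config <- function(regions = default_region_table()$name,
                          baseline_mean = default_baseline_means(regions),
                          baseline_sd = pmax(0.18 * baseline_mean, 0.08),
                          effects = data.frame(
                            contrast = c("pgg_high", "pgg_high", "pt_iic",
                                         "bcr_score", "bcr_score",
                                         "bcr_score", "bcr_score",
                                         "bcr_score", "bcr_score"),
                            region = c("3.60", "3.63", "0.93-0.96",
                                       "3.20", "3.22", "3.23",
                                       "2.10", "3.60", "3.63"),
                            delta = c(0.58, 0.42, 1.8,
                                      0.40, 0.36, 0.45,
                                      0.54, -0.27, -0.90),
                            stringsAsFactors = FALSE),
                          patient_sd = 0.5,
                          censor_months = 180,
                          hazard_link = 1.3) {
  if (any(baseline_sd <= 0)) stop("baseline SDs must be > 0")
  bad <- setdiff(effects$region, regions)
  if (length(bad))
    stop("effects reference unknown regions: ", paste(bad, collapse = ", "))
  structure(list(regions = regions,
                 baseline_mean = baseline_mean[regions],
                 baseline_sd = baseline_sd[regions],
                 effects = effects,
                 patient_sd = patient_sd,
                 censor_months = censor_months,
                 hazard_link = hazard_link),
            class = "effect_config")
}

# moment-matched lognormal draw (mean m, sd s on the natural scale)
rlnorm_matched <- function(n, m, s) {
  sig2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sig2 / 2, sdlog = sqrt(sig2))
}

#' Generate a synthetic two-cohort tissue study
#'
#' Draws patients with clinical covariates and labels (marginals near the
#' study population this generator emulates: age 58.5 +/- 6.5 y, PSA
#' lognormal with mean 5.6 / SD 3.1 ng/ml, prostate weight 47 +/- 12.6 g,
#' PGG frequencies 86:52:13:4:3, pT frequencies 56:76:26), 1-4 tissue
#' samples per patient with a shared patient random intercept, per-sample
#' region intensities = baseline + group effects + score effects + patient
#' intercept + noise, and (optionally) renders each sample as a spectrum
#' whose pseudo-Voigt peaks realize those region areas. The train/test
#' split is at patient level, alternating patients.
#'
#' @param n_patients Total number of patients across both cohorts (>= 2).
#' @param samples_per_patient Integer vector sampled uniformly for each
#'   patient's number of tissue samples.
#' @param effects An [effect_config()].
#' @param table A `region_table`.
#' @param seed Integer seed; the cohort is a pure function of
#'   (arguments, seed).
#' @param render Render spectra? When `FALSE` (useful for large statistical
#'   simulations) the `spectra` element is an empty list and analyses use
#'   the returned `intensities` directly.
#' @param noise_sd Spectral (grid-level) noise SD passed to
#'   [synthesize_spectrum()]; region-level biological noise is always drawn.
#' @param ppm_step Grid spacing for rendered spectra.
#' @return List with `spectra` (list of [mrs_spectrum()]), `records`
#'   (data.frame of sample metadata/outcomes), `intensities` (matrix of the
#'   planted relative intensities, percent, rows aligned with `records`,
#'   combined super-regions appended) and `score` (named per-patient
#'   planted discriminant score).
#' @export
generate_cohort <- function(n_patients = 160, samples_per_patient = 1:4,
                            effects = effect_config(),
                            table = default_region_table(),
                            seed = 1, render = TRUE, noise_sd = 0,
                            ppm_step = 0.002) {
  if (n_patients < 2) stop("need at least 2 patients")
  stopifnot(inherits(effects, "effect_config"),
            inherits(table, "region_table"))
  if (!setequal(effects$regions, table$name))
    stop("effect config regions do not match the region table")
  set.seed(as.integer(seed))

  regions <- table$name
  mu <- effects$baseline_mean[regions]
  sd_r <- effects$baseline_sd[regions]

  pid <- sprintf("P%03d", seq_len(n_patients))
  cohort <- ifelse(seq_len(n_patients) %% 2L == 1L, "training", "testing")
  age <- pmin(pmax(stats::rnorm(n_patients, 58.5, 6.5), 41), 75)
  psa <- pmin(rlnorm_matched(n_patients, 5.6, 3.1), 20)
  weight <- pmin(pmax(stats::rnorm(n_patients, 47.0, 12.6), 20.8), 140.8)
  free_psa <- pmin(pmax(stats::rnorm(n_patients, 15.0, 8.4), 4), 45)
  pgg <- sample(c(1L, 2L, 3L, 4L, 5L), n_patients, replace = TRUE,
                prob = c(86, 52, 13, 4, 3) / 158)
  pt <- sample(c("IIab", "IIc", "III"), n_patients, replace = TRUE,
               prob = c(56, 76, 26) / 158)
  pni <- sample(c("positive", "negative"), n_patients, replace = TRUE,
                prob = c(97, 61) / 158)
  score <- stats::rnorm(n_patients)
  names(score) <- pid
  # per-patient, per-region random intercepts (clustering of repeat samples)
  intercept_z <- matrix(stats::rnorm(n_patients * length(regions)),
                        n_patients, length(regions))
  n_samp <- sample(samples_per_patient, n_patients, replace = TRUE)

  eff <- effects$effects
  delta_for <- function(contrast) {
    d <- stats::setNames(rep(0, length(regions)), regions)
    rows <- eff[eff$contrast == contrast, , drop = FALSE]
    if (nrow(rows)) d[rows$region] <- rows$delta
    d
  }
  d_pgg <- delta_for("pgg_high")
  d_ptc <- delta_for("pt_iic")
  d_bcr <- delta_for("bcr_score")

  rec_list <- list()
  int_list <- list()
  sp_list <- list()
  k <- 0L
  for (i in seq_len(n_patients)) {
    base_i <- mu +
      (pgg[i] >= 3) * d_pgg +
      (pt[i] == "IIc") * d_ptc +
      score[i] * d_bcr +
      effects$patient_sd * sd_r * intercept_z[i, ]
    for (s in seq_len(n_samp[i])) {
      k <- k + 1L
      sid <- sprintf("%s_S%d", pid[i], s)
      vals <- pmax(base_i + stats::rnorm(length(regions), 0, sd_r), 0.02)
      is_cancer <- stats::runif(1) < 0.07
      if (is_cancer) {
        v_can <- stats::runif(1, 10, 60)
        v_epi <- stats::runif(1, 5, 90 - v_can)
      } else {
        v_can <- 0
        v_epi <- stats::runif(1, 10, 60)
      }
      v_can <- round(v_can, 1)
      v_epi <- round(v_epi, 1)
      v_str <- round(100 - v_can - v_epi, 1)
      rec_list[[k]] <- data.frame(
        sample_id = sid, patient_id = pid[i], cohort = cohort[i],
        tissue_class = if (is_cancer) "cancer" else "Hb",
        vol_pct_benign_epithelium = v_epi,
        vol_pct_cancer = v_can,
        vol_pct_stroma = v_str,
        pgg = pgg[i], pt_stage = pt[i], psa = psa[i],
        psa_density = psa[i] / weight[i], free_psa_pct = free_psa[i],
        age = age[i], prostate_weight = weight[i], pni = pni[i],
        bcr = "none", bcr_months = NA_real_,
        death = FALSE, survival_months = NA_real_,
        stringsAsFactors = FALSE)
      int_list[[k]] <- vals
    }
  }
  records <- do.call(rbind, rec_list)
  raw <- do.call(rbind, int_list)
  dimnames(raw) <- list(records$sample_id, regions)
  planted <- 100 * raw / rowSums(raw)
  for (nm in names(combined_regions())) {
    mem <- combined_regions()[[nm]]
    if (all(mem %in% colnames(planted))) {
      planted <- cbind(planted, rowSums(planted[, mem, drop = FALSE]))
      colnames(planted)[ncol(planted)] <- nm
    }
  }

  if (render) {
    grid <- seq(0.4, 4.6, by = ppm_step)
    ctr <- (table$low_ppm + table$high_ppm) / 2
    fwhm <- 0.01
    eta <- 0.5
    shape_area <- fwhm * (eta * 0.5 * sqrt(pi / log(2)) + (1 - eta) * pi / 2)
    for (k in seq_len(nrow(records))) {
      areas <- raw[k, ]
      pk <- lapply(seq_along(areas), function(r)
        peak_model(ctr[r], areas[r] / shape_area, fwhm, eta))
      sp_list[[k]] <- synthesize_spectrum(
        pk, grid, noise_sd = noise_sd, baseline = 0,
        sample_id = records$sample_id[k])
    }
  }

  records <- generate_outcomes(records, score,
                               link = effects$hazard_link,
                               censor_months = effects$censor_months,
                               seed = as.integer(seed) %% 1000000L + 104729L)
  list(spectra = sp_list, records = records,
       intensities = planted, score = score)
}

#' Attach recurrence and survival outcomes to sample records
#'
#' Per-patient biochemical recurrence (BCR) time drawn from an exponential
#' distribution whose log-hazard is proportional to the planted
#' discriminant score, with administrative censoring; death times are a
#' thinned, delayed transform of the BCR times. The baseline hazard is set
#' so that roughly a quarter of patients recur inside the censoring window
#' at `link = 0`.
#'
#' @param records data.frame of sample records (one or more rows per
#'   patient).
#' @param planted_score Named numeric vector, one score per patient id.
#' @param link Log-hazard coefficient (>= 0 plants higher hazard at higher
#'   score).
#' @param censor_months Administrative censoring window (>= 0).
#' @param seed Integer seed.
#' @return `records` with `bcr`, `bcr_months`, `death`, `survival_months`
#'   filled in (constant within patient).
#' @export
generate_outcomes <- function(records, planted_score, link = 1.3,
                              censor_months = 180, seed = 1) {
  if (censor_months < 0) stop("censor window must be >= 0")
  pids <- unique(records$patient_id)
  if (!all(pids %in% names(planted_score)))
    stop("planted_score must cover every patient id")
  set.seed(as.integer(seed))
  base_rate <- -log(1 - 0.25) / max(censor_months, 1)
  for (p in pids) {
    sc <- planted_score[[p]]
    t_bcr <- stats::rexp(1, rate = base_rate * exp(link * sc))
    event <- censor_months > 0 && t_bcr < censor_months
    rows <- records$patient_id == p
    records$bcr[rows] <- if (event) "event" else "free"
    records$bcr_months[rows] <- round(if (event) t_bcr else censor_months, 1)
    dies <- event && stats::runif(1) < 0.25
    t_death <- t_bcr + stats::rexp(1, rate = 1 / 36)
    records$death[rows] <- dies
    records$survival_months[rows] <-
      round(if (dies) t_death else censor_months, 1)
  }
  records
}
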