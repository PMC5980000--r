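# shared fixtures: tiny deterministic spectra and cohorts built in code

fine_grid <- function(from = 0.4, to = 4.6, by = 0.001) seq(from, to, by = by)

# spectrum with a single clean peak on a dense grid
single_peak_spectrum <- function(center = 3.60, amplitude = 5, fwhm = 0.008,
                                 eta = 0.3, noise_sd = 0, seed = 1,
                                 grid = seq(center - 0.1, center + 0.1,
                                            by = 5e-4)) {
  synthesize_spectrum(list(peak_model(center, amplitude, fwhm, eta)), grid,
                      noise_sd = noise_sd, seed = seed, sample_id = "single")
}

# zero-effect configuration (no group effects, no patient clustering)
null_effect_config <- function(patient_sd = 1e-9, ...) {
  effect_config(effects = data.frame(contrast = character(0),
                                     region = character(0),
                                     delta = numeric(0)),
                patient_sd = patient_sd, ...)
}

# deterministic "perfectly normal" sample: Gaussian quantiles
gaussian_quantile_sample <- function(n, mean = 0, sd = 1) {
  mean + sd * stats::qnorm(stats::ppoints(n))
}

# brute-force AUC: concordant pairs plus half ties over all class pairs
brute_auc <- function(scores, labels) {
  labels <- factor(labels)
  pos <- scores[labels == levels(labels)[2]]
  neg <- scores[labels != levels(labels)[2]]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force two-group log-rank: per-event-time 2x2 observed-minus-expected
brute_logrank <- function(times, events, group) {
  group <- as.integer(factor(group)) == 1L
  tt <- sort(unique(times[events]))
  O <- E <- V <- 0
  for (t in tt) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(events & times == t)
    d1 <- sum(events & times == t & group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
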