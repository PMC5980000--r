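# File formats (spectrum CSV / JCAMP-DX, cohort TSV, region table JSON/TSV,
# profile JSON), run configuration and the end-to-end pipeline runner.

#' Percentage of a count, printed-style
#'
#' `round(100 * n / d)` — how cohort fractions are reported (e.g. 27 of 365
#' samples -> 7).
#' @param n Numerator count.
#' @param d Denominator count (> 0).
#' @param digits Decimal places (default 0).
#' @return Numeric percentage.
#' @export
as_pct <- function(n, d, digits = 0) {
  if (d <= 0) stop("denominator must be > 0")
  round(100 * n / d, digits)
}

#' Read a spectrum from CSV or JCAMP-DX
#'
#' CSV: two columns `ppm,intensity` with that header. JCAMP-DX: a minimal
#' reader for `##XYDATA=(X++(Y..Y))` blocks in the fixed-point (AFFN)
#' dialect, using FIRSTX/LASTX/XFACTOR/YFACTOR/NPOINTS. Either way the grid
#' is re-sorted ascending and non-finite intensities are rejected with the
#' offending line number.
#'
#' @param path File path (`.csv` or `.jdx`/`.dx`).
#' @return An [mrs_spectrum()]; `sample_id` is the file stem.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sid <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  if (grepl("^##", first)) return(read_jcampdx(path, sid))
  header <- strsplit(trimws(first), ",")[[1]]
  if (!identical(tolower(trimws(header)), c("ppm", "intensity")))
    stop("malformed header in ", path, ": expected 'ppm,intensity'")
  lines <- readLines(path)[-1]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ",")
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != 2L)
      stop("parse error at line ", i + 1L, " of ", path)
    v <- suppressWarnings(as.numeric(parts[[i]]))
    if (any(!is.finite(v)))
      stop("non-numeric or non-finite value at line ", i + 1L, " of ", path)
    parts[[i]] <- v
  }
  m <- do.call(rbind, parts)
  mrs_spectrum(m[, 1], m[, 2], sid)
}

read_jcampdx <- function(path, sid) {
  lines <- readLines(path)
  getfield <- function(key) {
    i <- grep(paste0("^##", key, "="), lines)
    if (!length(i)) return(NA_real_)
    suppressWarnings(as.numeric(sub(paste0("^##", key, "="), "",
                                    lines[i[1]])))
  }
  firstx <- getfield("FIRSTX"); lastx <- getfield("LASTX")
  npts <- getfield("NPOINTS")
  xf <- getfield("XFACTOR"); yf <- getfield("YFACTOR")
  if (is.na(xf)) xf <- 1
  if (is.na(yf)) yf <- 1
  i0 <- grep("^##XYDATA=", lines)
  if (!length(i0)) stop("no ##XYDATA block in ", path)
  iend <- grep("^##END", lines)
  iend <- iend[iend > i0[1]][1]
  if (is.na(iend)) iend <- length(lines) + 1L
  body <- lines[(i0[1] + 1L):(iend - 1L)]
  xs <- c(); ys <- c()
  for (ln in body) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln),
                                                 "[ \t]+")[[1]]))
    if (any(is.na(vals))) stop("non-numeric JCAMP data line in ", path)
    xs <- c(xs, vals[1])
    ys <- c(ys, vals[-1])
  }
  if (is.na(npts)) npts <- length(ys)
  if (length(ys) != npts)
    stop("JCAMP NPOINTS mismatch in ", path, ": header says ", npts,
         ", found ", length(ys))
  x <- seq(firstx, lastx, length.out = npts) * xf
  mrs_spectrum(x, ys * yf, sid)
}

#' Write a spectrum as a two-column CSV
#'
#' @param spectrum An [mrs_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "mrs_spectrum"))
  df <- data.frame(ppm = spectrum$ppm, intensity = spectrum$intensity)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

cohort_enums <- list(
  cohort = c("training", "testing"),
  tissue_class = c("Hb", "cancer", "BPH", "Bx"),
  pt_stage = c("IIab", "IIc", "III", "none"),
  pni = c("positive", "negative", "none"),
  bcr = c("event", "free", "none"))

#' Validate and read a cohort sample-record table (TSV)
#'
#' Checks the controlled vocabularies (cohort, tissue class, pT, PNI, BCR),
#' that volume percentages sum to 100 +/- 0.1, that histologically benign
#' samples carry zero cancer volume, and that `bcr_months` is present
#' exactly when `bcr != "none"`. Offending rows are listed in errors.
#'
#' @param path TSV path with a header row.
#' @return data.frame of typed sample records.
#' @export
read_cohort <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  validate_cohort(rec)
  rec
}

validate_cohort <- function(rec) {
  for (col in names(cohort_enums)) {
    if (!col %in% names(rec)) next
    bad <- which(!is.na(rec[[col]]) & !rec[[col]] %in% cohort_enums[[col]])
    if (length(bad))
      stop("invalid ", col, " code(s) in row(s) ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  if (!is.null(rec$pgg)) {
    bad <- which(!is.na(rec$pgg) & !rec$pgg %in% 1:5)
    if (length(bad))
      stop("invalid pgg value(s) in row(s) ", paste(bad, collapse = ", "))
  }
  vol <- rec$vol_pct_benign_epithelium + rec$vol_pct_cancer +
    rec$vol_pct_stroma
  bad <- which(abs(vol - 100) > 0.1)
  if (length(bad))
    stop("vol% columns do not sum to 100 in row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(rec$tissue_class == "Hb" & rec$vol_pct_cancer > 0)
  if (length(bad))
    stop("Hb sample(s) with nonzero cancer vol% in row(s) ",
         paste(bad, collapse = ", "))
  if (!is.null(rec$bcr)) {
    need <- rec$bcr %in% c("event", "free")
    bad <- which((need & is.na(rec$bcr_months)) |
                   (!need & !is.na(rec$bcr_months)))
    if (length(bad))
      stop("bcr_months must be present iff bcr is event/free; row(s) ",
           paste(bad, collapse = ", "))
  }
  invisible(rec)
}

#' Write a cohort sample-record table (TSV)
#'
#' @param records data.frame of sample records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  validate_cohort(records)
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write a region table (TSV or JSON)
#'
#' TSV columns: `name  low_ppm  high_ppm  metabolites`; excluded ranges go
#' in a JSON sidecar field when JSON is used, or are absent for TSV.
#'
#' @param path `.tsv` or `.json` path.
#' @return A `region_table`.
#' @export
read_region_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    excl <- if (!is.null(obj$excluded) && length(obj$excluded))
      as.data.frame(obj$excluded)
    else data.frame(low_ppm = numeric(0), high_ppm = numeric(0))
    return(region_table(as.data.frame(obj$regions), excl))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  region_table(df)
}

#' @rdname read_region_table
#' @param table A `region_table` to write.
#' @export
write_region_table <- function(table, path) {
  stopifnot(inherits(table, "region_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(regions = as.data.frame(unclass(table)),
                              excluded = attr(table, "excluded")),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(unclass(table)), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory.
#' @param seed Integer seed (default 0) driving every random draw.
#' @param n_patients Patients simulated across both cohorts.
#' @param n_components PCs retained in the profile.
#' @param k_pcs PCs selected for the recurrence discriminant.
#' @param alpha Family-wise level for region/PC screening.
#' @param targets Screening targets (see [derive_target()]).
#' @param survival_stage Run the Kaplan-Meier / survival stage?
#' @param render_spectra Render and re-quantify spectra (full fidelity) or
#'   analyse the generator's region intensities directly.
#' @param force Overwrite a non-empty output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("tissuemrs_run_"), seed = 0,
                       n_patients = 160, n_components = 14L, k_pcs = 5L,
                       alpha = 0.05,
                       targets = c("pgg_group", "pt_binary",
                                   "aggressiveness"),
                       survival_stage = TRUE, render_spectra = TRUE,
                       force = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_patients = n_patients, n_components = n_components,
                 k_pcs = k_pcs, alpha = alpha, targets = targets,
                 survival_stage = survival_stage,
                 render_spectra = render_spectra, force = force),
            class = "run_config")
}

# greedy 1:1 matching of event cases to event-free cases within cohort,
# preferring same PGG then nearest (psa_density, age)
match_pairs <- function(df) {
  ev <- df[df$bcr == "event", , drop = FALSE]
  fr <- df[df$bcr == "free", , drop = FALSE]
  used <- logical(nrow(fr))
  pairs <- list()
  for (i in seq_len(nrow(ev))) {
    cand <- which(!used & fr$pgg == ev$pgg[i])
    if (!length(cand)) cand <- which(!used)
    if (!length(cand)) break
    d <- abs(fr$psa_density[cand] - ev$psa_density[i]) * 10 +
      abs(fr$age[cand] - ev$age[i]) / 10
    j <- cand[which.min(d)]
    used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(ev$patient_id[i], fr$patient_id[j])
  }
  pairs
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages: simulate -> quantify -> screen (training) -> profile (train) ->
#' transfer (testing) -> outcomes. Writes the cohort TSV, the intensity
#' matrix TSV, screening TSVs, the frozen profile JSON and a summary JSON
#' into `config$out_dir`, then returns the summary.
#'
#' @param config A [run_config()].
#' @return Named list (the summary), invisibly also written as
#'   `summary.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (dir.exists(out) && length(dir(out)) && !config$force)
    stop("output directory ", out, " is not empty; use force = TRUE")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  table <- default_region_table()

  message("[simulate] n_patients=", config$n_patients,
          " seed=", config$seed)
  cohort <- generate_cohort(n_patients = config$n_patients,
                            table = table, seed = config$seed,
                            render = config$render_spectra)
  write_cohort(cohort$records, file.path(out, "cohort.tsv"))
  write_region_table(table, file.path(out, "regions.tsv"))

  if (config$render_spectra) {
    message("[quantify] fitting ", length(cohort$spectra), " spectra x ",
            nrow(table), " regions")
    X <- quantify_cohort(cohort$spectra, table)
  } else {
    message("[quantify] using generator region intensities directly")
    X <- cohort$intensities
  }
  utils::write.table(data.frame(sample_id = rownames(X), X,
                                check.names = FALSE),
                     file.path(out, "intensities.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  rec <- cohort$records
  hb <- rec$tissue_class == "Hb"
  tr <- hb & rec$cohort == "training"
  te <- hb & rec$cohort == "testing"

  screens <- list()
  for (tgt in config$targets) {
    message("[screen] training cohort, target=", tgt)
    screens[[tgt]] <- screen_features(X[tr, , drop = FALSE],
                                      rec[tr, , drop = FALSE], tgt,
                                      alpha_family = config$alpha)
  }
  all_screens <- do.call(rbind, screens)
  utils::write.table(all_screens, file.path(out, "screen.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # patient-level (case) matrix for recurrence profiling: mean over each
  # patient's Hb samples, region columns only
  region_cols <- table$name
  case_rows <- function(mask) {
    pids <- unique(rec$patient_id[mask])
    M <- t(vapply(pids, function(p) {
      colMeans(X[mask & rec$patient_id == p, region_cols, drop = FALSE])
    }, numeric(length(region_cols))))
    rownames(M) <- pids
    M
  }
  tr_cases <- case_rows(tr)
  te_cases <- case_rows(te)
  case_info <- function(pids) {
    i <- match(pids, rec$patient_id)
    data.frame(patient_id = pids, pgg = rec$pgg[i], bcr = rec$bcr[i],
               bcr_months = rec$bcr_months[i], psa = rec$psa[i],
               pt_stage = rec$pt_stage[i], age = rec$age[i],
               psa_density = rec$psa_density[i],
               death = rec$death[i],
               survival_months = rec$survival_months[i],
               stringsAsFactors = FALSE)
  }
  tr_info <- case_info(rownames(tr_cases))
  te_info <- case_info(rownames(te_cases))

  message("[profile] matched recurrence pairs, PCA + canonical discriminant")
  pairs <- match_pairs(tr_info[tr_info$pgg %in% 1:3 &
                                 tr_info$pt_stage != "III", , drop = FALSE])
  pair_ids <- unlist(pairs)
  lab_all <- factor(ifelse(rownames(tr_cases) %in% pair_ids,
                           tr_info$bcr[match(rownames(tr_cases),
                                             tr_info$patient_id)], NA),
                    levels = c("free", "event"))
  model <- train_profile(tr_cases, lab_all,
                         n_components = config$n_components,
                         k = config$k_pcs,
                         msd_reference = X[te, "3.60-3.63"])
  write_profile(model, file.path(out, "profile.json"))

  message("[transfer] applying frozen profile to the testing cohort")
  pairs_te <- match_pairs(te_info[te_info$pgg %in% 1:3 &
                                    te_info$pt_stage != "III", ,
                                  drop = FALSE])
  te_pair_ids <- unlist(pairs_te)
  te_scores <- canonical_scores(model, te_cases[te_pair_ids, , drop = FALSE])
  te_lab <- factor(te_info$bcr[match(te_pair_ids, te_info$patient_id)],
                   levels = c("free", "event"))
  roc_te <- roc_summary(te_scores, te_lab)

  msd <- msd_threshold(X[te, "3.60-3.63"])
  agg_te <- derive_target(rec[te, , drop = FALSE], "aggressiveness")
  low_flags <- msd$flags[!is.na(agg_te) & agg_te == "low"]

  summary <- list(
    seed = config$seed,
    n_patients = config$n_patients,
    n_samples = nrow(rec),
    n_hb_samples = sum(hb),
    n_regions = length(region_cols),
    bonferroni_regions = as.numeric(bonferroni_threshold(
      config$alpha, length(region_cols))),
    bonferroni_pcs = as.numeric(bonferroni_threshold(
      config$alpha, config$n_components)),
    variance_explained_retained = sum(
      model$var_explained[seq_len(config$n_components)]),
    flagged_samples = attr(X, "flagged"),
    screen = lapply(screens, function(s)
      s[s$tier != "none", c("feature", "target", "test", "p_value", "tier")]),
    testing_bcr_auc = roc_te$auc,
    testing_bcr_accuracy = roc_te$overall_accuracy,
    msd_threshold = msd$threshold,
    msd_flagged_low_aggressive_frac =
      if (length(low_flags)) mean(low_flags) else NA_real_)

  if (config$survival_stage) {
    message("[outcomes] KM split at frozen threshold, log-rank, survival")
    pgg23 <- te_info$pgg %in% c(2, 3) & te_info$bcr %in% c("event", "free")
    km_sc <- canonical_scores(model, te_cases[pgg23, , drop = FALSE])
    grp <- km_sc > model$km_threshold
    if (length(unique(grp)) == 2L) {
      lr <- logrank(te_info$bcr_months[pgg23],
                    te_info$bcr[pgg23] == "event", grp)
      summary$km_logrank_stat <- lr$statistic
      summary$km_logrank_p <- lr$p_value
      km_hi <- km_estimate(te_info$bcr_months[pgg23][grp],
                           te_info$bcr[pgg23][grp] == "event")
      km_lo <- km_estimate(te_info$bcr_months[pgg23][!grp],
                           te_info$bcr[pgg23][!grp] == "event")
      km_tab <- rbind(
        data.frame(group = "above", time = km_hi$time, surv = km_hi$surv,
                   n_risk = km_hi$n_risk),
        data.frame(group = "below", time = km_lo$time, surv = km_lo$surv,
                   n_risk = km_lo$n_risk))
      utils::write.table(km_tab, file.path(out, "km.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    dec <- te_info$death %in% TRUE
    if (sum(dec) >= 3) {
      reg <- score_survival_regression(
        canonical_scores(model, te_cases[dec, , drop = FALSE]),
        te_info$survival_months[dec])
      summary$survival_slope <- reg$slope
      summary$survival_r <- reg$correlation
      summary$survival_p <- reg$p_value
    }
    comb <- combine_with_psa(te_scores,
                             te_info$psa[match(te_pair_ids,
                                               te_info$patient_id)],
                             te_lab)
    summary$testing_bcr_auc_with_psa <-
      roc_summary(comb$combined_scores, te_lab)$auc
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(summary)
}
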