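# End-to-end orchestration: configuration, file simulation/extraction, and
# the full OFF/ON analysis (univariate statistics, hypokinetic and
# hyperkinetic models, compound scores, LOOCV, transition experiment).

#' Pipeline configuration
#'
#' Validated bundle of the tunable analysis parameters; every downstream
#' stage reads from it so a run is fully described by its config + seed.
#'
#' @param frame,hop Acoustic frame length and hop, s.
#' @param f_min,f_max F0 search range, Hz.
#' @param voicing_threshold Autocorrelation voicing threshold.
#' @param silence_rel_db Segmentation threshold below track maximum, dB.
#' @param pause_min,speech_min Segmentation floors, s.
#' @param ltas_band LTAS band, Hz.
#' @param alpha_normality Shapiro-Wilk routing level.
#' @param importance_method `"pmvd"` or `"lmg"`.
#' @param exact_max Largest p for exact importance enumeration.
#' @param threshold Classification threshold.
#' @param nested_selection Re-run selection inside LOOCV folds?
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(frame = 0.04, hop = 0.01, f_min = 60, f_max = 400,
                            voicing_threshold = 0.45, silence_rel_db = 25,
                            pause_min = 0.06, speech_min = 0.06,
                            ltas_band = c(0, 8000), alpha_normality = 0.05,
                            importance_method = c("pmvd", "lmg"),
                            exact_max = 12, threshold = 0.5,
                            nested_selection = FALSE) {
  importance_method <- match.arg(importance_method)
  stopifnot(frame > 0, hop > 0, hop <= frame, 0 < f_min, f_min < f_max,
            voicing_threshold > 0, voicing_threshold < 1,
            length(ltas_band) == 2, ltas_band[1] < ltas_band[2],
            alpha_normality > 0, alpha_normality < 1,
            threshold > 0, threshold < 1, exact_max >= 1)
  structure(list(frame = frame, hop = hop, f_min = f_min, f_max = f_max,
                 voicing_threshold = voicing_threshold,
                 silence_rel_db = silence_rel_db, pause_min = pause_min,
                 speech_min = speech_min, ltas_band = ltas_band,
                 alpha_normality = alpha_normality,
                 importance_method = importance_method,
                 exact_max = exact_max, threshold = threshold,
                 nested_selection = nested_selection),
            class = "pipeline_config")
}

#' Run the full OFF/ON analysis on a paired cohort
#'
#' Reproduces the analysis chain on one cohort: (1) normality-routed paired
#' OFF/ON comparisons with Holm adjustment over the 16 biomarkers; (2)
#' backward stepwise AIC linear models of the hypokinetic outcome
#' (MDS-UPDRS-III without tremor change) and the hyperkinetic outcome
#' (Marconi axial change) starting from all 16 change scores; (3) pmvd
#' importance and weighted z-scored compound scores for both models; (4)
#' LOOCV metrics and per-subscore prediction for the hypokinetic feature
#' set; (5) the randomized medication-state-transition experiment on the
#' union of the selected features.
#'
#' @param cohort A `paired_cohort`.
#' @param seed Integer seed (drives the transition label draw).
#' @param config A [pipeline_config()].
#' @return A `levo_analysis` list; see the individual components.
#' @export
analyze_cohort <- function(cohort, seed = 1, config = pipeline_config()) {
  stopifnot(inherits(cohort, "paired_cohort"))
  feats <- canonical_features()
  ch <- cohort_changes(cohort)
  Xall <- as.data.frame(ch[, feats])

  comparisons <- paired_compare_all(cohort, feats, config$alpha_normality)
  comparisons$effect_class <-
    vapply(comparisons$effect_size, effect_size_classify, character(1))

  fit_branch <- function(y) {
    sw <- stepwise_linear(Xall, y)
    if (!length(sw$selected)) return(list(stepwise = sw))
    imp <- if (length(sw$selected) <= config$exact_max)
      importance(Xall, y, sw$selected, config$importance_method)
    else importance(Xall, y, sw$selected, config$importance_method,
                    n_orderings = 5000, seed = seed)
    ref <- data.frame(feature = sw$selected,
                      mean = vapply(Xall[sw$selected], mean, numeric(1)),
                      sd = vapply(Xall[sw$selected], sd, numeric(1)))
    comp <- build_compound(sw, imp, ref)
    score <- apply_compound(comp, Xall)
    list(stepwise = sw, importance = imp, compound = comp,
         compound_scores = score,
         compound_cor = cor(score, y),
         loocv = loocv_regression(Xall[, sw$selected, drop = FALSE], y))
  }

  hypo <- fit_branch(ch$d_updrs3_nt)
  hyper <- fit_branch(ch$d_marconi_axial)

  subscores <- if (length(hypo$stepwise$selected)) {
    sub <- ch[, c("d_bradykinesia", "d_axial", "d_rigidity", "d_tremor")]
    ok <- vapply(sub, function(v) sd(v) > 0, logical(1))
    predict_subscores(Xall[, hypo$stepwise$selected, drop = FALSE],
                      sub[, ok, drop = FALSE])
  } else NULL

  pool <- union(hypo$stepwise$selected, hyper$stepwise$selected)
  transition <- if (length(pool) >= 1) {
    ds <- make_transition_dataset(Xall, seed = seed)
    transition_eval(ds, pool, nested = config$nested_selection)
  } else NULL

  structure(list(comparisons = comparisons, hypokinetic = hypo,
                 hyperkinetic = hyper, subscores = subscores,
                 transition = transition, changes = ch,
                 config = config, seed = seed),
            class = "levo_analysis")
}

#' @export
print.levo_analysis <- function(x, ...) {
  cat("<levo_analysis>\n== hypokinetic model ==\n")
  print(x$hypokinetic$stepwise)
  if (!is.null(x$hypokinetic$loocv)) {
    cat(sprintf("  compound r = %.3f\n", x$hypokinetic$compound_cor))
    print(x$hypokinetic$loocv)
  }
  cat("== hyperkinetic model ==\n")
  print(x$hyperkinetic$stepwise)
  if (!is.null(x$hyperkinetic$loocv))
    cat(sprintf("  compound r = %.3f\n", x$hyperkinetic$compound_cor))
  if (!is.null(x$transition)) {
    cat("== transition model ==\n")
    print(x$transition)
  }
  invisible(x)
}

#' Simulate a synthetic study to files
#'
#' Writes the feature cohort (`cohort_features.csv`), the clinical tables
#' (`cohort_clinical.csv`), the healthy-control features (`hc_features.csv`)
#' and a ground-truth JSON sidecar; with `audio = TRUE` also writes
#' `{subject}_{state}_{task}.wav` recordings whose planted parameters follow
#' each subject's cohort feature values.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [synthetic_cohort_spec()].
#' @param audio Also synthesize per-subject WAV files? (Sizeable: three
#'   tasks per subject and state.)
#' @param seed Integer seed.
#' @return Invisibly, the generated `paired_cohort`.
#' @export
pipeline_simulate <- function(out_dir, spec = synthetic_cohort_spec(),
                              audio = FALSE, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec$seed <- if (!is.null(spec$seed)) spec$seed else seed
  cohort <- gen_cohort(spec)
  utils::write.csv(cohort$features, file.path(out_dir, "cohort_features.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(out_dir, "cohort_clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$hc, file.path(out_dir, "hc_features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = spec$seed, n_pd = spec$n_pd, n_hc = spec$n_hc,
         effect_scale = spec$effect_scale, D = cohort$truth$D,
         planted_hypo = as.list(spec$planted_hypo_features),
         planted_hyper = as.list(spec$planted_hyper_features)),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  if (audio) {
    f <- cohort$features
    for (i in seq_len(nrow(f))) {
      row <- f[i, ]
      base <- sprintf("%s_%s", row$subject, row$state)
      sd_seed <- (spec$seed * 1000L + i) %% .Machine$integer.max
      ph <- audio_ground_truth("phon",
        f0_mean = 120, f0_sd = 0.3, snr = max(5, row$HNR_phon),
        intensity_slope = row$Int_slope_phon,
        phonation_dur = min(max(row$MPT_phon, 0.6), 8), seed = sd_seed)
      write_wav(synth_phonation(ph),
                file.path(out_dir, paste0(base, "_phon.wav")))
      dk <- audio_ground_truth("ddk", vot_gap = max(0, row$VOT_ddk),
        syllable_count = 36L, snr = 30, seed = sd_seed + 1L)
      write_wav(synth_ddk(dk), file.path(out_dir, paste0(base, "_ddk.wav")))
      n_pause <- 4L
      tx <- audio_ground_truth("text",
        f0_mean = 110, f0_sd = max(0.2, row$sdF0_text),
        intensity_sd = max(0.2, row$Int_sd_text / 4),
        pause_durations = rep(max(0.08, row$DPI_text / 1000), n_pause),
        syllable_count = max(10L, round(row$NSR_text * 4)),
        snr = 30, seed = sd_seed + 2L)
      write_wav(synth_reading(tx), file.path(out_dir, paste0(base, "_text.wav")))
    }
  }
  invisible(cohort)
}

#' Extract biomarker tables from a directory of WAV recordings
#'
#' Expects files named `{subject}_{state}_{task}.wav` (task one of
#' phon/ddk/text, repeats may append `_2` etc.); unreadable files are
#' skipped with a warning. Writes one row per subject/state with the 16
#' canonical columns.
#'
#' @param audio_dir Directory of WAV files.
#' @param out_csv Output CSV path (optional).
#' @param config A [pipeline_config()].
#' @return The feature tibble, invisibly if `out_csv` is given.
#' @export
pipeline_extract <- function(audio_dir, out_csv = NULL,
                             config = pipeline_config()) {
  files <- list.files(audio_dir, pattern = "\\.wav$", full.names = TRUE)
  if (!length(files)) stop("no WAV files in ", audio_dir, call. = FALSE)
  info <- regmatches(basename(files),
                     regexec("^(.+)_(OFF|ON)_(phon|ddk|text)(_\\d+)?\\.wav$",
                             basename(files)))
  ok <- lengths(info) == 5L
  if (!any(ok)) stop("no files match {subject}_{state}_{task}.wav", call. = FALSE)
  meta <- do.call(rbind, lapply(info[ok], function(m)
    data.frame(file = NA, subject = m[2], state = m[3], task = m[4])))
  meta$file <- files[ok]
  groups <- split(meta, paste(meta$subject, meta$state))
  rows <- list()
  for (g in groups) {
    recs <- list()
    bad <- FALSE
    for (task in unique(g$task)) {
      ws <- lapply(g$file[g$task == task], function(fp)
        tryCatch(read_wav(fp, task = task),
                 error = function(e) {
                   warning("skipping unreadable WAV: ", fp, call. = FALSE)
                   NULL
                 }))
      ws <- Filter(Negate(is.null), ws)
      if (length(ws)) recs[[task]] <- ws
    }
    if (!length(recs)) next
    v <- extract_all(recs, frame = config$frame, hop = config$hop,
                     f_min = config$f_min, f_max = config$f_max,
                     voicing_threshold = config$voicing_threshold)
    rows[[length(rows) + 1L]] <-
      dplyr::bind_cols(tibble::tibble(subject = g$subject[1], state = g$state[1]),
                       tibble::as_tibble(as.list(v)))
  }
  if (!length(rows)) stop("all WAV files failed to extract", call. = FALSE)
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_csv)) {
    utils::write.csv(out, out_csv, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Fit and evaluate from feature/clinical CSV files
#'
#' Joins a feature table and a clinical table (as written by
#' [pipeline_simulate()]), runs [analyze_cohort()], and writes the model
#' reports to `out_dir` (JSON summary + per-subject prediction CSVs).
#'
#' @param features_csv,clinical_csv,hc_csv Input tables; `hc_csv` optional.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param config A [pipeline_config()].
#' @return The `levo_analysis`, invisibly.
#' @export
pipeline_fit_evaluate <- function(features_csv, clinical_csv, hc_csv = NULL,
                                  out_dir, seed = 1,
                                  config = pipeline_config()) {
  for (fp in c(features_csv, clinical_csv))
    if (!file.exists(fp)) stop("missing input file: ", fp, call. = FALSE)
  features <- tibble::as_tibble(utils::read.csv(features_csv))
  clinical <- tibble::as_tibble(utils::read.csv(clinical_csv))
  miss <- setdiff(unique(features$subject), unique(clinical$subject))
  if (length(miss))
    stop("subjects missing from clinical table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  hc <- if (!is.null(hc_csv) && file.exists(hc_csv))
    tibble::as_tibble(utils::read.csv(hc_csv)) else NULL
  cohort <- structure(list(features = features, clinical = clinical,
                           hc = hc, truth = NULL), class = "paired_cohort")
  res <- analyze_cohort(cohort, seed = seed, config = config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    seed = seed,
    comparisons = res$comparisons,
    hypokinetic = model_report(res$hypokinetic),
    hyperkinetic = model_report(res$hyperkinetic),
    transition = if (!is.null(res$transition))
      res$transition[c("auc", "accuracy", "accuracy_ci", "sensitivity",
                       "specificity", "ppv", "npv", "selected")])
  jsonlite::write_json(report, file.path(out_dir, "analysis_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.csv(res$changes, file.path(out_dir, "change_scores.csv"),
                   row.names = FALSE)
  invisible(res)
}

model_report <- function(branch) {
  sw <- branch$stepwise
  out <- list(selected = sw$selected,
              coefficients = as.list(sw$coefficients),
              final_aic = sw$final_aic, r2 = sw$r2, adj_r2 = sw$adj_r2)
  if (!is.null(branch$importance))
    out$importance <- as.list(branch$importance$shares)
  if (!is.null(branch$loocv))
    out[c("loocv_mae", "loocv_rmse", "loocv_r2_pred")] <-
      branch$loocv[c("mae", "rmse", "r2_pred")]
  if (!is.null(branch$compound_cor)) out$compound_cor <- branch$compound_cor
  out
}
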