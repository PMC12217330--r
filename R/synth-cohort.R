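# Feature-level synthetic OFF/ON cohorts with a latent dopaminergic-response
# structure. A single latent response D_i scales each planted biomarker
# change; the clinical outcomes load on the realized per-feature changes, so
# every planted feature carries its own pathway into the outcome (see the
# methods vignette for the calibration).

#' Reference distributions for the 16 biomarkers
#'
#' Healthy-control mean/sd in natural units and the OFF-state shift in HC sd
#' units (the direction of the untreated impairment); used by the cohort
#' generator for baselines and change scaling.
#' @return A tibble with columns `feature`, `hc_mean`, `hc_sd`, `off_shift`.
#' @export
feature_reference <- function() {
  tibble::tribble(
    ~feature,         ~hc_mean, ~hc_sd, ~off_shift,
    "sdF0_text",          3.4,    0.8,   -1.2,
    "Int_sd_text",        8.0,    1.5,   -1.0,
    "Int_kurt_text",      3.5,    0.8,    0.8,
    "Int_skew_text",     -0.4,    0.3,    0.5,
    "NSR_text",           4.8,    0.6,   -0.9,
    "DPI_text",         180.0,   40.0,    1.1,
    "RST_text",          40.0,    8.0,   -0.8,
    "VOT_ddk",           22.0,    5.0,    0.9,
    "HNR_phon",          18.0,    3.0,   -1.0,
    "MPT_phon",          18.0,    5.0,   -0.7,
    "Int_slope_phon",    -1.0,    0.5,   -1.0,
    "Int_sd_phon",        1.2,    0.4,    0.6,
    "LTAS_mean",        580.0,   90.0,   -0.8,
    "LTAS_sd",          680.0,   80.0,    0.3,
    "LTAS_skew",          2.6,    0.5,    0.6,
    "LTAS_kurt",         10.0,    3.0,    0.5
  )
}

#' Default planted hypokinetic loadings
#'
#' The eight biomarkers whose changes track the latent dopaminergic response
#' in the default synthetic cohort (prosody, timing, spectral, and
#' articulation features), with their change directions.
#' @return Named numeric vector of loadings.
#' @export
default_hypo_loadings <- function() {
  c(sdF0_text = 1, Int_kurt_text = -1, RST_text = 1, LTAS_skew = -1,
    Int_sd_text = 1, NSR_text = -1, LTAS_mean = -1, VOT_ddk = 1)
}

#' Default planted hyperkinetic loadings
#'
#' The six biomarkers whose changes track dyskinesia severity in the default
#' synthetic cohort (two shared with the hypokinetic set).
#' @return Named numeric vector of loadings.
#' @export
default_hyper_loadings <- function() {
  c(MPT_phon = 1, Int_sd_text = 1, Int_sd_phon = -1, LTAS_sd = 1,
    LTAS_skew = -1, LTAS_kurt = -1)
}

#' Specification of a synthetic paired OFF/ON cohort
#'
#' Defaults emulate the study conditions this analysis assumes: 51 PD
#' patients with moderate-to-severe motor fluctuations and 43 healthy
#' controls; 8 planted hypokinetic and 6 planted hyperkinetic feature
#' loadings (two shared); feature noise and outcome noise calibrated so the
#' hypokinetic stepwise model reaches an in-sample R-squared near 0.6.
#'
#' @param n_pd,n_hc Cohort sizes (PD pairs, healthy controls).
#' @param planted_hypo_features,planted_hyper_features Named loading vectors
#'   (names must be canonical biomarker names); loading sign is the direction
#'   of the feature change per unit latent response.
#' @param noise_sd Per-feature change noise, in latent units (scalar or named
#'   per-feature vector).
#' @param outcome_noise_sd Noise sd of the hypokinetic outcome change
#'   (MDS-UPDRS-III without tremor items), scale points.
#' @param hyper_outcome_noise_sd Noise sd of the hyperkinetic outcome change
#'   (Marconi axial subscore), scale points.
#' @param effect_scale Multiplier on the latent dopaminergic response;
#'   `0` produces a null cohort.
#' @param hypo_gain,hyper_gain Outcome points per latent unit of planted
#'   feature change.
#' @param hypo_intercept,hyper_intercept Feature-independent outcome change.
#' @param seed Integer seed; fixed seed reproduces the cohort exactly.
#' @return An object of class `cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_pd = 51, n_hc = 43,
                                  planted_hypo_features = default_hypo_loadings(),
                                  planted_hyper_features = default_hyper_loadings(),
                                  noise_sd = 2.5,
                                  outcome_noise_sd = 7.2,
                                  hyper_outcome_noise_sd = 2.2,
                                  effect_scale = 1,
                                  hypo_gain = 1, hyper_gain = 0.22,
                                  hypo_intercept = -12, hyper_intercept = 6.7,
                                  seed = NULL) {
  feats <- canonical_features()
  check_map <- function(m, nm) {
    if (!length(m)) return(invisible())
    if (is.null(names(m)) || !all(names(m) %in% feats))
      stop("`", nm, "` names must be canonical biomarker names", call. = FALSE)
    if (anyNA(m) || any(!is.finite(m)))
      stop("`", nm, "` loadings must be finite", call. = FALSE)
  }
  check_map(planted_hypo_features, "planted_hypo_features")
  check_map(planted_hyper_features, "planted_hyper_features")
  if (n_pd < 3) stop("`n_pd` must be >= 3", call. = FALSE)
  if (length(noise_sd) > 1 && is.null(names(noise_sd)))
    stop("per-feature `noise_sd` must be named", call. = FALSE)
  structure(list(n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
                 planted_hypo_features = planted_hypo_features,
                 planted_hyper_features = planted_hyper_features,
                 noise_sd = noise_sd, outcome_noise_sd = outcome_noise_sd,
                 hyper_outcome_noise_sd = hyper_outcome_noise_sd,
                 effect_scale = effect_scale,
                 hypo_gain = hypo_gain, hyper_gain = hyper_gain,
                 hypo_intercept = hypo_intercept,
                 hyper_intercept = hyper_intercept, seed = seed),
            class = "cohort_spec")
}

# MDS-UPDRS-III item layout with laterality collapsed by sum. The no-tremor
# total (excluding items 3.15-3.18) has maximum 92; tremor items add 40.
updrs3_items <- function() {
  tibble::tibble(
    item = sprintf("updrs3_%02d", 1:18),
    max = c(4, 4, 20, 8, 8, 8, 8, 8, 4, 4, 4, 4, 4, 4, 8, 8, 20, 4),
    group = c("axial", "axial", "rigidity", rep("bradykinesia", 5),
              rep("axial", 6), rep("tremor", 4)))
}

# Distribute an integer subscore across its items under per-item caps.
allocate_items <- function(total, caps) {
  x <- integer(length(caps))
  total <- min(total, sum(caps))
  while (total > 0L) {
    open <- which(x < caps)
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    x[pick] <- x[pick] + 1L
    total <- total - 1L
  }
  x
}

trunc_norm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic paired OFF/ON cohort
#'
#' Per PD subject a latent dopaminergic response `D ~ N(1, 0.3)` truncated at
#' zero scales the planted feature changes
#' `eta_k = loading_k * effect_scale * D + N(0, noise_sd_k)`; the hypokinetic
#' outcome change (MDS-UPDRS-III without tremor) loads negatively and the
#' hyperkinetic outcome change (Marconi axial) positively on the realized
#' planted changes. OFF baselines are drawn from HC-referenced
#' distributions; ON equals OFF plus the change; clinical scores are
#' integerized at item level and bounded by the scale ranges ([-92, 0]-style
#' bounds arise from the item caps).
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return A `paired_cohort`: list with `features` (tibble: subject, state,
#'   16 biomarker columns), `clinical` (tibble: item-level MDS-UPDRS-III,
#'   totals, Marconi axial, demographics), `hc` (tibble of control rows), and
#'   `truth` (generator state: latent responses, loadings, latent changes).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_truth_seed(spec$seed, gen_cohort_impl(spec))
}

gen_cohort_impl <- function(spec) {
  feats <- canonical_features()
  ref <- feature_reference()
  n <- spec$n_pd
  noise <- if (length(spec$noise_sd) == 1L)
    setNames(rep(spec$noise_sd, 16L), feats) else {
      ns <- setNames(rep(2.5, 16L), feats)
      ns[names(spec$noise_sd)] <- spec$noise_sd
      ns
    }
  load_all <- setNames(rep(0, 16L), feats)
  load_all[names(spec$planted_hyper_features)] <- spec$planted_hyper_features
  load_all[names(spec$planted_hypo_features)] <- spec$planted_hypo_features

  D <- trunc_norm_pos(n, 1, 0.3)
  # latent changes eta (n x 16, latent units) and feature-unit changes
  eta <- sapply(feats, function(k)
    load_all[k] * spec$effect_scale * D + rnorm(n, 0, noise[k]))
  delta_scale <- setNames(0.2 * ref$hc_sd, ref$feature)
  delta <- sweep(eta, 2, delta_scale[feats], "*")

  # outcomes load on the realized planted latent changes
  hypo_sig <- as.numeric(eta[, names(spec$planted_hypo_features), drop = FALSE] %*%
                           sign_or_load(spec$planted_hypo_features))
  hyper_sig <- as.numeric(eta[, names(spec$planted_hyper_features), drop = FALSE] %*%
                            sign_or_load(spec$planted_hyper_features))
  # the outcome-feature coupling carries the same effect dial as the feature
  # changes, so effect_scale = 0 severs every link between features and scores
  d_nt <- spec$hypo_intercept -
    spec$hypo_gain * spec$effect_scale * hypo_sig +
    rnorm(n, 0, spec$outcome_noise_sd)
  d_marconi <- spec$hyper_intercept +
    spec$hyper_gain * spec$effect_scale * hyper_sig +
    rnorm(n, 0, spec$hyper_outcome_noise_sd)

  # OFF feature baselines referenced to HC distributions, with a mild common
  # age trend so covariate adjustment has something to do
  age_pd <- rnorm(n, 63.3, 7.9)
  age_hc <- rnorm(spec$n_hc, 66.7, 8.5)
  off <- sapply(seq_len(16L), function(j)
    ref$hc_mean[j] + ref$off_shift[j] * ref$hc_sd[j] +
      rnorm(n, 0, ref$hc_sd[j]) - 0.015 * ref$hc_sd[j] * (age_pd - 65))
  colnames(off) <- ref$feature
  off <- off[, feats, drop = FALSE]
  on <- off + delta

  hc <- sapply(seq_len(16L), function(j)
    ref$hc_mean[j] + rnorm(spec$n_hc, 0, ref$hc_sd[j]) -
      0.015 * ref$hc_sd[j] * (age_hc - 65))
  colnames(hc) <- ref$feature

  subj <- sprintf("PD%02d", seq_len(n))
  features <- tibble::tibble(
    subject = rep(subj, 2L),
    state = rep(c("OFF", "ON"), each = n)) |>
    dplyr::bind_cols(tibble::as_tibble(rbind(off, on)))

  clinical <- gen_clinical(spec, subj, d_nt, d_marconi, age_pd)

  hc_tbl <- tibble::tibble(subject = sprintf("HC%02d", seq_len(spec$n_hc))) |>
    dplyr::bind_cols(tibble::as_tibble(hc[, feats, drop = FALSE])) |>
    dplyr::mutate(age = age_hc,
                  gender = ifelse(runif(spec$n_hc) < 0.79, "m", "f"),
                  moca = pmin(30, round(rnorm(spec$n_hc, 26.7, 2.3))))

  structure(list(features = features, clinical = clinical, hc = hc_tbl,
                 truth = list(D = D, eta = eta, delta = delta,
                              latent_d_nt = d_nt, latent_d_marconi = d_marconi,
                              delta_scale = delta_scale, spec = spec)),
            class = "paired_cohort")
}

sign_or_load <- function(m) as.numeric(m)

# Item-level clinical tables for both states; subscore changes split the
# latent no-tremor change so planted loadings drive bradykinesia and axial
# subscores but not tremor.
gen_clinical <- function(spec, subj, d_nt, d_marconi, age_pd) {
  n <- length(subj)
  items <- updrs3_items()
  nt_items <- items[items$group != "tremor", ]
  tr_items <- items[items$group == "tremor", ]

  # OFF severity tracks response magnitude (stronger responders start
  # higher), which keeps ON-state scores off the scale floor
  off_nt <- pmin(pmax(round(26 - 0.6 * d_nt + rnorm(n, 0, 6)), 5), 85)
  brady_off <- pmin(pmax(round(0.45 * off_nt + rnorm(n, 0, 2)), 0), 40)
  rigid_off <- pmin(pmax(round(0.20 * off_nt + rnorm(n, 0, 1.5)), 0), 20)
  axial_off <- pmin(pmax(off_nt - brady_off - rigid_off, 0), 32)
  tremor_off <- pmin(pmax(round(rnorm(n, 8, 4)), 0), 40)

  nu_b <- rnorm(n, 0, 1.5); nu_a <- rnorm(n, 0, 1.5)
  d_brady <- 0.50 * d_nt + nu_b
  d_axial <- 0.35 * d_nt + nu_a
  d_rigid <- d_nt - d_brady - d_axial
  d_tremor <- rnorm(n, -4, 2)

  brady_on <- pmin(pmax(round(brady_off + d_brady), 0), 40)
  rigid_on <- pmin(pmax(round(rigid_off + d_rigid), 0), 20)
  axial_on <- pmin(pmax(round(axial_off + d_axial), 0), 32)
  tremor_on <- pmin(pmax(round(tremor_off + d_tremor), 0), 40)

  marconi_off <- ifelse(runif(n) < 0.9, 0L, sample(1:3, n, replace = TRUE))
  marconi_on <- pmin(pmax(marconi_off + round(d_marconi), 0), 12)

  sub_caps <- split(items$max, items$group)
  sub_items <- split(items$item, items$group)
  build_items <- function(brady, rigid, axial, tremor) {
    m <- matrix(0L, length(brady), 18L,
                dimnames = list(NULL, items$item))
    for (i in seq_along(brady)) {
      m[i, sub_items$bradykinesia] <-
        allocate_items(brady[i], sub_caps$bradykinesia)
      m[i, sub_items$rigidity] <- allocate_items(rigid[i], sub_caps$rigidity)
      m[i, sub_items$axial] <- allocate_items(axial[i], sub_caps$axial)
      m[i, sub_items$tremor] <- allocate_items(tremor[i], sub_caps$tremor)
    }
    m
  }
  it_off <- build_items(brady_off, rigid_off, axial_off, tremor_off)
  it_on <- build_items(brady_on, rigid_on, axial_on, tremor_on)

  gender <- ifelse(runif(n) < 0.80, "m", "f")
  language <- sample(c("de", "fr", "it", "en"), n, replace = TRUE,
                     prob = c(0.67, 0.21, 0.10, 0.02))
  moca <- pmin(30, round(rnorm(n, 25.9, 3.7)))
  dis_dur <- pmax(1, round(rnorm(n, 11, 4)))
  per_state <- function(state, it, marconi) {
    tibble::tibble(subject = subj, state = state) |>
      dplyr::bind_cols(tibble::as_tibble(it)) |>
      dplyr::mutate(marconi_axial = as.integer(marconi),
                    updrs1 = pmax(0L, round(rnorm(n, 12.6, 5.2))),
                    updrs2 = pmax(0L, round(rnorm(n, 15.6, 6.4))),
                    updrs4 = pmax(0L, round(rnorm(n, 9.7, 4.2))),
                    moca = moca, age = age_pd, gender = gender,
                    language = language, disease_duration = dis_dur)
  }
  dplyr::bind_rows(per_state("OFF", it_off, marconi_off),
                   per_state("ON", it_on, marconi_on))
}

#' MDS-UPDRS-III subscores from item-level columns
#'
#' Sums the conventional item groups: bradykinesia (items 3.4-3.8), rigidity
#' (item 3.3), axial (items 3.1-3.2, 3.9-3.14), tremor (items 3.15-3.18),
#' and the no-tremor total (maximum 92).
#'
#' @param clin Tibble with `updrs3_01` ... `updrs3_18` columns.
#' @return Tibble of subscores aligned with `clin` rows.
#' @export
updrs3_subscores <- function(clin) {
  items <- updrs3_items()
  g <- split(items$item, items$group)
  s <- function(cols) rowSums(as.matrix(clin[, cols, drop = FALSE]))
  tibble::tibble(
    bradykinesia = s(g$bradykinesia), rigidity = s(g$rigidity),
    axial = s(g$axial), tremor = s(g$tremor),
    no_tremor_total = s(c(g$bradykinesia, g$rigidity, g$axial)))
}

#' ON - OFF change scores for a paired cohort
#'
#' @param cohort A `paired_cohort` from [gen_cohort()] (or assembled from
#'   files with the same structure).
#' @return Tibble with one row per subject: the 16 biomarker changes plus
#'   clinical changes `d_updrs3_nt`, `d_bradykinesia`, `d_axial`,
#'   `d_rigidity`, `d_tremor`, `d_marconi_axial`.
#' @export
cohort_changes <- function(cohort) {
  stopifnot(inherits(cohort, "paired_cohort"))
  feats <- canonical_features()
  f <- cohort$features
  off <- f[f$state == "OFF", ]; on <- f[f$state == "ON", ]
  on <- on[match(off$subject, on$subject), ]
  d_feat <- as.matrix(on[, feats]) - as.matrix(off[, feats])
  cl <- cohort$clinical
  cl_off <- cl[cl$state == "OFF", ]; cl_on <- cl[cl$state == "ON", ]
  cl_on <- cl_on[match(cl_off$subject, cl_on$subject), ]
  stopifnot(identical(off$subject, cl_off$subject))
  s_off <- updrs3_subscores(cl_off); s_on <- updrs3_subscores(cl_on)
  tibble::tibble(subject = off$subject) |>
    dplyr::bind_cols(tibble::as_tibble(d_feat)) |>
    dplyr::mutate(
      d_updrs3_nt = s_on$no_tremor_total - s_off$no_tremor_total,
      d_bradykinesia = s_on$bradykinesia - s_off$bradykinesia,
      d_axial = s_on$axial - s_off$axial,
      d_rigidity = s_on$rigidity - s_off$rigidity,
      d_tremor = s_on$tremor - s_off$tremor,
      d_marconi_axial = cl_on$marconi_axial - cl_off$marconi_axial)
}
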