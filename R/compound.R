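# Compound speech scores: selected features, coefficient signs, normalized
# importance weights, and the z-scoring reference captured at build time.

#' Build a compound score definition
#'
#' Combines a stepwise selection with its importance decomposition: each
#' selected feature contributes `sign(coefficient) * weight * z`, where the
#' weights are the importance shares normalized to sum to one and `z` uses
#' the reference mean/sd captured here.
#'
#' @param sw A `stepwise_result`.
#' @param imp An `importance_decomposition` over exactly `sw$selected`.
#' @param ref_stats Data frame with columns `feature`, `mean`, `sd` giving
#'   the z-scoring reference (typically the change-score distribution of the
#'   cohort the model was fit on).
#' @return A `compound_score` definition.
#' @export
build_compound <- function(sw, imp, ref_stats) {
  stopifnot(inherits(sw, "stepwise_result"),
            inherits(imp, "importance_decomposition"))
  if (!setequal(names(imp$shares), sw$selected))
    stop("importance features must match the stepwise selection", call. = FALSE)
  if (!length(sw$selected)) stop("no selected features", call. = FALSE)
  tot <- sum(imp$shares)
  if (tot <= 0) stop("zero total importance", call. = FALSE)
  ref_stats <- as.data.frame(ref_stats)
  if (!all(sw$selected %in% ref_stats$feature))
    stop("reference stats missing for some selected features", call. = FALSE)
  ref <- ref_stats[match(sw$selected, ref_stats$feature), ]
  if (any(ref$sd <= 0)) stop("non-positive reference sd", call. = FALSE)
  structure(list(features = sw$selected,
                 signs = sign(sw$coefficients[sw$selected]),
                 weights = imp$shares[sw$selected] / tot,
                 reference_mean = setNames(ref$mean, sw$selected),
                 reference_sd = setNames(ref$sd, sw$selected)),
            class = "compound_score")
}

#' Apply a compound score to biomarker changes
#'
#' @param def A `compound_score` from [build_compound()].
#' @param changes Data frame/matrix of biomarker changes (columns must cover
#'   `def$features`), or a single named vector.
#' @return Numeric score(s): `sum_k sign_k * weight_k * z_k`.
#' @export
apply_compound <- function(def, changes) {
  stopifnot(inherits(def, "compound_score"))
  if (is.vector(changes) && !is.null(names(changes)))
    changes <- as.data.frame(as.list(changes))
  changes <- as.data.frame(changes)
  miss <- setdiff(def$features, colnames(changes))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
  M <- as.matrix(changes[, def$features, drop = FALSE])
  Z <- sweep(sweep(M, 2, def$reference_mean), 2, def$reference_sd, "/")
  as.numeric(Z %*% (def$signs * def$weights))
}

#' @export
print.compound_score <- function(x, ...) {
  cat("<compound_score>\n")
  print(data.frame(feature = x$features, sign = unname(x$signs),
                   weight = round(unname(x$weights), 4)))
  invisible(x)
}
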