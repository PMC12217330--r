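# Relative importance by ordering-averaged R^2 decomposition: LMG (equal
# weights over orderings) and pmvd (proportional marginal variance
# decomposition; data-dependent weights with the exclusion property for
# zero-coefficient predictors). Both are computed from a memoized R^2
# lattice over all 2^p subsets; pmvd uses a forward/backward dynamic program
# over the lattice instead of enumerating p! orderings.

# R^2 of y on every subset of columns of X, indexed by bitmask + 1.
r2_lattice <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- nrow(X)
  yc <- y - mean(y)
  Xc <- scale(X, scale = FALSE)
  G <- crossprod(Xc) / n
  g <- crossprod(Xc, yc) / n
  syy <- mean(yc^2)
  r2 <- numeric(2^p)
  for (m in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) > 0)
    b <- tryCatch(solve(G[idx, idx, drop = FALSE], g[idx, , drop = FALSE]),
                  error = function(e) NULL)
    r2[m + 1] <- if (is.null(b)) NA_real_ else
      as.numeric(crossprod(g[idx, , drop = FALSE], b)) / syy
  }
  if (anyNA(r2)) stop("singular predictor subset in R^2 lattice", call. = FALSE)
  r2
}

#' R-squared of an OLS fit on a feature subset
#'
#' @param X Matrix/data frame of predictors.
#' @param y Numeric outcome.
#' @param subset Column names (or indices) of the subset; empty gives 0.
#' @return The OLS R-squared.
#' @export
subset_r2 <- function(X, y, subset = colnames(X)) {
  X <- as.data.frame(X)
  if (!length(subset)) return(0)
  if (is.character(subset)) {
    if (!all(subset %in% colnames(X)))
      stop("subset names not in X", call. = FALSE)
    subset <- match(subset, colnames(X))
  }
  Xs <- as.matrix(X[, subset, drop = FALSE])
  summary(lm(y ~ Xs))$r.squared
}

bit_count <- function(m) {
  n <- 0L
  while (m > 0L) { n <- n + bitwAnd(m, 1L); m <- bitwShiftR(m, 1L) }
  n
}

#' Ordering-averaged relative importance (pmvd / LMG)
#'
#' Decomposes the full-model R-squared into non-negative per-feature shares.
#' `lmg` averages each feature's sequential R-squared increment uniformly
#' over all p! entry orderings. `pmvd` weights orderings proportionally to
#' `prod_i 1 / (R2_full - R2(first i features))` (Feldman's proportional
#' marginal variance decomposition), which sends the share of a
#' zero-coefficient predictor to zero (the exclusion property). Degenerate
#' zero gaps are regularized at 1e-12.
#'
#' Exact computation enumerates the 2^p subset lattice and requires
#' `p <= exact_max`; above that, supply `n_orderings` to average over
#' seeded sampled orderings instead.
#'
#' @param X Matrix/data frame of predictors.
#' @param y Numeric outcome.
#' @param features Columns to decompose (default all).
#' @param method `"pmvd"` or `"lmg"`.
#' @param exact_max Largest p for exact lattice computation.
#' @param n_orderings Number of sampled orderings for p > exact_max.
#' @param seed Seed for the sampling mode.
#' @return An `importance_decomposition`: list with `shares` (named,
#'   non-negative, summing to `total`), `total` (full-model R-squared), and
#'   `method`.
#' @export
importance <- function(X, y, features = colnames(as.data.frame(X)),
                       method = c("pmvd", "lmg"), exact_max = 12,
                       n_orderings = NULL, seed = NULL) {
  method <- match.arg(method)
  X <- as.data.frame(X)[, features, drop = FALSE]
  p <- ncol(X)
  if (p == 0) stop("no features to decompose", call. = FALSE)
  if (p > exact_max && is.null(n_orderings))
    stop("p > ", exact_max, " features: exact enumeration disabled; ",
         "set `n_orderings` to sample orderings (with `seed`)", call. = FALSE)
  if (p > exact_max) {
    return(with_truth_seed(seed,
      importance_sampled(as.matrix(X), y, method, n_orderings)))
  }
  r2 <- r2_lattice(X, y)
  full <- r2[2^p]
  shares <- if (method == "lmg") lmg_lattice(r2, p) else pmvd_lattice(r2, p)
  names(shares) <- colnames(X)
  structure(list(shares = pmax(shares, 0), total = full, method = method),
            class = "importance_decomposition")
}

lmg_lattice <- function(r2, p) {
  sizes <- vapply(0:(2^p - 1), bit_count, integer(1))
  wts <- factorial(0:(p - 1)) * factorial(p - 1 - (0:(p - 1))) / factorial(p)
  shares <- numeric(p)
  for (k in seq_len(p)) {
    bit <- bitwShiftL(1L, k - 1L)
    S <- which(bitwAnd(0:(2^p - 1), bit) == 0L) - 1L
    inc <- r2[S + bit + 1L] - r2[S + 1L]
    shares[k] <- sum(wts[sizes[S + 1L] + 1L] * inc)
  }
  shares
}

pmvd_lattice <- function(r2, p, eps = 1e-12) {
  full <- r2[2^p]
  nsub <- 2^p
  # per-subset ordering-weight factor: 1 / (R2_full - R2(S)) for proper,
  # non-empty prefixes S
  f <- rep(1, nsub)
  mid <- 2:(nsub - 1)
  f[mid] <- 1 / pmax(full - r2[mid], eps)
  sizes <- vapply(0:(nsub - 1), bit_count, integer(1))
  ord_sets <- split(0:(nsub - 1), sizes)
  # backward mass B(S): weighted count of orderings of S arriving at S
  B <- numeric(nsub); B[1] <- 1
  for (s in 1:p) {
    for (m in ord_sets[[s + 1L]]) {
      bits <- bitwAnd(m, bitwShiftL(1L, 0:(p - 1)))
      inset <- which(bits > 0)
      tot <- sum(B[m - bits[inset] + 1L])
      B[m + 1L] <- if (s < p) tot * f[m + 1L] else tot
    }
  }
  # forward mass T(S): weighted completions from S to the full set
  Tm <- numeric(nsub); Tm[nsub] <- 1
  for (s in (p - 1):0) {
    for (m in ord_sets[[s + 1L]]) {
      out <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) == 0)
      nxt <- m + bitwShiftL(1L, out - 1L)
      Tm[m + 1L] <- sum(ifelse(nxt + 1L < nsub, f[nxt + 1L], 1) * Tm[nxt + 1L])
    }
  }
  W <- B[nsub]
  shares <- numeric(p)
  for (k in seq_len(p)) {
    bit <- bitwShiftL(1L, k - 1L)
    S <- which(bitwAnd(0:(nsub - 1), bit) == 0L) - 1L
    nxt <- S + bit
    fac <- ifelse(nxt + 1L < nsub, f[nxt + 1L], 1)
    inc <- r2[nxt + 1L] - r2[S + 1L]
    shares[k] <- sum(B[S + 1L] * fac * Tm[nxt + 1L] * inc) / W
  }
  shares
}

importance_sampled <- function(X, y, method, n_orderings) {
  p <- ncol(X)
  full <- subset_r2(X, y)
  incs <- matrix(0, n_orderings, p)
  wts <- numeric(n_orderings)
  for (i in seq_len(n_orderings)) {
    ord <- sample.int(p)
    r2s <- numeric(p)
    for (j in seq_len(p)) r2s[j] <- subset_r2(X, y, ord[seq_len(j)])
    inc <- diff(c(0, r2s))
    incs[i, ord] <- inc
    wts[i] <- if (method == "pmvd")
      prod(1 / pmax(full - r2s[seq_len(p - 1)], 1e-12)) else 1
  }
  shares <- colSums(incs * wts) / sum(wts)
  names(shares) <- colnames(X)
  structure(list(shares = pmax(shares, 0), total = full, method = method),
            class = "importance_decomposition")
}

#' @export
print.importance_decomposition <- function(x, ...) {
  cat(sprintf("<importance_decomposition> method=%s  total R2=%.4f\n",
              x$method, x$total))
  print(round(sort(x$shares, decreasing = TRUE), 4))
  invisible(x)
}
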