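# Front-end for paired omics tables: modified centered log-ratio transform
# for compositional counts, per-group standardization, cross-correlations
# with their asymptotic variances, and the two-group differential
# cross-correlation z statistic.

#' Modified centered log-ratio transform
#'
#' Applies the clr transform per sample over the positive entries only
#' (`t_k = log y_k - mean(log y)` over positive `y`), then shifts every
#' positive result by `|min t| + eps`, where the minimum is taken over the
#' whole block, so that transformed positives are strictly positive while
#' zeros remain exactly zero. Using a single global shift preserves the
#' ordering of values across samples.
#'
#' @param counts Non-negative samples x features matrix (rows are
#'   samples).
#' @param eps Positive offset added to the shift (default 1).
#' @return Matrix of the same shape; zero entries stay zero.
#' @export
#' @examples
#' mclr(rbind(s1 = c(1, exp(1), exp(2), 0)))  # (1, 2, 3, 0) with eps = 1
mclr <- function(counts, eps = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("mclr requires non-negative counts")
  pos <- counts > 0
  empty <- rowSums(pos) == 0
  if (any(empty)) {
    ids <- rownames(counts)
    bad <- if (is.null(ids)) which(empty)[1] else ids[which(empty)[1]]
    stop(sprintf("sample '%s' has no positive entries", bad))
  }
  lg <- log(counts)
  lg[!pos] <- NA
  tmat <- lg - rowMeans(lg, na.rm = TRUE)
  shift <- abs(min(tmat, na.rm = TRUE)) + eps
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  out[pos] <- tmat[pos] + shift
  out
}

#' Center and scale feature columns
#'
#' Standardizes each column to mean zero and variance one, with the
#' variance computed with denominator `m` (the sample size) so that the
#' squared entries of each column sum to `m`. This convention makes the
#' plug-in cross-correlation `m^-1 sum Y1 Y2` a true correlation in
#' `[-1, 1]`.
#'
#' @param Y Samples x features matrix.
#' @return Standardized matrix of the same shape.
#' @export
standardize <- function(Y) {
  Y <- as.matrix(Y)
  m <- nrow(Y)
  if (m < 2) stop("standardization needs at least 2 samples")
  Yc <- sweep(Y, 2, colMeans(Y))
  v <- colMeans(Yc^2)
  if (any(v <= 0)) {
    ids <- colnames(Y)
    bad <- if (is.null(ids)) which(v <= 0)[1] else ids[which(v <= 0)[1]]
    stop(sprintf("feature '%s' is constant and cannot be standardized", bad))
  }
  sweep(Yc, 2, sqrt(v), "/")
}

.check_paired <- function(Y1t, Y2t) {
  if (nrow(Y1t) != nrow(Y2t)) stop("the two blocks have different sample sizes")
  r1 <- rownames(Y1t)
  r2 <- rownames(Y2t)
  if (!is.null(r1) && !is.null(r2) && !identical(r1, r2)) {
    stop("sample identifiers of the two blocks do not match")
  }
}

#' Cross-correlation between two standardized blocks
#'
#' `rho[i, j] = m^-1 sum_k Y1t[k, i] Y2t[k, j]` for blocks standardized
#' with [standardize()] (denominator `m`), so every entry lies in
#' `[-1, 1]`.
#'
#' @param Y1t,Y2t Standardized samples x features matrices with matching
#'   rows.
#' @return `ncol(Y1t) x ncol(Y2t)` correlation matrix.
#' @export
cross_corr <- function(Y1t, Y2t) {
  Y1t <- as.matrix(Y1t)
  Y2t <- as.matrix(Y2t)
  .check_paired(Y1t, Y2t)
  crossprod(Y1t, Y2t) / nrow(Y1t)
}

#' Asymptotic variance of the cross-correlations
#'
#' Influence-function (delta-method) variance of each empirical
#' correlation. The default `"squared"` form uses the influence terms
#' `2 Y1 Y2 - rho Y1^2 - rho Y2^2`, which vanish at perfect correlation as
#' a variance must. The `"as_printed"` form uses unsquared centring terms
#' `2 Y1 Y2 - rho Y1 - rho Y2`; it is provided for fidelity with the
#' formula as sometimes displayed, but it does not vanish at perfect
#' correlation and the squared form is recommended.
#'
#' @inheritParams cross_corr
#' @param rho_hat Optional precomputed [cross_corr()] matrix.
#' @param form `"squared"` (default) or `"as_printed"`.
#' @return Matrix `s` of non-negative variances, `ncol(Y1t) x ncol(Y2t)`.
#' @export
corr_variance <- function(Y1t, Y2t, rho_hat = NULL,
                          form = c("squared", "as_printed")) {
  form <- match.arg(form)
  Y1t <- as.matrix(Y1t)
  Y2t <- as.matrix(Y2t)
  .check_paired(Y1t, Y2t)
  if (is.null(rho_hat)) rho_hat <- cross_corr(Y1t, Y2t)
  m <- nrow(Y1t)
  n1 <- ncol(Y1t)
  n2 <- ncol(Y2t)
  s <- matrix(NA_real_, n1, n2, dimnames = dimnames(rho_hat))
  Y1sq <- Y1t^2
  for (j in seq_len(n2)) {
    b <- Y2t[, j]
    centre <- if (form == "squared") Y1sq + b^2 else Y1t + b
    infl <- 2 * Y1t * b - sweep(centre, 2, rho_hat[, j], "*")
    s[, j] <- colMeans(infl^2)
  }
  s
}

#' Differential cross-correlation z-scores between two groups
#'
#' Standardizes each block within each group, computes the within-group
#' cross-correlations and their asymptotic variances, and forms the
#' two-group statistic
#' `x_ij = 2 (rho1_ij - rho2_ij) / sqrt(s1_ij / m1 + s2_ij / m2)`, which is
#' approximately standard normal under the no-difference null. The group
#' order follows the factor levels of `groups`. Entries where both the
#' numerator and denominator vanish (identical degenerate correlations)
#' are set to 0.
#'
#' @param Y1,Y2 Samples x features matrices with matched rows (e.g. taxa
#'   and metabolites).
#' @param groups Two-level factor (or vector) of length `nrow(Y1)`; each
#'   group needs at least 3 samples.
#' @param form Variance form passed to [corr_variance()].
#' @return A [score_matrix()] with `ncol(Y1)` rows and `ncol(Y2)` columns.
#' @export
differential_z <- function(Y1, Y2, groups, form = c("squared", "as_printed")) {
  form <- match.arg(form)
  Y1 <- as.matrix(Y1)
  Y2 <- as.matrix(Y2)
  .check_paired(Y1, Y2)
  groups <- as.factor(groups)
  if (length(groups) != nrow(Y1)) {
    stop("groups must have one label per sample")
  }
  if (nlevels(droplevels(groups)) != 2L) {
    stop("exactly two group labels are required")
  }
  groups <- droplevels(groups)
  rho <- s <- vector("list", 2)
  msize <- integer(2)
  for (d in 1:2) {
    idx <- which(groups == levels(groups)[d])
    msize[d] <- length(idx)
    if (msize[d] < 3L) {
      stop(sprintf("group '%s' has fewer than 3 samples",
                   levels(groups)[d]))
    }
    Y1d <- standardize(Y1[idx, , drop = FALSE])
    Y2d <- standardize(Y2[idx, , drop = FALSE])
    rho[[d]] <- cross_corr(Y1d, Y2d)
    s[[d]] <- corr_variance(Y1d, Y2d, rho[[d]], form = form)
  }
  num <- 2 * (rho[[1]] - rho[[2]])
  den <- sqrt(s[[1]] / msize[1] + s[[2]] / msize[2])
  x <- ifelse(num == 0, 0, num / den)
  score_matrix(x, row_ids = colnames(Y1), col_ids = colnames(Y2))
}
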