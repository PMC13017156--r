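# From a fitted model to decisions: structured l-value matrix, marginal-FDR
# calibrated thresholding, truth-based error rates, and the classical
# p-value baselines (Benjamini-Hochberg, Storey q-values).

#' Structured l-value matrix of a fit
#'
#' Plugs the hard memberships `Z1_hat`, `Z2_hat` and the fitted parameters
#' into the block l-value formula for every entry of `X`. With a single
#' block per axis this reduces to the entrywise two-group local false
#' discovery rate.
#'
#' @param X A [score_matrix()] or bare matrix.
#' @param fit A [fit_bnsbm()] result for the same matrix.
#' @return An `n1 x n2` matrix of posterior null probabilities in `[0, 1]`.
#' @export
lvalue_matrix <- function(X, fit) {
  X <- .as_score_matrix(X)
  xv <- X$values
  if (length(fit$Z1_hat) != nrow(xv) || length(fit$Z2_hat) != ncol(xv)) {
    stop("fit dimensions do not match the score matrix")
  }
  L <- matrix(NA_real_, nrow(xv), ncol(xv), dimnames = dimnames(xv))
  th <- fit$theta_hat
  for (q in seq_along(th$alpha1)) {
    rows <- which(fit$Z1_hat == q)
    if (!length(rows)) next
    for (l in seq_along(th$alpha2)) {
      cols <- which(fit$Z2_hat == l)
      if (!length(cols)) next
      L[rows, cols] <- ell_value(xv[rows, cols, drop = FALSE], q, l, th)
    }
  }
  L
}

#' Marginal-FDR calibrated l-value threshold
#'
#' Sorts the l-values increasingly and finds the largest `k` whose running
#' mean does not exceed `alpha`; the threshold `tau` is the k-th smallest
#' l-value (or `-Inf` when even the smallest exceeds `alpha`). The running
#' mean of the rejected l-values is the plug-in estimate of the marginal
#' FDR of the rejection set. Ties at `tau` are all rejected.
#'
#' @param lvalues Numeric vector or matrix of l-values.
#' @param alpha Nominal marginal-FDR level in `(0, 1]`.
#' @return A list with `tau`, a logical `reject` vector (column-major order
#'   of the input), and the rejection count `k`.
#' @export
#' @examples
#' mfdr_threshold(c(0.01, 0.02, 0.5), alpha = 0.1)  # rejects two
mfdr_threshold <- function(lvalues, alpha) {
  l <- as.vector(lvalues)
  if (!length(l)) stop("no l-values supplied")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]")
  }
  s <- sort(l)
  cm <- cumsum(s) / seq_along(s)
  if (!any(cm <= alpha)) {
    return(list(tau = -Inf, reject = rep(FALSE, length(l)), k = 0L))
  }
  tau <- s[max(which(cm <= alpha))]
  reject <- l <= tau
  list(tau = tau, reject = reject, k = sum(reject))
}

#' Decide which hypotheses to reject
#'
#' Computes the structured l-value matrix of the fit and thresholds it at
#' the marginal-FDR calibrated cutoff for level `alpha`.
#'
#' @inheritParams lvalue_matrix
#' @param alpha Nominal marginal-FDR level in `(0, 1]`.
#' @return An object of class `bnsbm_decision` with the `lvalues` matrix,
#'   threshold `tau`, binary `reject` matrix, `mfdr_hat` (mean rejected
#'   l-value, 0 when nothing is rejected), `alpha` and `n_rejected`.
#' @export
decide <- function(X, fit, alpha) {
  X <- .as_score_matrix(X)
  L <- lvalue_matrix(X, fit)
  th <- mfdr_threshold(L, alpha)
  reject <- matrix(th$reject, nrow(L), ncol(L), dimnames = dimnames(L))
  mfdr_hat <- if (th$k > 0) mean(L[reject]) else 0
  structure(list(lvalues = L, tau = th$tau, reject = reject,
                 mfdr_hat = mfdr_hat, alpha = alpha,
                 n_rejected = th$k),
            class = "bnsbm_decision")
}

#' @export
print.bnsbm_decision <- function(x, ...) {
  cat(sprintf(
    "bnsbm_decision: %d of %d hypotheses rejected at alpha = %.3g\n",
    x$n_rejected, length(x$lvalues), x$alpha))
  cat(sprintf("  tau = %.4g, estimated mFDR = %.4g\n", x$tau, x$mfdr_hat))
  invisible(x)
}

#' Empirical discovery rates against the latent truth
#'
#' For simulated data with known adjacency `A`: the false discovery
#' proportion `FDP = sum (1 - A) phi / (sum phi v 1)` (the `v 1` guard
#' makes the proportion 0 when nothing is rejected) and the true discovery
#' proportion `TDP = sum A phi / sum A`. The raw counts are returned so a
#' simulation harness can average numerators and denominators separately
#' (as the marginal FDR and TDR definitions require).
#'
#' @param decision A [decide()] result (or any object with a binary
#'   `reject` matrix).
#' @param truth A [latent_truth()] with matching dimensions.
#' @param require_tdp Error when there are no true edges (the TDP is then
#'   undefined); set to `FALSE` to return `NA` instead.
#' @return A list with `fdp`, `tdp`, `n_rejected`, `n_false`,
#'   `n_true_found` and `n_true`.
#' @export
empirical_rates <- function(decision, truth, require_tdp = TRUE) {
  phi <- decision$reject
  A <- truth$A
  if (!all(dim(phi) == dim(A))) stop("decision and truth shapes differ")
  phi <- phi * 1
  R <- sum(phi)
  V <- sum((1 - A) * phi)
  S <- sum(A * phi)
  TT <- sum(A)
  tdp <- if (TT > 0) {
    S / TT
  } else if (require_tdp) {
    stop("no true edges in the latent truth: TDP is undefined")
  } else {
    NA_real_
  }
  list(fdp = V / max(R, 1), tdp = tdp, n_rejected = R, n_false = V,
       n_true_found = S, n_true = TT)
}

#' Two-sided p-values from z-scores
#'
#' @param z Numeric vector or matrix of z-scores.
#' @param sigma0 Null standard deviation.
#' @return `2 (1 - Phi(|z| / sigma0))`, same shape as `z`.
#' @export
z_to_pvalue <- function(z, sigma0 = 1) {
  2 * stats::pnorm(-abs(z) / sigma0)
}

#' Benjamini-Hochberg rejections
#'
#' Classical step-up procedure at level `alpha`, as a baseline for the
#' structured procedure.
#'
#' @param pvalues Numeric vector or matrix of p-values in `[0, 1]`.
#' @param alpha Nominal FDR level.
#' @return Logical vector/matrix of rejections, same shape as the input.
#' @export
bh_reject <- function(pvalues, alpha) {
  p <- as.vector(pvalues)
  if (any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  out <- stats::p.adjust(p, method = "BH") <= alpha
  if (is.matrix(pvalues)) {
    out <- matrix(out, nrow(pvalues), ncol(pvalues),
                  dimnames = dimnames(pvalues))
  }
  out
}

#' Storey q-values
#'
#' Estimates the null proportion as
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) N))` and converts the
#' p-values to q-values by the usual running-minimum construction;
#' rejecting `q <= alpha` targets FDR `alpha`.
#'
#' @param pvalues Numeric vector or matrix of p-values.
#' @param lambda Tuning parameter of the null-proportion estimate, in
#'   `(0, 1)`.
#' @return q-values, same shape as the input, each in `[0, 1]` and
#'   monotone in the p-values.
#' @export
storey_q <- function(pvalues, lambda = 0.5) {
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  p <- as.vector(pvalues)
  if (any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  N <- length(p)
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * N))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(pi0 * N * p[o] / (N:1)))
  out <- numeric(N)
  out[o] <- q
  if (is.matrix(pvalues)) {
    out <- matrix(out, nrow(pvalues), ncol(pvalues),
                  dimnames = dimnames(pvalues))
  }
  out
}
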