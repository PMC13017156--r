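# Choice of the block counts (B1, B2): BIC-style penalty, ICL criterion,
# grid search, and a subsampling stability score.

#' BIC penalty for the ICL criterion
#'
#' `pen(B1, B2) = (B1 - 1) log n1 + (B2 - 1) log n2 +
#'  [d0 + (1 + d1) B1 B2] log(n1 n2)`.
#' The first two terms count the free mixing proportions; the last counts
#' the connectivity parameters (one per block) and the `d0` null plus
#' `d1` alternative density parameters per block.
#'
#' @param B1,B2 Block counts.
#' @param n1,n2 Matrix dimensions.
#' @param d0 Number of estimated null-density parameters (0 when the null
#'   is fixed, 1 for a Gaussian null with estimated variance).
#' @param d1 Number of alternative-density parameters per block (2 for a
#'   Gaussian).
#' @return Scalar penalty, strictly increasing in `B1` and `B2`.
#' @export
bic_penalty <- function(B1, B2, n1, n2, d0, d1) {
  if (B1 < 1 || B2 < 1 || n1 < 1 || n2 < 1 || d0 < 0 || d1 < 1) {
    stop("invalid penalty arguments")
  }
  (B1 - 1) * log(n1) + (B2 - 1) * log(n2) +
    (d0 + (1 + d1) * B1 * B2) * log(n1 * n2)
}

# Entropy of the fitted variational distribution: the membership entropies
# plus the beta-weighted binary entropies of the edge responsibilities.
.q_entropy <- function(xv, theta, state) {
  hmem <- function(beta) {
    pos <- beta > 0
    -sum(beta[pos] * log(beta[pos]))
  }
  bl <- .block_quantities(xv, theta)
  B1 <- length(theta$alpha1)
  B2 <- length(theta$alpha2)
  hb <- 0
  for (q in seq_len(B1)) {
    for (l in seq_len(B2)) {
      R <- bl$R[[(q - 1L) * B2 + l]]
      Hmat <- -(ifelse(R > 0, R * log(R), 0) +
                  ifelse(R < 1, (1 - R) * log1p(-R), 0))
      hb <- hb + drop(crossprod(state$beta1[, q], Hmat %*% state$beta2[, l]))
    }
  }
  hmem(state$beta1) + hmem(state$beta2) + hb
}

#' Integrated classification likelihood of a fit
#'
#' `ICL = E_Q[log complete-data likelihood] - pen`, computed as
#' `ELBO - H(Q) - pen`: the ELBO equals the expected complete-data
#' log-likelihood plus the entropy of the variational distribution, so
#' subtracting the entropy (membership entropies plus the beta-weighted
#' binary entropies of the edge responsibilities) recovers the expected
#' complete-data term. The entropy favours compact, well-separated
#' clusters. For a degenerate fit (one-hot memberships, responsibilities
#' in {0, 1}) the entropy vanishes and the ICL equals the complete-data
#' log-likelihood minus the penalty.
#'
#' @param X A [score_matrix()] or bare matrix.
#' @param fit A [fit_bnsbm()] result.
#' @param d0,d1 Density parameter counts for the penalty; by default `d0`
#'   follows the fit's `fix_null` flag and `d1 = 2` (Gaussian).
#' @return Scalar ICL value; always `<= ELBO - pen`.
#' @export
icl <- function(X, fit, d0 = if (fit$opts$fix_null) 0 else 1, d1 = 2) {
  X <- .as_score_matrix(X)
  xv <- X$values
  th <- fit$theta_hat
  el <- elbo(X, th, fit$state)
  H <- .q_entropy(xv, th, fit$state)
  el - H - bic_penalty(length(th$alpha1), length(th$alpha2),
                       nrow(xv), ncol(xv), d0, d1)
}

#' Select the number of blocks by ICL
#'
#' Fits the model for every pair in `B1_range x B2_range` (each with the
#' restart policy in `opts`) and returns the pair with the largest ICL.
#' Ties are broken toward the smaller `B1 + B2`, then the smaller `B1`.
#' Cells whose fit fails are marked failed and excluded; the best pair is
#' chosen among the successes.
#'
#' @param X A [score_matrix()] or bare matrix.
#' @param B1_range,B2_range Integer vectors of candidate block counts
#'   (default `1:5`, wide enough for typical association matrices).
#' @param opts A [fit_options()]; its `B1`/`B2` are overridden cell by
#'   cell.
#' @param keep_fits Keep every fitted model (memory permitting) instead of
#'   only the best one.
#' @return An object of class `bnsbm_selection`: a `grid` data frame with
#'   columns `B1`, `B2`, `icl`, `elbo`, `converged`, `failed`, the `best`
#'   pair, the corresponding `best_fit`, and optionally `fits`.
#' @export
#' @examples
#' sim <- sample_noisysbm(40, 50, scenario_a_params(), seed = 1)
#' sel <- select_model(sim$X, 2:3, 2:3,
#'                     fit_options(1, 1, n_restarts = 2, seed = 1))
#' sel$best
select_model <- function(X, B1_range = 1:5, B2_range = 1:5,
                         opts = fit_options(1, 1), keep_fits = FALSE) {
  X <- .as_score_matrix(X)
  if (!length(B1_range) || !length(B2_range)) {
    stop("block-count ranges must be non-empty")
  }
  grid <- expand.grid(B1 = as.integer(sort(B1_range)),
                      B2 = as.integer(sort(B2_range)))
  grid$icl <- NA_real_
  grid$elbo <- NA_real_
  grid$converged <- NA
  grid$failed <- FALSE
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    o <- opts
    o$B1 <- grid$B1[i]
    o$B2 <- grid$B2[i]
    fit <- tryCatch(fit_bnsbm(X, o, warn = FALSE), error = function(e) e)
    if (inherits(fit, "error")) {
      grid$failed[i] <- TRUE
      next
    }
    fit$icl <- icl(X, fit)
    grid$icl[i] <- fit$icl
    grid$elbo[i] <- utils::tail(fit$elbo_trace, 1)
    grid$converged[i] <- fit$converged
    if (keep_fits) fits[[i]] <- fit else fits[[i]] <- NULL
    if (!keep_fits) {
      # retain only the incumbent best fit
      ok <- !grid$failed & !is.na(grid$icl)
      if (which.max(replace(grid$icl, !ok, -Inf)) == i) fits[[i]] <- fit
    }
  }
  ok <- which(!grid$failed)
  if (!length(ok)) stop("every cell of the selection grid failed to fit")
  ord <- ok[order(-grid$icl[ok], grid$B1[ok] + grid$B2[ok], grid$B1[ok])]
  best_i <- ord[1]
  best_fit <- fits[[best_i]]
  if (is.null(best_fit)) {
    o <- opts
    o$B1 <- grid$B1[best_i]
    o$B2 <- grid$B2[best_i]
    best_fit <- fit_bnsbm(X, o, warn = FALSE)
    best_fit$icl <- icl(X, best_fit)
  }
  structure(list(grid = grid,
                 best = c(B1 = grid$B1[best_i], B2 = grid$B2[best_i]),
                 best_fit = best_fit,
                 fits = if (keep_fits) fits else NULL),
            class = "bnsbm_selection")
}

#' @export
print.bnsbm_selection <- function(x, ...) {
  cat(sprintf("bnsbm_selection: best (B1, B2) = (%d, %d)\n",
              x$best[["B1"]], x$best[["B2"]]))
  print(x$grid[order(-x$grid$icl), c("B1", "B2", "icl", "converged")],
        row.names = FALSE)
  invisible(x)
}

# Adjusted Rand index that treats two single-cluster labellings as in
# perfect agreement (mclust returns NaN there).
.ari <- function(a, b) {
  if (length(unique(a)) == 1L && length(unique(b)) == 1L) return(1)
  mclust::adjustedRandIndex(a, b)
}

#' Subsampling stability of a biclustering
#'
#' A simple reproducibility score: fit the model on `n_subsamples` random
#' row/column subsamples (a fraction `frac` of each axis), then average the
#' pairwise adjusted Rand indices of the row clusterings and of the column
#' clusterings restricted to shared features. An axis with a single block
#' scores 1 by convention. Pairs in which a fit collapses to a single
#' cluster on an axis with more than one block are skipped; the number of
#' skipped pairs is attached as attribute `"n_skipped"`.
#'
#' This score is a pragmatic stand-in for more elaborate cluster-stability
#' procedures; it is meant for relative comparisons across `(B1, B2)`
#' pairs on the same data.
#'
#' @param X A [score_matrix()] or bare matrix.
#' @param B1,B2 Block counts to assess.
#' @param n_subsamples Number of subsample fits.
#' @param frac Fraction of rows and columns retained (in `(0.5, 1)`).
#' @param opts A [fit_options()] template for the subsample fits.
#' @return Mean pairwise adjusted Rand index in `[-1, 1]`.
#' @export
stability_score <- function(X, B1, B2, n_subsamples = 20, frac = 0.8,
                            opts = fit_options(B1, B2, n_restarts = 2)) {
  X <- .as_score_matrix(X)
  if (frac <= 0.5 || frac >= 1) stop("frac must lie in (0.5, 1)")
  xv <- X$values
  n1 <- nrow(xv)
  n2 <- ncol(xv)
  rows <- cols <- vector("list", n_subsamples)
  for (s in seq_len(n_subsamples)) {
    set.seed(opts$seed + 7654L * s)
    ri <- sort(sample.int(n1, floor(frac * n1)))
    ci <- sort(sample.int(n2, floor(frac * n2)))
    o <- opts
    o$B1 <- as.integer(B1)
    o$B2 <- as.integer(B2)
    o$seed <- opts$seed + s
    fit <- tryCatch(fit_bnsbm(xv[ri, ci, drop = FALSE], o, warn = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) next
    z1 <- fit$Z1_hat
    names(z1) <- as.character(ri)
    z2 <- fit$Z2_hat
    names(z2) <- as.character(ci)
    rows[[s]] <- z1
    cols[[s]] <- z2
  }
  pair_scores <- numeric(0)
  n_skipped <- 0L
  axis_score <- function(za, zb, B) {
    if (B == 1L) return(1)
    shared <- intersect(names(za), names(zb))
    a <- za[shared]
    b <- zb[shared]
    if (length(unique(a)) == 1L || length(unique(b)) == 1L) return(NA_real_)
    .ari(a, b)
  }
  done <- which(!vapply(rows, is.null, logical(1)))
  for (a in done) {
    for (b in done[done > a]) {
      sr <- axis_score(rows[[a]], rows[[b]], as.integer(B1))
      sc <- axis_score(cols[[a]], cols[[b]], as.integer(B2))
      if (is.na(sr) || is.na(sc)) {
        n_skipped <- n_skipped + 1L
        next
      }
      pair_scores <- c(pair_scores, (sr + sc) / 2)
    }
  }
  if (!length(pair_scores)) {
    stop("no usable subsample pairs; all clusterings were degenerate")
  }
  out <- mean(pair_scores)
  attr(out, "n_skipped") <- n_skipped
  out
}
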