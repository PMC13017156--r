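# Domain types and per-entry probabilistic quantities shared by the whole
# package: score matrices, parametric density families, block-model
# parameters, edge responsibilities, structured l-values and the ELBO.

# Probabilities are clipped away from {0, 1} before any logarithm; the
# variational updates divide by rho and 1 - rho.
.PROB_EPS <- 1e-10

.clip_prob <- function(p) pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)

# Gaussian log-density without the dispatch overhead of dnorm(); used in the
# inner loops where it is evaluated thousands of times per fit.
.gauss_ld <- function(x, mean, var) {
  -0.5 * log(2 * pi * var) - (x - mean)^2 / (2 * var)
}

#' Score matrix of association statistics
#'
#' Wraps an `n1 x n2` real matrix of association scores (typically z-scores,
#' rows indexing one feature type such as taxa and columns the other such as
#' metabolites) together with unique row and column identifiers.
#'
#' @param values Numeric matrix with at least two rows and two columns; all
#'   entries must be finite.
#' @param row_ids,col_ids Character vectors of unique identifiers. Default to
#'   the dimnames of `values`, or `row1, row2, ...` / `col1, col2, ...`.
#' @return An object of class `score_matrix` with fields `values`, `row_ids`
#'   and `col_ids`.
#' @export
#' @examples
#' X <- score_matrix(matrix(rnorm(12), 3, 4))
#' dim(X$values)
score_matrix <- function(values, row_ids = NULL, col_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n1 <- nrow(values)
  n2 <- ncol(values)
  if (n1 < 2L || n2 < 2L) {
    stop("a score matrix needs at least 2 rows and 2 columns")
  }
  if (!all(is.finite(values))) {
    stop("all association scores must be finite")
  }
  if (is.null(row_ids)) row_ids <- rownames(values)
  if (is.null(row_ids)) row_ids <- paste0("row", seq_len(n1))
  if (is.null(col_ids)) col_ids <- colnames(values)
  if (is.null(col_ids)) col_ids <- paste0("col", seq_len(n2))
  row_ids <- as.character(row_ids)
  col_ids <- as.character(col_ids)
  if (length(row_ids) != n1 || length(col_ids) != n2) {
    stop("identifier lengths do not match the matrix dimensions")
  }
  if (anyDuplicated(row_ids)) stop("row identifiers must be unique")
  if (anyDuplicated(col_ids)) stop("column identifiers must be unique")
  dimnames(values) <- list(row_ids, col_ids)
  structure(list(values = values, row_ids = row_ids, col_ids = col_ids),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d x %d\n", nrow(x$values), ncol(x$values)))
  cat(sprintf("  value range [%.3f, %.3f]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

# Accept either a score_matrix or a bare numeric matrix everywhere.
.as_score_matrix <- function(X) {
  if (inherits(X, "score_matrix")) X else score_matrix(X)
}

#' Parametric density specification
#'
#' A single member of a parametric density family. Currently the Gaussian
#' family is supported; the `family` argument is the extension point for
#' other parametric families (such as Gamma) with tractable M-step updates.
#'
#' @param family Density family name; only `"gaussian"` is supported.
#' @param mean,var Gaussian mean and variance (`var > 0`).
#' @return An object of class `density_spec`.
#' @export
#' @examples
#' g0 <- density_spec("gaussian", mean = 0, var = 1)
#' density_eval(g0, 0)
density_spec <- function(family = "gaussian", mean = 0, var = 1) {
  family <- as.character(family)
  if (!identical(family, "gaussian")) {
    stop(sprintf("unsupported density family '%s'", family))
  }
  if (!is.finite(var) || var <= 0) stop("variance must be positive")
  structure(list(family = family, params = c(mean = mean, var = var)),
            class = "density_spec")
}

#' Evaluate a parametric log-density
#'
#' @param spec A [density_spec()].
#' @param x Numeric scalar, vector or matrix; the shape is preserved.
#' @return Log-density values, finite for finite `x`.
#' @export
density_eval <- function(spec, x) {
  if (!inherits(spec, "density_spec")) stop("`spec` must be a density_spec")
  switch(spec$family,
         gaussian = .gauss_ld(x, spec$params[["mean"]], spec$params[["var"]]),
         stop(sprintf("unsupported density family '%s'", spec$family)))
}

#' Bipartite noisy SBM parameters
#'
#' The complete parameter set of the model: mixing proportions for row and
#' column blocks, a `B1 x B2` matrix of within-block edge probabilities, a
#' null density (Gaussian with mean fixed at zero) and one Gaussian
#' alternative density per block, stored as matrices of means and variances.
#'
#' @param alpha1,alpha2 Probability vectors over the `B1` row and `B2`
#'   column blocks (each sums to one).
#' @param Pi `B1 x B2` matrix of edge probabilities in `[0, 1]`.
#' @param nu0 Null [density_spec()]; its mean must be 0.
#' @param mu,sigma2 `B1 x B2` matrices of alternative Gaussian means and
#'   variances (`sigma2 > 0`).
#' @return An object of class `block_model_params`.
#' @export
#' @examples
#' theta <- block_model_params(c(0.5, 0.5), c(0.5, 0.5),
#'                             Pi = matrix(0.3, 2, 2),
#'                             mu = matrix(2, 2, 2),
#'                             sigma2 = matrix(1, 2, 2))
block_model_params <- function(alpha1, alpha2, Pi,
                               nu0 = density_spec("gaussian", 0, 1),
                               mu, sigma2) {
  alpha1 <- as.numeric(alpha1)
  alpha2 <- as.numeric(alpha2)
  B1 <- length(alpha1)
  B2 <- length(alpha2)
  Pi <- as.matrix(Pi)
  mu <- as.matrix(mu)
  sigma2 <- as.matrix(sigma2)
  if (any(alpha1 < 0) || any(alpha2 < 0) ||
      abs(sum(alpha1) - 1) > 1e-8 || abs(sum(alpha2) - 1) > 1e-8) {
    stop("mixing proportions must be non-negative and sum to 1")
  }
  if (!all(dim(Pi) == c(B1, B2)) || !all(dim(mu) == c(B1, B2)) ||
      !all(dim(sigma2) == c(B1, B2))) {
    stop("Pi, mu and sigma2 must all be B1 x B2")
  }
  if (any(Pi < 0) || any(Pi > 1)) stop("Pi entries must lie in [0, 1]")
  if (any(sigma2 <= 0)) stop("alternative variances must be positive")
  if (!inherits(nu0, "density_spec")) stop("`nu0` must be a density_spec")
  if (nu0$family == "gaussian" && abs(nu0$params[["mean"]]) > 0) {
    stop("the null Gaussian mean is fixed at 0")
  }
  structure(list(alpha1 = alpha1, alpha2 = alpha2, Pi = Pi, nu0 = nu0,
                 mu = mu, sigma2 = sigma2, family = "gaussian"),
            class = "block_model_params")
}

#' @export
print.block_model_params <- function(x, ...) {
  cat(sprintf("block_model_params: B1 = %d, B2 = %d\n",
              length(x$alpha1), length(x$alpha2)))
  cat("alpha1:", signif(x$alpha1, 3), "\n")
  cat("alpha2:", signif(x$alpha2, 3), "\n")
  cat("Pi:\n"); print(signif(x$Pi, 3))
  cat("mu:\n"); print(signif(x$mu, 3))
  invisible(x)
}

#' Latent truth of a simulated instance
#'
#' The unobserved adjacency matrix and, when the generator has them, the
#' latent block memberships of a simulated score matrix.
#'
#' @param A Binary `n1 x n2` adjacency matrix (`A[i, j] = 1` means the null
#'   for pair `(i, j)` is false).
#' @param Z1,Z2 Optional integer membership vectors.
#' @return An object of class `latent_truth`.
#' @export
latent_truth <- function(A, Z1 = NULL, Z2 = NULL) {
  A <- as.matrix(A)
  if (!all(A %in% c(0, 1))) stop("A must be binary")
  storage.mode(A) <- "integer"
  if (!is.null(Z1)) {
    Z1 <- as.integer(Z1)
    if (length(Z1) != nrow(A) || any(Z1 < 1L)) stop("invalid Z1")
  }
  if (!is.null(Z2)) {
    Z2 <- as.integer(Z2)
    if (length(Z2) != ncol(A) || any(Z2 < 1L)) stop("invalid Z2")
  }
  structure(list(A = A, Z1 = Z1, Z2 = Z2), class = "latent_truth")
}

#' Variational membership probabilities
#'
#' Factorized variational parameters: each row of `beta1` (`beta2`) is the
#' approximate posterior over row (column) block memberships for one row
#' (column) feature. Edge responsibilities are recomputed on demand from the
#' current parameters rather than stored.
#'
#' @param beta1 `n1 x B1` matrix with rows summing to one.
#' @param beta2 `n2 x B2` matrix with rows summing to one.
#' @return An object of class `variational_state`.
#' @export
variational_state <- function(beta1, beta2) {
  beta1 <- as.matrix(beta1)
  beta2 <- as.matrix(beta2)
  if (any(beta1 < 0) || any(beta2 < 0) ||
      any(abs(rowSums(beta1) - 1) > 1e-8) ||
      any(abs(rowSums(beta2) - 1) > 1e-8)) {
    stop("membership probabilities must be non-negative with unit row sums")
  }
  structure(list(beta1 = beta1, beta2 = beta2), class = "variational_state")
}

# Log-odds that entry x in block (q, l) is an edge.
.edge_logit <- function(x, q, l, theta) {
  p <- .clip_prob(theta$Pi[q, l])
  lg1 <- .gauss_ld(x, theta$mu[q, l], theta$sigma2[q, l])
  lg0 <- density_eval(theta$nu0, x)
  log(p) - log1p(-p) + lg1 - lg0
}

#' Posterior edge responsibility
#'
#' Probability that entry `x`, assigned to block `(q, l)`, is a true edge:
#' `pi_ql g(x) / (pi_ql g(x) + (1 - pi_ql) g0(x))`, computed in log space so
#' it is stable for `|x|` up to at least 40.
#'
#' @param x Numeric scalar, vector or matrix of scores (shape preserved).
#' @param q,l Row and column block indices (1-based).
#' @param theta A [block_model_params()].
#' @return Values in `[0, 1]`. Exactly 0 when `Pi[q, l] <= 0` and exactly 1
#'   when `Pi[q, l] >= 1`.
#' @export
responsibility <- function(x, q, l, theta) {
  p <- theta$Pi[q, l]
  if (p <= 0) return(x * 0)
  if (p >= 1) return(x * 0 + 1)
  stats::plogis(.edge_logit(x, q, l, theta))
}

#' Structured l-value
#'
#' Posterior probability that the null hypothesis is true for an entry in
#' block `(q, l)`:
#' `(1 - pi_ql) g0(x) / (pi_ql g(x) + (1 - pi_ql) g0(x))`.
#' This is the structured analogue of a local false discovery rate and is
#' the exact complement of [responsibility()].
#'
#' @inheritParams responsibility
#' @return Values in `[0, 1]`.
#' @export
#' @examples
#' theta <- block_model_params(1, 1, Pi = matrix(0.5, 1, 1),
#'                             mu = matrix(2, 1, 1), sigma2 = matrix(1, 1, 1))
#' ell_value(0, 1, 1, theta)  # 0.8808
ell_value <- function(x, q, l, theta) {
  p <- theta$Pi[q, l]
  if (p <= 0) return(x * 0 + 1)
  if (p >= 1) return(x * 0)
  stats::plogis(-.edge_logit(x, q, l, theta))
}

#' Variational edge term
#'
#' The per-entry contribution
#' `rho log(pi g(x) / rho) + (1 - rho) log((1 - pi) g0(x) / (1 - rho))`
#' appearing in the ELBO and in the membership fixed-point updates, with the
#' conventions `0 log(. / 0) = 0`. As a function of `rho` on `[0, 1]` it is
#' maximized at `rho = responsibility(x, q, l, theta)`, where it equals the
#' log marginal mixture density of the block.
#'
#' @inheritParams responsibility
#' @param rho Edge probability (or array of them, matching `x`) in `[0, 1]`.
#' @return Numeric, same shape as `x`.
#' @export
d_term <- function(x, q, l, theta, rho) {
  if (any(rho < 0) || any(rho > 1)) stop("rho must lie in [0, 1]")
  p <- .clip_prob(theta$Pi[q, l])
  lg1 <- .gauss_ld(x, theta$mu[q, l], theta$sigma2[q, l])
  lg0 <- density_eval(theta$nu0, x)
  t1 <- ifelse(rho > 0, rho * (log(p) + lg1 - log(rho)), 0)
  t0 <- ifelse(rho < 1, (1 - rho) * (log1p(-p) + lg0 - log1p(-rho)), 0)
  t1 + t0
}

# Per-block log mixture densities log(pi g1 + (1 - pi) g0) and edge
# responsibilities, both evaluated at theta. Returned as lists indexed by
# (q - 1) * B2 + l; lg0 may be passed in to avoid recomputation.
.block_quantities <- function(xv, theta, lg0 = NULL, want_resp = TRUE) {
  B1 <- length(theta$alpha1)
  B2 <- length(theta$alpha2)
  if (is.null(lg0)) lg0 <- density_eval(theta$nu0, xv)
  D <- vector("list", B1 * B2)
  R <- if (want_resp) vector("list", B1 * B2) else NULL
  for (q in seq_len(B1)) {
    for (l in seq_len(B2)) {
      k <- (q - 1L) * B2 + l
      p <- .clip_prob(theta$Pi[q, l])
      a <- log(p) + .gauss_ld(xv, theta$mu[q, l], theta$sigma2[q, l])
      del <- a - (log1p(-p) + lg0)
      if (want_resp) R[[k]] <- stats::plogis(del)
      m <- pmax(a, a - del)
      D[[k]] <- m + log1p(exp(-abs(del)))
    }
  }
  list(D = D, R = R)
}

# sum_i sum_q beta[i, q] * (log alpha[q] - log beta[i, q]) with 0 log 0 = 0
.mem_term <- function(beta, alpha) {
  la <- log(.clip_prob(alpha))
  s <- 0
  for (q in seq_along(alpha)) {
    b <- beta[, q]
    pos <- b > 0
    s <- s + sum(b[pos] * (la[q] - log(b[pos])))
  }
  s
}

.elbo_blocks <- function(D, theta, state) {
  B1 <- length(theta$alpha1)
  B2 <- length(theta$alpha2)
  cross <- 0
  for (q in seq_len(B1)) {
    for (l in seq_len(B2)) {
      cross <- cross +
        drop(crossprod(state$beta1[, q],
                       D[[(q - 1L) * B2 + l]] %*% state$beta2[, l]))
    }
  }
  .mem_term(state$beta1, theta$alpha1) +
    .mem_term(state$beta2, theta$alpha2) + cross
}

#' Evidence lower bound
#'
#' The variational lower bound on the log marginal likelihood:
#' membership terms `sum_i sum_q beta1[i, q] log(alpha1[q] / beta1[i, q])`
#' (and likewise for columns) plus the cross term
#' `sum_ij sum_ql beta1[i, q] beta2[j, l] d_ij^ql`, where each [d_term()] is
#' evaluated at the posterior responsibility for the current `theta` so it
#' reduces to the log mixture density of the block.
#'
#' @param X A [score_matrix()] (or bare matrix).
#' @param theta A [block_model_params()].
#' @param state A [variational_state()] with dimensions matching `X` and
#'   `theta`.
#' @return Scalar ELBO value; never exceeds the exact log marginal
#'   likelihood.
#' @export
elbo <- function(X, theta, state) {
  X <- .as_score_matrix(X)
  xv <- X$values
  if (nrow(state$beta1) != nrow(xv) || nrow(state$beta2) != ncol(xv) ||
      ncol(state$beta1) != length(theta$alpha1) ||
      ncol(state$beta2) != length(theta$alpha2)) {
    stop("dimension mismatch between X, theta and state")
  }
  bl <- .block_quantities(xv, theta, want_resp = FALSE)
  .elbo_blocks(bl$D, theta, state)
}
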