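# Independent oracles used across the suite. These deliberately avoid the
# package's log-space code paths: densities are evaluated with dnorm() and
# combined with plain arithmetic, and marginal likelihoods are obtained by
# enumerating every block assignment.

# mixture density of one entry in block (q, l), plain arithmetic
oracle_mix_density <- function(x, theta, q, l) {
  p <- theta$Pi[q, l]
  s0 <- theta$nu0$params[["var"]]
  p * stats::dnorm(x, theta$mu[q, l], sqrt(theta$sigma2[q, l])) +
    (1 - p) * stats::dnorm(x, 0, sqrt(s0))
}

# P(A = 0 | x, Z1 = q, Z2 = l) by direct density arithmetic
oracle_null_posterior <- function(x, theta, q, l) {
  p <- theta$Pi[q, l]
  s0 <- theta$nu0$params[["var"]]
  g0 <- stats::dnorm(x, 0, sqrt(s0))
  g1 <- stats::dnorm(x, theta$mu[q, l], sqrt(theta$sigma2[q, l]))
  (1 - p) * g0 / (p * g1 + (1 - p) * g0)
}

# exact log marginal likelihood by enumerating all B1^n1 * B2^n2 membership
# assignments; the adjacency marginalizes analytically given memberships
oracle_log_marginal <- function(xv, theta) {
  n1 <- nrow(xv)
  n2 <- ncol(xv)
  B1 <- length(theta$alpha1)
  B2 <- length(theta$alpha2)
  z1s <- as.matrix(expand.grid(rep(list(seq_len(B1)), n1)))
  z2s <- as.matrix(expand.grid(rep(list(seq_len(B2)), n2)))
  vals <- numeric(0)
  for (a in seq_len(nrow(z1s))) {
    for (b in seq_len(nrow(z2s))) {
      z1 <- z1s[a, ]
      z2 <- z2s[b, ]
      ll <- sum(log(theta$alpha1[z1])) + sum(log(theta$alpha2[z2]))
      for (i in seq_len(n1)) {
        for (j in seq_len(n2)) {
          ll <- ll + log(oracle_mix_density(xv[i, j], theta, z1[i], z2[j]))
        }
      }
      vals <- c(vals, ll)
    }
  }
  m <- max(vals)
  m + log(sum(exp(vals - m)))
}

# random valid parameter set for property tests
random_theta <- function(B1, B2, seed, s0 = 1) {
  set.seed(seed)
  a1 <- stats::runif(B1, 0.5, 1.5)
  a2 <- stats::runif(B2, 0.5, 1.5)
  block_model_params(
    a1 / sum(a1), a2 / sum(a2),
    Pi = matrix(stats::runif(B1 * B2, 0.05, 0.95), B1, B2),
    nu0 = density_spec("gaussian", 0, s0),
    mu = matrix(stats::runif(B1 * B2, -3, 3), B1, B2),
    sigma2 = matrix(stats::runif(B1 * B2, 0.5, 2), B1, B2))
}

random_state <- function(n1, n2, B1, B2, seed) {
  set.seed(seed)
  b1 <- matrix(stats::rexp(n1 * B1), n1, B1)
  b2 <- matrix(stats::rexp(n2 * B2), n2, B2)
  variational_state(b1 / rowSums(b1), b2 / rowSums(b2))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in all_perms(n - 1)) {
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# permutation of fitted block labels maximizing agreement with the truth
match_labels <- function(z_hat, z_true, B) {
  best <- NULL
  best_agree <- -1
  for (p in all_perms(B)) {
    agree <- sum(p[z_hat] == z_true)
    if (agree > best_agree) {
      best_agree <- agree
      best <- p
    }
  }
  best
}

# direct one-dimensional two-component EM with a fixed null, used as the
# oracle for the single-block special case
pooled_mixture_em <- function(x, s0 = 1, tol = 1e-12, max_iter = 20000) {
  pi <- mean(2 * stats::pnorm(-abs(x) / sqrt(s0)) < 0.5)
  flag <- 2 * stats::pnorm(-abs(x) / sqrt(s0)) < 0.5
  mu <- mean(x[flag])
  s2 <- max(stats::var(x[flag]), 1e-4)
  for (i in seq_len(max_iter)) {
    num <- pi * stats::dnorm(x, mu, sqrt(s2))
    r <- num / (num + (1 - pi) * stats::dnorm(x, 0, sqrt(s0)))
    pin <- mean(r)
    mun <- sum(r * x) / sum(r)
    s2n <- sum(r * (x - mun)^2) / sum(r)
    done <- abs(pin - pi) < tol && abs(mun - mu) < tol && abs(s2n - s2) < tol
    pi <- pin
    mu <- mun
    s2 <- s2n
    if (done) break
  }
  num <- pi * stats::dnorm(x, mu, sqrt(s2))
  r <- num / (num + (1 - pi) * stats::dnorm(x, 0, sqrt(s0)))
  list(pi = pi, mu = mu, s2 = s2, lvalues = 1 - r)
}
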