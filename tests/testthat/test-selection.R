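# ICL model selection and the subsampling stability score.

test_that("the BIC penalty matches direct arithmetic and is monotone", {
  # single block: only the d0 + (1 + d1) block parameters remain
  expect_equal(bic_penalty(1, 1, 10, 20, d0 = 0, d1 = 2), 3 * log(200))
  expect_equal(bic_penalty(3, 3, 150, 200, d0 = 1, d1 = 2),
               2 * log(150) + 2 * log(200) + 28 * log(30000))
  expect_equal(bic_penalty(3, 3, 150, 200, d0 = 1, d1 = 2), 309.2685,
               tolerance = 1e-6)
  for (B in 1:4) {
    expect_lt(bic_penalty(B, 2, 50, 60, 1, 2), bic_penalty(B + 1, 2, 50, 60, 1, 2))
    expect_lt(bic_penalty(2, B, 50, 60, 1, 2), bic_penalty(2, B + 1, 50, 60, 1, 2))
  }
})

test_that("a degenerate fit's ICL is the complete-data log-likelihood minus the penalty", {
  set.seed(101)
  n1 <- 4
  n2 <- 5
  xv <- matrix(rnorm(n1 * n2, 2), n1, n2)
  # responsibilities pinned to ~1 by an extreme edge probability
  th <- block_model_params(c(.5, .5), 1, Pi = matrix(1 - 1e-10, 2, 1),
                           mu = matrix(2, 2, 1), sigma2 = matrix(1, 2, 1))
  cl <- c(1, 1, 2, 2)
  st <- variational_state(cbind(cl == 1, cl == 2) * 1, matrix(1, n2, 1))
  fit <- structure(list(theta_hat = th, state = st,
                        opts = fit_options(2, 1, fix_null = TRUE)),
                   class = "bnsbm_fit")
  # complete-data log-likelihood with A == 1 everywhere and hard Z
  ll <- sum(log(th$alpha1[cl])) + n2 * log(1) +
    sum(log(1 - 1e-10)) * n1 * n2 +
    sum(dnorm(xv, 2, 1, log = TRUE))
  pen <- bic_penalty(2, 1, n1, n2, 0, 2)
  expect_equal(icl(xv, fit), ll - pen, tolerance = 1e-5)
  # and never above ELBO minus the penalty
  expect_lte(icl(xv, fit), elbo(xv, th, st) - pen + 1e-10)
})

test_that("the expected complete-data likelihood matches an enumeration oracle", {
  set.seed(111)
  n1 <- n2 <- 3
  B1 <- B2 <- 2
  xv <- matrix(rnorm(9, 1), 3, 3)
  th <- random_theta(B1, B2, 112)
  st <- random_state(n1, n2, B1, B2, 113)
  fit <- structure(list(theta_hat = th, state = st,
                        opts = fit_options(B1, B2, fix_null = TRUE)),
                   class = "bnsbm_fit")
  got <- icl(xv, fit) + bic_penalty(B1, B2, n1, n2, 0, 2)

  # oracle: enumerate memberships weighted by the factorized Q, then take
  # the exact conditional expectation over A entry by entry
  z1s <- as.matrix(expand.grid(rep(list(1:B1), n1)))
  z2s <- as.matrix(expand.grid(rep(list(1:B2), n2)))
  s0 <- th$nu0$params[["var"]]
  expected <- 0
  for (a in seq_len(nrow(z1s))) {
    for (b in seq_len(nrow(z2s))) {
      z1 <- z1s[a, ]
      z2 <- z2s[b, ]
      wq <- prod(st$beta1[cbind(1:n1, z1)]) *
        prod(st$beta2[cbind(1:n2, z2)])
      if (wq == 0) next
      contrib <- sum(log(th$alpha1[z1])) + sum(log(th$alpha2[z2]))
      for (i in 1:n1) {
        for (j in 1:n2) {
          q <- z1[i]
          l <- z2[j]
          p <- th$Pi[q, l]
          r <- 1 - oracle_null_posterior(xv[i, j], th, q, l)
          contrib <- contrib +
            r * (log(p) + dnorm(xv[i, j], th$mu[q, l],
                                sqrt(th$sigma2[q, l]), log = TRUE)) +
            (1 - r) * (log(1 - p) + dnorm(xv[i, j], 0, sqrt(s0),
                                          log = TRUE))
        }
      }
      expected <- expected + wq * contrib
    }
  }
  expect_equal(got, expected, tolerance = 1e-8)
})

test_that("ICL is invariant to block relabelling", {
  sim <- sample_noisysbm(25, 30, scenario_a_params(), seed = 121)
  fit <- fit_bnsbm(sim$X, fit_options(3, 2, n_restarts = 2, seed = 121),
                   warn = FALSE)
  base <- icl(sim$X, fit)
  perm <- c(2, 3, 1)
  fit2 <- fit
  fit2$theta_hat$alpha1 <- fit$theta_hat$alpha1[perm]
  fit2$theta_hat$Pi <- fit$theta_hat$Pi[perm, , drop = FALSE]
  fit2$theta_hat$mu <- fit$theta_hat$mu[perm, , drop = FALSE]
  fit2$theta_hat$sigma2 <- fit$theta_hat$sigma2[perm, , drop = FALSE]
  fit2$state$beta1 <- fit$state$beta1[, perm, drop = FALSE]
  expect_equal(icl(sim$X, fit2), base, tolerance = 1e-9)
})

test_that("model selection prefers the true block structure and honours ties", {
  sim <- sample_noisysbm(100, 140, scenario_a_params(), seed = 131)
  sel <- select_model(sim$X, c(1, 3), c(1, 3),
                      fit_options(1, 1, n_restarts = 2, seed = 131))
  icl11 <- sel$grid$icl[sel$grid$B1 == 1 & sel$grid$B2 == 1]
  icl33 <- sel$grid$icl[sel$grid$B1 == 3 & sel$grid$B2 == 3]
  expect_gt(icl33, icl11)
  expect_equal(unname(sel$best), c(3, 3))
  expect_s3_class(sel$best_fit, "bnsbm_fit")
  # a one-cell grid selects that cell
  sel1 <- select_model(sim$X, 2, 2, fit_options(1, 1, n_restarts = 1,
                                                seed = 131))
  expect_equal(unname(sel1$best), c(2, 2))
})

test_that("stability is high for separable structure and low for pure noise", {
  set.seed(141)
  # strongly separated two-bicluster data
  xv <- rbind(cbind(matrix(rnorm(20 * 24, 4), 20, 24),
                    matrix(rnorm(20 * 24, 0), 20, 24)),
              cbind(matrix(rnorm(20 * 24, 0), 20, 24),
                    matrix(rnorm(20 * 24, 4), 20, 24)))
  s_good <- stability_score(xv, 2, 2, n_subsamples = 6, frac = 0.8,
                            opts = fit_options(2, 2, n_restarts = 2,
                                               seed = 141))
  expect_gte(s_good, 0.9)
  # single-block axes are stable by convention
  expect_equal(as.numeric(stability_score(xv, 1, 1, n_subsamples = 3,
                                          opts = fit_options(1, 1,
                                                             n_restarts = 1,
                                                             seed = 141))), 1)
  # pure noise has no reproducible 3 x 3 structure
  noise <- matrix(rnorm(40 * 48), 40, 48)
  s_noise <- stability_score(noise, 3, 3, n_subsamples = 6, frac = 0.8,
                             opts = fit_options(3, 3, n_restarts = 2,
                                                seed = 142))
  expect_lt(s_noise, 0.4)
})
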