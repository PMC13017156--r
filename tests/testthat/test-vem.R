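# Initialization, E-step, M-step and the full variational EM fit.

test_that("initialization recovers separable row groups and tabulated block rates", {
  set.seed(11)
  # two clearly separated row-mean groups
  xv <- rbind(matrix(rnorm(10 * 20, 6), 10, 20),
              matrix(rnorm(10 * 20, -6), 10, 20))
  init <- initialize_vem(score_matrix(xv), fit_options(2, 1, seed = 1))
  cl <- max.col(init$state$beta1)
  expect_equal(length(unique(cl[1:10])), 1)
  expect_equal(length(unique(cl[11:20])), 1)
  expect_true(cl[1] != cl[20])

  # initial Pi equals an independent tabulation of 1{p < 0.5} block means
  sim <- sample_noisysbm(40, 50, scenario_a_params(), seed = 3)
  set.seed(5)
  init <- initialize_vem(sim$X, fit_options(3, 3, seed = 5))
  cl1 <- max.col(init$state$beta1)
  cl2 <- max.col(init$state$beta2)
  flag <- 2 * pnorm(-abs(sim$X$values)) < 0.5
  for (q in 1:3) {
    for (l in 1:3) {
      expected <- mean(flag[cl1 == q, cl2 == l])
      expected <- min(max(expected, 1e-10), 1 - 1e-10)
      expect_equal(init$theta$Pi[q, l], expected, tolerance = 1e-12)
    }
  }
})

test_that("all-zero scores give an edge-free single-block initialization", {
  xv <- matrix(0, 6, 7)
  init <- initialize_vem(score_matrix(xv), fit_options(1, 1, seed = 1))
  # p-value is 1 everywhere, so no entry is flagged and Pi sits at the floor
  expect_lt(init$theta$Pi[1, 1], 1e-9)
})

test_that("E-step fixed points respect symmetry and optimize each membership row", {
  set.seed(21)
  xv <- matrix(rnorm(9, 1), 3, 3)
  # single block: memberships have nowhere to move
  th1 <- block_model_params(1, 1, Pi = matrix(0.4, 1, 1),
                            mu = matrix(2, 1, 1), sigma2 = matrix(1, 1, 1))
  st1 <- variational_state(matrix(1, 3, 1), matrix(1, 3, 1))
  out1 <- e_step(xv, th1, st1)
  expect_equal(out1$beta1, matrix(1, 3, 1))

  # fully exchangeable blocks: the uniform state is a fixed point
  th_sym <- block_model_params(c(.5, .5), c(.5, .5),
                               Pi = matrix(0.3, 2, 2),
                               mu = matrix(2, 2, 2),
                               sigma2 = matrix(1, 2, 2))
  st_u <- variational_state(matrix(0.5, 3, 2), matrix(0.5, 3, 2))
  out_u <- e_step(xv, th_sym, st_u)
  expect_equal(out_u$beta1, matrix(0.5, 3, 2), tolerance = 1e-12)
  expect_equal(out_u$beta2, matrix(0.5, 3, 2), tolerance = 1e-12)

  # generic instance: ELBO does not decrease, and the last-updated side is
  # row-wise optimal against a fine simplex grid
  th <- random_theta(2, 2, 22)
  st <- random_state(3, 3, 2, 2, 23)
  out <- e_step(xv, th, st, inner_iter = 5)
  expect_gte(elbo(xv, th, out), elbo(xv, th, st) - 1e-10)
  base <- elbo(xv, th, out)
  for (j in 1:3) {
    for (t in seq(0, 1, by = 0.01)) {
      st_mod <- out
      st_mod$beta2[j, ] <- c(t, 1 - t)
      expect_lte(elbo(xv, th, st_mod), base + 1e-10)
    }
  }
})

test_that("M-step formulas match a naive triple-loop accumulation", {
  set.seed(31)
  n1 <- 4
  n2 <- 5
  B1 <- 2
  B2 <- 2
  xv <- matrix(rnorm(n1 * n2, 1), n1, n2)
  th <- random_theta(B1, B2, 32)
  st <- random_state(n1, n2, B1, B2, 33)
  out <- m_step(xv, st, th, fix_null = FALSE)

  rho <- function(x, q, l) oracle_null_posterior(x, th, q, l)
  for (q in seq_len(B1)) {
    expect_equal(out$alpha1[q], mean(st$beta1[, q]))
    for (l in seq_len(B2)) {
      sw <- se <- sx <- sv <- s0n <- s0d <- 0
      for (i in seq_len(n1)) {
        for (j in seq_len(n2)) {
          w <- st$beta1[i, q] * st$beta2[j, l]
          r <- 1 - rho(xv[i, j], q, l)
          sw <- sw + w
          se <- se + w * r
          sx <- sx + w * r * xv[i, j]
        }
      }
      expect_equal(out$Pi[q, l], se / sw, tolerance = 1e-10)
      mu_hat <- sx / se
      expect_equal(out$mu[q, l], mu_hat, tolerance = 1e-10)
      for (i in seq_len(n1)) {
        for (j in seq_len(n2)) {
          w <- st$beta1[i, q] * st$beta2[j, l]
          r <- 1 - rho(xv[i, j], q, l)
          sv <- sv + w * r * (xv[i, j] - mu_hat)^2
        }
      }
      expect_equal(out$sigma2[q, l], sv / se, tolerance = 1e-10)
    }
  }
  expect_equal(sum(out$alpha1), 1, tolerance = 1e-12)
  expect_equal(sum(out$alpha2), 1, tolerance = 1e-12)
  # null variance accumulates over all blocks
  s0n <- s0d <- 0
  for (q in seq_len(B1)) {
    for (l in seq_len(B2)) {
      for (i in seq_len(n1)) {
        for (j in seq_len(n2)) {
          w <- st$beta1[i, q] * st$beta2[j, l] * rho(xv[i, j], q, l)
          s0n <- s0n + w * xv[i, j]^2
          s0d <- s0d + w
        }
      }
    }
  }
  expect_equal(out$nu0$params[["var"]], s0n / s0d, tolerance = 1e-10)
})

test_that("near-certain responsibilities collapse block means to arithmetic means", {
  set.seed(41)
  xv <- matrix(rnorm(30, 3), 5, 6)
  th <- block_model_params(c(.6, .4), 1,
                           Pi = matrix(1 - 1e-10, 2, 1),
                           mu = matrix(3, 2, 1), sigma2 = matrix(1, 2, 1))
  cl <- c(1, 1, 1, 2, 2)
  st <- variational_state(cbind(cl == 1, cl == 2) * 1, matrix(1, 6, 1))
  out <- m_step(xv, st, th)
  expect_equal(out$mu[1, 1], mean(xv[1:3, ]), tolerance = 1e-6)
  expect_equal(out$mu[2, 1], mean(xv[4:5, ]), tolerance = 1e-6)
})

test_that("the single-block fit reproduces a direct pooled mixture EM", {
  sim <- sample_noisysbm(40, 50, scenario_a_params(), seed = 51)
  opts <- fit_options(1, 1, n_restarts = 1, seed = 51,
                      elbo_rel_tol = 1e-12, max_outer_iter = 20000)
  fit <- fit_bnsbm(sim$X, opts, warn = FALSE)
  oracle <- pooled_mixture_em(as.vector(sim$X$values))
  # the two stopping rules (ELBO change vs parameter change) land within
  # 1e-4 of each other on the same stationary point
  expect_equal(fit$theta_hat$Pi[1, 1], oracle$pi, tolerance = 1e-4)
  expect_equal(fit$theta_hat$mu[1, 1], oracle$mu, tolerance = 1e-4)
  L <- lvalue_matrix(sim$X, fit)
  expect_lt(max(abs(as.vector(L) - oracle$lvalues)), 1e-3)
  # and the fitted parameters are a fixed point of the direct EM map:
  # one oracle update barely moves them
  x <- as.vector(sim$X$values)
  pi0 <- fit$theta_hat$Pi[1, 1]
  mu0 <- fit$theta_hat$mu[1, 1]
  s20 <- fit$theta_hat$sigma2[1, 1]
  num <- pi0 * dnorm(x, mu0, sqrt(s20))
  r <- num / (num + (1 - pi0) * dnorm(x))
  expect_equal(mean(r), pi0, tolerance = 1e-5)
  expect_equal(sum(r * x) / sum(r), mu0, tolerance = 1e-5)
})

test_that("fitting a row-permuted matrix permutes the answer, not the model", {
  sim <- sample_noisysbm(120, 160, scenario_a_params(), seed = 61)
  opts <- fit_options(3, 3, n_restarts = 4, seed = 61)
  fit1 <- fit_bnsbm(sim$X, opts, warn = FALSE)
  set.seed(62)
  perm <- sample(120)
  Xp <- score_matrix(sim$X$values[perm, ],
                     row_ids = sim$X$row_ids[perm],
                     col_ids = sim$X$col_ids)
  fit2 <- fit_bnsbm(Xp, opts, warn = FALSE)
  # canonical labels make the parameter sets comparable directly
  expect_equal(fit2$theta_hat$Pi, fit1$theta_hat$Pi, tolerance = 1e-3)
  expect_equal(fit2$theta_hat$mu, fit1$theta_hat$mu, tolerance = 1e-3)
  expect_equal(unname(fit2$Z1_hat), unname(fit1$Z1_hat[perm]))
})

test_that("the fitted biclustering recovers the modular scenario", {
  sim <- sample_noisysbm(150, 200, scenario_a_params(), seed = 71)
  fit <- fit_bnsbm(sim$X, fit_options(3, 3, n_restarts = 3, seed = 71),
                   warn = FALSE)
  expect_gte(mclust::adjustedRandIndex(fit$Z1_hat, sim$truth$Z1), 0.9)
  expect_gte(mclust::adjustedRandIndex(fit$Z2_hat, sim$truth$Z2), 0.9)
  expect_true(all(diff(fit$elbo_trace) >= -1e-8))
})

test_that("hard memberships are the argmax of the membership probabilities", {
  sim <- sample_noisysbm(30, 40, scenario_a_params(), seed = 81)
  fit <- fit_bnsbm(sim$X, fit_options(2, 2, n_restarts = 2, seed = 81),
                   warn = FALSE)
  expect_equal(unname(fit$Z1_hat), max.col(fit$state$beta1, "first"))
  expect_equal(unname(fit$Z2_hat), max.col(fit$state$beta2, "first"))
  # canonical order: mixing proportions non-increasing
  expect_true(all(diff(fit$theta_hat$alpha1) <= 1e-12))
})
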