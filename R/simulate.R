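# Generators for the three benchmark scenarios: (a) a modular bipartite
# SBM, (b) a fully nested graph with one generalist per vertex type, and
# (c) a bipartite preferential-attachment graph; plus score sampling from
# any fixed latent graph. All generators are pure functions of their seed
# (R's default Mersenne-Twister RNG).

#' Sample a bipartite noisy SBM instance
#'
#' Draws block memberships from the mixing proportions, edges from the
#' block connectivities, and scores from the null density on non-edges and
#' the block alternative density on edges.
#'
#' @param n1,n2 Numbers of row and column features.
#' @param theta A [block_model_params()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `X` (a [score_matrix()]) and `truth` (a
#'   [latent_truth()] carrying `A`, `Z1`, `Z2`).
#' @export
#' @examples
#' sim <- sample_noisysbm(30, 40, scenario_a_params(), seed = 7)
#' mean(sim$truth$A)  # about 1/3 under the modular scenario
sample_noisysbm <- function(n1, n2, theta, seed) {
  set.seed(seed)
  B1 <- length(theta$alpha1)
  B2 <- length(theta$alpha2)
  Z1 <- sample.int(B1, n1, replace = TRUE, prob = theta$alpha1)
  Z2 <- sample.int(B2, n2, replace = TRUE, prob = theta$alpha2)
  P <- theta$Pi[Z1, Z2, drop = FALSE]
  A <- matrix(as.integer(stats::runif(n1 * n2) < P), n1, n2)
  s0 <- sqrt(theta$nu0$params[["var"]])
  x0 <- matrix(stats::rnorm(n1 * n2, 0, s0), n1, n2)
  x1 <- matrix(stats::rnorm(n1 * n2), n1, n2) *
    sqrt(theta$sigma2)[Z1, Z2, drop = FALSE] +
    theta$mu[Z1, Z2, drop = FALSE]
  xv <- ifelse(A == 1L, x1, x0)
  list(X = score_matrix(xv), truth = latent_truth(A, Z1, Z2))
}

#' Parameters of the modular benchmark scenario
#'
#' Three equal-probability blocks per axis; within-block (diagonal)
#' connectivity 0.8 and between-block connectivity 0.1; standard normal
#' null; unit-variance Gaussian alternatives with mean 1 on the three
#' dense diagonal blocks and mean 3 elsewhere, so the sparser blocks carry
#' the larger effect size.
#'
#' @return A [block_model_params()] with `B1 = B2 = 3`.
#' @export
scenario_a_params <- function() {
  Pi <- matrix(0.1, 3, 3)
  diag(Pi) <- 0.8
  mu <- matrix(3, 3, 3)
  diag(mu) <- 1
  block_model_params(rep(1, 3) / 3, rep(1, 3) / 3, Pi,
                     density_spec("gaussian", 0, 1), mu, matrix(1, 3, 3))
}

#' Nested bipartite graph from a degree sequence
#'
#' Builds the fully nested graph in which row `i` connects to the first
#' `degrees[i]` columns; with a non-increasing degree sequence every two
#' row neighbourhoods are inclusion-comparable.
#'
#' @param degrees Non-increasing integer vector of row degrees, each in
#'   `[0, n2]`.
#' @param n2 Number of columns.
#' @return Binary `length(degrees) x n2` matrix.
#' @export
nested_graph_from_degrees <- function(degrees, n2) {
  degrees <- as.integer(degrees)
  if (any(diff(degrees) > 0)) stop("degrees must be non-increasing")
  if (any(degrees < 0) || any(degrees > n2)) {
    stop("degrees must lie in [0, n2]")
  }
  A <- matrix(0L, length(degrees), n2)
  for (i in seq_along(degrees)) {
    if (degrees[i] > 0L) A[i, seq_len(degrees[i])] <- 1L
  }
  A
}

#' Single-generalist nested bipartite graph
#'
#' The minimal fully nested graph with one generalist per vertex type:
#' `A[i, j] = 1` iff `i = 1` or `j = 1`. Row 1 connects to every column
#' and column 1 to every row; specialist-specialist pairs are never
#' connected, giving `n1 + n2 - 1` edges in total.
#'
#' @param n1,n2 Numbers of rows and columns (`>= 2`).
#' @return Binary `n1 x n2` matrix.
#' @export
nested_graph <- function(n1, n2) {
  if (n1 < 2 || n2 < 2) stop("n1 and n2 must be at least 2")
  nested_graph_from_degrees(c(n2, rep(1L, n1 - 1L)), n2)
}

.pa_graph_once <- function(n1, lambda, degree_choices, seed) {
  set.seed(seed)
  deg2 <- integer(0)
  nbr <- vector("list", n1)
  for (i in seq_len(n1)) {
    d <- degree_choices[sample.int(length(degree_choices), 1L)]
    mine <- integer(0)
    for (e in seq_len(d)) {
      if (length(deg2) == 0L || stats::runif(1) > lambda) {
        deg2 <- c(deg2, 0L)
        j <- length(deg2)
      } else {
        # preferential attachment; a duplicate pair is redrawn within the
        # existing pool, and a fresh vertex opens if redraws are exhausted
        attempts <- 0L
        repeat {
          j <- sample.int(length(deg2), 1L, prob = deg2)
          if (!(j %in% mine)) break
          attempts <- attempts + 1L
          if (attempts >= 50L) {
            deg2 <- c(deg2, 0L)
            j <- length(deg2)
            break
          }
        }
      }
      mine <- c(mine, j)
      deg2[j] <- deg2[j] + 1L
    }
    nbr[[i]] <- mine
  }
  A <- matrix(0L, n1, length(deg2))
  for (i in seq_len(n1)) A[i, nbr[[i]]] <- 1L
  A
}

#' Bipartite preferential-attachment graph
#'
#' Type-I vertices arrive one at a time; each samples its degree uniformly
#' from `degree_choices` and attaches each of its edges either to a
#' brand-new type-II vertex (probability `1 - lambda`) or to an existing
#' one chosen with probability proportional to its current degree. A
#' duplicate pair is redrawn (up to 50 attempts, after which a new vertex
#' is opened instead); the first type-I vertex necessarily creates all of
#' its neighbours. When `n2` is given, graphs with fewer type-II vertices
#' are padded with isolated columns and graphs with more trigger a restart
#' under a new sub-seed (up to `max_restarts`).
#'
#' @param n1 Number of type-I (row) vertices.
#' @param lambda Preferential-attachment probability in `[0, 1]`.
#' @param degree_choices Candidate degrees, sampled uniformly.
#' @param seed Integer seed.
#' @param n2 Optional exact number of type-II (column) vertices.
#' @param max_restarts Restart budget when `n2` is requested.
#' @return Binary adjacency matrix with attribute `"n2_raw"`, the number
#'   of type-II vertices generated before any padding.
#' @export
pa_graph <- function(n1, lambda = 0.8, degree_choices = 2:6, seed = 1,
                     n2 = NULL, max_restarts = 20L) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (!length(degree_choices)) stop("degree_choices must be non-empty")
  for (attempt in seq_len(max_restarts)) {
    A <- .pa_graph_once(n1, lambda, degree_choices,
                        seed + 100003L * (attempt - 1L))
    raw <- ncol(A)
    if (is.null(n2)) {
      attr(A, "n2_raw") <- raw
      return(A)
    }
    if (raw <= n2) {
      if (raw < n2) A <- cbind(A, matrix(0L, n1, n2 - raw))
      attr(A, "n2_raw") <- raw
      return(A)
    }
  }
  stop(sprintf(
    "could not generate at most %d type-II vertices in %d restarts; lower the degrees or raise lambda",
    n2, max_restarts))
}

#' Sample scores on a fixed latent graph
#'
#' Draws each entry independently from the null density where `A = 0` and
#' from the alternative density where `A = 1`.
#'
#' @param A Binary adjacency matrix.
#' @param null,alt [density_spec()]s for non-edges and edges.
#' @param seed Integer seed.
#' @return A [score_matrix()] of the same dimensions as `A`.
#' @export
scores_from_graph <- function(A, null = density_spec("gaussian", 0, 1),
                              alt = density_spec("gaussian", 2, 1), seed) {
  A <- as.matrix(A)
  set.seed(seed)
  n <- length(A)
  x0 <- stats::rnorm(n, null$params[["mean"]], sqrt(null$params[["var"]]))
  x1 <- stats::rnorm(n, alt$params[["mean"]], sqrt(alt$params[["var"]]))
  xv <- matrix(ifelse(A == 1L, x1, x0), nrow(A), ncol(A))
  score_matrix(xv)
}

#' Simulate a full benchmark scenario
#'
#' Convenience wrapper producing the score matrix and latent truth for the
#' three benchmark scenarios: `"a"` the modular bipartite SBM of
#' [scenario_a_params()], `"b"` the single-generalist [nested_graph()]
#' with `N(0,1)` / `N(2,1)` scores, and `"c"` a [pa_graph()] with the same
#' score densities.
#'
#' @param scenario One of `"a"`, `"b"`, `"c"`.
#' @param n1,n2 Matrix dimensions (defaults 150 x 200, the benchmark
#'   sizes).
#' @param seed Integer seed.
#' @param lambda,degree_choices Scenario (c) parameters.
#' @return A list with `X` and `truth` (memberships only for scenario a).
#' @export
simulate_scenario <- function(scenario = c("a", "b", "c"), n1 = 150,
                              n2 = 200, seed = 1, lambda = 0.8,
                              degree_choices = 2:6) {
  scenario <- match.arg(scenario)
  if (n1 < 2 || n2 < 2) stop("n1 and n2 must be at least 2")
  switch(scenario,
         a = sample_noisysbm(n1, n2, scenario_a_params(), seed),
         b = {
           A <- nested_graph(n1, n2)
           list(X = scores_from_graph(A, seed = seed),
                truth = latent_truth(A))
         },
         c = {
           A <- pa_graph(n1, lambda, degree_choices, seed = seed, n2 = n2)
           X <- scores_from_graph(A, seed = seed + 500000L)
           attr(A, "n2_raw") <- NULL
           list(X = X, truth = latent_truth(A))
         })
}
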