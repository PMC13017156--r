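# TSV and JSON persistence. One tabular dialect throughout: UTF-8
# tab-separated files whose first column holds row identifiers and whose
# header row holds column identifiers.

#' Write a score matrix to TSV
#'
#' @param X A [score_matrix()] or bare matrix.
#' @param path Output file path.
#' @export
write_score_tsv <- function(X, path) {
  X <- .as_score_matrix(X)
  df <- data.frame(id = X$row_ids, X$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score matrix from TSV
#'
#' Expects a header row of column identifiers and a first column of row
#' identifiers.
#'
#' @param path Input file path.
#' @return A [score_matrix()].
#' @export
read_score_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop(sprintf("malformed TSV '%s': need an id column and at least 2 value columns", path))
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1] + 1L
    stop(sprintf("malformed TSV '%s': column %d is not numeric", path, bad))
  }
  score_matrix(m, row_ids = ids, col_ids = colnames(df)[-1])
}

#' Write a binary adjacency matrix to TSV
#' @param A Binary matrix.
#' @param path Output file path.
#' @export
write_adjacency_tsv <- function(A, path) {
  A <- as.matrix(A)
  ids <- rownames(A)
  if (is.null(ids)) ids <- paste0("row", seq_len(nrow(A)))
  cn <- colnames(A)
  if (is.null(cn)) cn <- paste0("col", seq_len(ncol(A)))
  df <- data.frame(id = ids, A, check.names = FALSE)
  colnames(df) <- c("id", cn)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary adjacency matrix from TSV
#' @param path Input file path.
#' @return Integer binary matrix with dimnames.
#' @export
read_adjacency_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write block memberships to TSV
#'
#' Two columns: feature identifier and block label.
#'
#' @param z Named integer vector of memberships.
#' @param path Output file path.
#' @param axis Axis label recorded in the file (1 = rows, 2 = columns).
#' @export
write_membership_tsv <- function(z, path, axis = 1L) {
  df <- data.frame(id = names(z), axis = axis, block = as.integer(z))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a decision as edge and cluster tables
#'
#' `edges_path` gets one row per hypothesis with columns `row_id`,
#' `col_id`, `x`, `lvalue`, `reject`; `clusters_path` gets the hard block
#' memberships with columns `id`, `axis`, `block`.
#'
#' @param decision A [decide()] result.
#' @param X The [score_matrix()] the decision was made on.
#' @param fit The underlying [fit_bnsbm()].
#' @param edges_path,clusters_path Output file paths.
#' @export
write_decision_tsv <- function(decision, X, fit, edges_path,
                               clusters_path) {
  X <- .as_score_matrix(X)
  n1 <- nrow(X$values)
  n2 <- ncol(X$values)
  edges <- data.frame(
    row_id = rep(X$row_ids, times = n2),
    col_id = rep(X$col_ids, each = n1),
    x = as.vector(X$values),
    lvalue = as.vector(decision$lvalues),
    reject = as.integer(as.vector(decision$reject)))
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clusters <- data.frame(
    id = c(names(fit$Z1_hat), names(fit$Z2_hat)),
    axis = rep(1:2, c(n1, n2)),
    block = c(as.integer(fit$Z1_hat), as.integer(fit$Z2_hat)))
  utils::write.table(clusters, clusters_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges_path)
}

.FIT_JSON_KEYS <- c("format", "B1", "B2", "alpha1", "alpha2", "Pi", "nu0",
                    "mu", "sigma2", "beta1", "beta2", "Z1_hat", "Z2_hat",
                    "row_ids", "col_ids", "elbo_trace", "converged", "icl",
                    "opts")

#' Serialize a fit to JSON
#'
#' Writes everything needed to reproduce decisions: parameters,
#' membership probabilities, hard memberships, identifiers, ELBO trace
#' and options. The JSON round-trips losslessly through
#' [fit_from_json()].
#'
#' @param fit A [fit_bnsbm()] result.
#' @param path Output file path.
#' @export
fit_to_json <- function(fit, path) {
  th <- fit$theta_hat
  obj <- list(
    format = "bnsbm_fit",
    B1 = length(th$alpha1), B2 = length(th$alpha2),
    alpha1 = th$alpha1, alpha2 = th$alpha2, Pi = th$Pi,
    nu0 = list(family = th$nu0$family,
               mean = th$nu0$params[["mean"]],
               var = th$nu0$params[["var"]]),
    mu = th$mu, sigma2 = th$sigma2,
    beta1 = fit$state$beta1, beta2 = fit$state$beta2,
    Z1_hat = as.integer(fit$Z1_hat), Z2_hat = as.integer(fit$Z2_hat),
    row_ids = fit$row_ids, col_ids = fit$col_ids,
    elbo_trace = fit$elbo_trace, converged = fit$converged,
    icl = fit$icl, opts = unclass(fit$opts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a fit from JSON
#'
#' Rejects files with unknown top-level keys so stale or foreign
#' configuration cannot slip through silently.
#'
#' @param path Input file path.
#' @return A `bnsbm_fit` object.
#' @export
fit_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  unknown <- setdiff(names(obj), .FIT_JSON_KEYS)
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in fit JSON: %s",
                 paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(.FIT_JSON_KEYS, names(obj))
  if (length(missing)) {
    stop(sprintf("fit JSON is missing key(s): %s",
                 paste(missing, collapse = ", ")))
  }
  as_mat <- function(m, nr, nc) matrix(as.numeric(m), nr, nc)
  B1 <- obj$B1
  B2 <- obj$B2
  theta <- block_model_params(
    obj$alpha1, obj$alpha2, as_mat(obj$Pi, B1, B2),
    density_spec(obj$nu0$family, obj$nu0$mean, obj$nu0$var),
    as_mat(obj$mu, B1, B2), as_mat(obj$sigma2, B1, B2))
  beta1 <- as_mat(obj$beta1, length(obj$row_ids), B1)
  beta2 <- as_mat(obj$beta2, length(obj$col_ids), B2)
  Z1 <- as.integer(obj$Z1_hat)
  Z2 <- as.integer(obj$Z2_hat)
  names(Z1) <- obj$row_ids
  names(Z2) <- obj$col_ids
  opts <- do.call(fit_options, obj$opts[c("B1", "B2", "fix_null",
                                          "max_outer_iter", "elbo_rel_tol",
                                          "inner_iter", "n_restarts",
                                          "seed", "sigma0")])
  structure(list(theta_hat = theta,
                 state = variational_state(beta1, beta2),
                 Z1_hat = Z1, Z2_hat = Z2,
                 elbo_trace = as.numeric(obj$elbo_trace),
                 converged = isTRUE(obj$converged),
                 icl = if (is.null(obj$icl)) NA_real_ else obj$icl,
                 opts = opts, row_ids = obj$row_ids,
                 col_ids = obj$col_ids),
            class = "bnsbm_fit")
}
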