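#' Build a random planted network (Gaussian graphical model)
#'
#' Ground truth for validating the inference pipeline. `n_edges` unordered
#' gene pairs are chosen uniformly without replacement and given
#' off-diagonal precision entries of magnitude `strength` with random signs.
#' Each diagonal entry is set to the absolute row sum of its off-diagonals
#' plus 0.1, which makes the precision matrix strictly diagonally dominant
#' and hence positive definite, and the matrix is then rescaled to unit
#' diagonal so off-diagonals read directly as (negated) partial correlations.
#' Conditional independence holds exactly for every non-edge pair.
#'
#' @param p Number of genes (>= 2).
#' @param n_edges Number of planted edges, at most p(p-1)/2.
#' @param strength Off-diagonal precision magnitude before rescaling, in (0, 1).
#' @param seed Integer seed; construction is deterministic given the seed.
#' @return A `planted_network`: list with `p`, `gene_ids`, `omega` (p x p
#'   precision matrix) and `edges`, a tibble of `gene_a`, `gene_b`,
#'   `partial_correlation` (the realized partial correlation
#'   \eqn{-\omega_{ij}} after unit-diagonal scaling).
#' @export
make_planted_network <- function(p, n_edges, strength = 0.5, seed = 1L) {
  p <- as.integer(p)
  n_edges <- as.integer(n_edges)
  if (p < 2) abort("`p` must be at least 2.")
  max_edges <- p * (p - 1L) / 2L
  if (n_edges < 0 || n_edges > max_edges) {
    abort(paste0("`n_edges` must lie in [0, ", max_edges, "]."))
  }
  if (strength <= 0 || strength >= 1) abort("`strength` must lie in (0, 1).")
  pairs <- pair_index(max(p, 2L))
  omega <- matrix(0, p, p)
  withr::with_seed(seed, {
    chosen <- if (n_edges > 0) sort(sample.int(max_edges, n_edges)) else integer(0)
    signs <- if (n_edges > 0) sample(c(-1, 1), n_edges, replace = TRUE) else numeric(0)
  })
  for (e in seq_along(chosen)) {
    i <- pairs$i[chosen[e]]; j <- pairs$j[chosen[e]]
    omega[i, j] <- omega[j, i] <- signs[e] * strength
  }
  diag(omega) <- rowSums(abs(omega)) + 0.1
  d <- diag(omega)
  omega <- omega / sqrt(outer(d, d))
  gene_ids <- paste0("g", seq_len(p))
  dimnames(omega) <- list(gene_ids, gene_ids)
  edges <- tibble::tibble(
    gene_a = gene_ids[pairs$i[chosen]],
    gene_b = gene_ids[pairs$j[chosen]],
    partial_correlation = -omega[cbind(pairs$i[chosen], pairs$j[chosen])]
  )
  structure(
    list(p = p, gene_ids = gene_ids, omega = omega, edges = edges),
    class = "planted_network"
  )
}

#' @export
print.planted_network <- function(x, ...) {
  cat("<planted_network> ", x$p, " genes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Simulate expression data from a planted network
#'
#' Draws `n` independent condition profiles from the multivariate normal with
#' precision matrix `net$omega` (covariance its inverse), so the planted
#' edges are exactly the conditional dependencies the regression-based
#' scorers target. Genes in rows, conditions in columns, ids `g1..gp` /
#' `c1..cn`.
#'
#' @param net A `planted_network`.
#' @param n Number of conditions (>= 4).
#' @param seed Integer seed; output is bitwise reproducible.
#' @return An unstandardized `expression_matrix`.
#' @export
simulate_expression <- function(net, n, seed = 1L) {
  stopifnot(inherits(net, "planted_network"))
  n <- as.integer(n)
  if (n < 4) abort("`n` must be at least 4 conditions.")
  sigma <- solve(net$omega)
  u <- chol(sigma)  # sigma = u'u
  vals <- withr::with_seed(seed, {
    z <- matrix(rnorm(net$p * n), nrow = net$p, ncol = n)
    crossprod(u, z)  # u'z has covariance u'u = sigma per column
  })
  dimnames(vals) <- list(net$gene_ids, paste0("c", seq_len(n)))
  expression_matrix(vals, standardized = FALSE)
}

#' Write a simulated dataset to disk
#'
#' Writes the expression matrix in the exact CSV dialect read by
#' [read_expression_matrix()] plus the ground-truth edge list
#' (`gene_a,gene_b,partial_correlation`), e.g. for benchmarking external
#' tools.
#'
#' @param net A `planted_network`.
#' @param x The matching `expression_matrix` (e.g. from
#'   [simulate_expression()]).
#' @param outdir Output directory, created if needed.
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_simulation <- function(net, x, outdir) {
  stopifnot(inherits(net, "planted_network"), inherits(x, "expression_matrix"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  expr_path <- file.path(outdir, "expression.csv")
  truth_path <- file.path(outdir, "truth_edges.csv")
  df <- tibble::as_tibble(x$values, rownames = "gene")
  readr::write_csv(df, expr_path, progress = FALSE)
  readr::write_csv(net$edges, truth_path, progress = FALSE)
  invisible(c(expression = expr_path, truth = truth_path))
}
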