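#' Scoring parameters
#'
#' Bundles the tuning parameters of the regression-based scorers: the number
#' of principal components `pcr_k`, the number of latent PLS components
#' `pls_v`, and the ridge penalty `ridge_lambda`. The defaults (3, 3, 1)
#' follow the reference network-scoring lineage these estimators come from.
#'
#' @param pcr_k Positive integer, components used by the PCR scorer.
#' @param pls_v Positive integer, latent components used by the PLS scorer.
#' @param ridge_lambda Non-negative ridge penalty.
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(pcr_k = 3L, pls_v = 3L, ridge_lambda = 1.0) {
  pcr_k <- as.integer(pcr_k)
  pls_v <- as.integer(pls_v)
  if (is.na(pcr_k) || pcr_k < 1) abort("`pcr_k` must be a positive integer.")
  if (is.na(pls_v) || pls_v < 1) abort("`pls_v` must be a positive integer.")
  if (!is.finite(ridge_lambda) || ridge_lambda < 0) {
    abort("`ridge_lambda` must be a non-negative number.")
  }
  structure(
    list(pcr_k = pcr_k, pls_v = pls_v, ridge_lambda = ridge_lambda),
    class = "scoring_params"
  )
}

scorer_labels <- c("correlation", "pcr", "pls", "ridge")

new_edge_scores <- function(scores, gene_ids, method) {
  dimnames(scores) <- list(gene_ids, gene_ids)
  structure(
    list(gene_ids = gene_ids, scores = scores, method = method),
    class = "edge_scores"
  )
}

#' @export
print.edge_scores <- function(x, ...) {
  cat("<edge_scores> method = ", x$method, ", ", length(x$gene_ids),
      " genes\n", sep = "")
  invisible(x)
}

#' Turn a score matrix into a tidy per-edge tibble
#'
#' @param x An `edge_scores` object.
#' @param ... Unused.
#' @return A tibble with one row per unordered gene pair: `gene_a`, `gene_b`,
#'   `score`, `method`.
#' @method as_tibble edge_scores
#' @export
as_tibble.edge_scores <- function(x, ...) {
  pairs <- pair_index(length(x$gene_ids))
  tibble::tibble(
    gene_a = x$gene_ids[pairs$i],
    gene_b = x$gene_ids[pairs$j],
    score = upper_pairs(x$scores),
    method = x$method
  )
}

check_standardized <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!x$standardized) {
    abort("Expression matrix must be standardized first; see standardize().")
  }
  invisible(x)
}

#' Symmetrize a directional score matrix
#'
#' The regression-based scorers produce one coefficient per ordered pair
#' (gene k in the model for target g, and vice versa); a single per-pair
#' connectivity score is their arithmetic mean. The diagonal is set to 0 and
#' never reported as an edge.
#'
#' @param directional A square numeric matrix with finite entries.
#' @return A symmetric matrix with zero diagonal.
#' @export
symmetrize_scores <- function(directional) {
  if (!is.matrix(directional) || nrow(directional) != ncol(directional)) {
    abort("`directional` must be a square matrix.")
  }
  if (any(!is.finite(directional))) abort("`directional` contains non-finite entries.")
  s <- (directional + t(directional)) / 2
  s <- (s + t(s)) / 2  # force bitwise symmetry
  diag(s) <- 0
  s
}

# -- internal scorers on a plain standardized genes x conditions matrix -------

score_matrix_correlation <- function(v) {
  g <- tcrossprod(v)                       # x_i' x_k across conditions
  d <- sqrt(diag(g))
  s <- g / outer(d, d)
  symmetrize_scores(s)
}

score_matrix_pcr <- function(v, k) {
  p <- nrow(v); n <- ncol(v)
  if (k > p - 1) abort(paste0("`pcr_k` must be at most p - 1 = ", p - 1, "."))
  g <- tcrossprod(v)
  out <- matrix(0, p, p)
  warned <- FALSE
  for (gi in seq_len(p)) {
    gp <- g[-gi, -gi, drop = FALSE]        # X' X of the leave-one-out design
    gy <- g[-gi, gi]
    ev <- eigen(gp / (n - 1), symmetric = TRUE)
    vk <- ev$vectors[, seq_len(k), drop = FALSE]
    # deterministic eigenvector orientation: largest-|entry| coordinate positive
    for (c0 in seq_len(k)) {
      if (vk[which.max(abs(vk[, c0])), c0] < 0) vk[, c0] <- -vk[, c0]
    }
    ttt <- crossprod(vk, gp %*% vk)        # T'T of the component scores
    tty <- crossprod(vk, gy)               # T'y
    beta <- tryCatch(
      solve(ttt, tty),
      error = function(e) {
        if (!warned) {
          warn("Rank-deficient component scores; using least-squares pseudo-solution.")
          warned <<- TRUE
        }
        MASS::ginv(ttt) %*% tty
      }
    )
    out[gi, -gi] <- as.vector(vk %*% beta) # back-transform to per-gene scores
  }
  symmetrize_scores(out)
}

score_matrix_pls <- function(v, vcomp) {
  p <- nrow(v)
  if (vcomp > min(p - 1, ncol(v))) {
    abort(paste0("`pls_v` must be at most min(p - 1, n) = ", min(p - 1, ncol(v)), "."))
  }
  out <- matrix(0, p, p)
  warned <- FALSE
  for (gi in seq_len(p)) {
    y <- v[gi, ]
    xl <- t(v[-gi, , drop = FALSE])        # n x (p-1) predictor block
    acc <- numeric(p - 1)
    for (l in seq_len(vcomp)) {
      cw <- crossprod(xl, y)               # direction weights, X^(l)' x_i
      nw <- sqrt(sum(cw^2))
      if (nw < 1e-10) {
        if (!warned) {
          warn("PLS components capped at predictor-block rank.")
          warned <- TRUE
        }
        break
      }
      cw <- cw / nw                        # normalized c_ik^(l)
      tl <- drop(xl %*% cw)                # latent component t_i^(l)
      tt <- sum(tl^2)
      if (tt < 1e-20) break
      beta <- sum(tl * y) / tt             # (t't)^-1 t' x_i
      acc <- acc + beta * cw
      xl <- xl - tcrossprod(tl) %*% xl / tt  # deflate the predictor block
    }
    out[gi, -gi] <- acc
  }
  symmetrize_scores(out)
}

score_matrix_ridge <- function(v, lambda) {
  p <- nrow(v)
  g <- tcrossprod(v)
  out <- matrix(0, p, p)
  for (gi in seq_len(p)) {
    a <- g[-gi, -gi, drop = FALSE]
    diag(a) <- diag(a) + lambda
    coef <- tryCatch(
      solve(a, g[-gi, gi]),
      error = function(e) {
        abort(paste0(
          "Singular leave-one-out design for gene '", rownames(v)[gi],
          "' with lambda = ", lambda, "; use a positive ridge penalty."
        ))
      }
    )
    out[gi, -gi] <- coef
  }
  symmetrize_scores(out)
}

score_matrix <- function(v, method, params) {
  switch(method,
    correlation = score_matrix_correlation(v),
    pcr = score_matrix_pcr(v, params$pcr_k),
    pls = score_matrix_pls(v, params$pls_v),
    ridge = score_matrix_ridge(v, params$ridge_lambda),
    abort(paste0("Unknown scoring method: ", method))
  )
}

#' Correlation connectivity scores
#'
#' For standardized gene rows the score of genes i and k is
#' \eqn{S_{ik} = x_i^T x_k / \sqrt{(x_i^T x_i)(x_k^T x_k)}}, i.e. their
#' Pearson correlation across conditions; all off-diagonal scores lie in
#' \eqn{[-1, 1]}.
#'
#' @param x A standardized `expression_matrix`.
#' @return An `edge_scores` object (symmetric p x p score matrix, zero
#'   diagonal); use [as_tibble.edge_scores()] for the per-pair tibble.
#' @family connectivity scorers
#' @export
score_correlation <- function(x) {
  check_standardized(x)
  new_edge_scores(score_matrix_correlation(x$values), x$gene_ids, "correlation")
}

#' Principal component regression connectivity scores
#'
#' Each gene in turn is regressed on the leading `k` principal-component
#' scores of the remaining genes (components from the eigendecomposition of
#' the leave-one-out covariance, ordered by descending eigenvalue), and the
#' latent coefficients are back-transformed through the eigenvector matrix to
#' one coefficient per predictor gene. The two directional coefficients of
#' each pair are averaged ([symmetrize_scores()]). With `k = p - 1` on a
#' full-rank design this reduces to ordinary least squares.
#'
#' @param x A standardized `expression_matrix`.
#' @param k Number of principal components, `1 <= k <= p - 1`.
#' @return An `edge_scores` object.
#' @family connectivity scorers
#' @export
score_pcr <- function(x, k = 3L) {
  check_standardized(x)
  k <- as.integer(k)
  if (is.na(k) || k < 1) abort("`k` must be a positive integer.")
  new_edge_scores(score_matrix_pcr(x$values, k), x$gene_ids, "pcr")
}

#' Partial least squares connectivity scores
#'
#' For each target gene, `v` latent components are extracted from the
#' remaining genes by the univariate NIPALS recursion: direction weights
#' proportional to the covariance of each predictor with the target
#' (normalized to unit length), the latent component as the weighted
#' predictor sum, a one-dimensional regression of the target on the
#' component, then deflation of the predictor block. The per-gene score sums
#' the weight-times-coefficient contribution over components; the two
#' directional scores of each pair are averaged.
#'
#' @param x A standardized `expression_matrix`.
#' @param v Number of latent components, `1 <= v <= min(p - 1, n)`.
#' @return An `edge_scores` object.
#' @family connectivity scorers
#' @export
score_pls <- function(x, v = 3L) {
  check_standardized(x)
  v <- as.integer(v)
  if (is.na(v) || v < 1) abort("`v` must be a positive integer.")
  new_edge_scores(score_matrix_pls(x$values, v), x$gene_ids, "pls")
}

#' Ridge regression connectivity scores
#'
#' Each gene is regressed on all remaining genes with an L2 penalty:
#' \eqn{s_g = (\tilde X_g^T \tilde X_g + \lambda I)^{-1} \tilde X_g^T x_g},
#' where \eqn{\tilde X_g} is the leave-one-out design. The penalty
#' stabilizes the fit when genes outnumber conditions; `lambda = 0` (only
#' valid on full-rank designs) recovers ordinary least squares. Directional
#' coefficients are averaged per pair.
#'
#' @param x A standardized `expression_matrix`.
#' @param lambda Non-negative ridge penalty.
#' @return An `edge_scores` object.
#' @family connectivity scorers
#' @export
score_ridge <- function(x, lambda = 1.0) {
  check_standardized(x)
  if (!is.finite(lambda) || lambda < 0) abort("`lambda` must be non-negative.")
  new_edge_scores(score_matrix_ridge(x$values, lambda), x$gene_ids, "ridge")
}
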