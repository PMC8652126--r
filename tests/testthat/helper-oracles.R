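# Independent oracles coded from the textbook definitions, kept deliberately
# naive (explicit loops, lm() fits) so they share no code path with the
# package's vectorized implementations.

# random standardized expression matrix
random_standardized <- function(p, n, seed) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(p * n), p, n,
                dimnames = list(paste0("g", seq_len(p)), paste0("c", seq_len(n))))
  })
  standardize(expression_matrix(m))
}

# rows mutually orthogonal, mean 0, sd 1: orthogonal polynomial basis
orthogonal_rows <- function(p, n) {
  stopifnot(p < n)
  b <- stats::poly(seq_len(n), degree = p)       # orthonormal, mean-zero columns
  v <- t(b) * sqrt(n - 1)                        # unit sample sd rows
  dimnames(v) <- list(paste0("g", seq_len(p)), paste0("c", seq_len(n)))
  expression_matrix(v, standardized = TRUE)
}

# textbook Pearson correlation from the covariance definition
oracle_pearson <- function(v) {
  p <- nrow(v)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (k in seq_len(p)) {
      if (i == k) next
      xi <- v[i, ] - mean(v[i, ])
      xk <- v[k, ] - mean(v[k, ])
      out[i, k] <- sum(xi * xk) / sqrt(sum(xi^2) * sum(xk^2))
    }
  }
  out
}

# per-target OLS coefficients via the normal equations, then averaged per pair
oracle_ols <- function(v) {
  p <- nrow(v)
  out <- matrix(0, p, p)
  for (g in seq_len(p)) {
    x <- t(v[-g, , drop = FALSE])
    y <- v[g, ]
    beta <- solve(t(x) %*% x) %*% (t(x) %*% y)
    out[g, -g] <- beta
  }
  sym <- (out + t(out)) / 2
  diag(sym) <- 0
  sym
}

# ridge normal equations, direct dense solve
oracle_ridge <- function(v, lambda) {
  p <- nrow(v)
  out <- matrix(0, p, p)
  for (g in seq_len(p)) {
    x <- t(v[-g, , drop = FALSE])
    y <- v[g, ]
    out[g, -g] <- solve(t(x) %*% x + lambda * diag(p - 1), t(x) %*% y)
  }
  sym <- (out + t(out)) / 2
  diag(sym) <- 0
  sym
}

# literal transcription of the PLS scoring recursion, using lm() for the
# latent regression and per-column lm() residuals for deflation
oracle_pls <- function(v, vcomp) {
  p <- nrow(v)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) {
    y <- v[i, ]
    x <- t(v[-i, , drop = FALSE])
    s <- numeric(p - 1)
    for (l in seq_len(vcomp)) {
      cw <- as.vector(t(x) %*% y)
      cw <- cw / sqrt(sum(cw * cw))
      tl <- as.vector(x %*% cw)                  # t_i^(l) = sum_k c_ik X_k
      beta <- unname(coef(lm(y ~ tl - 1)))       # (t't)^-1 t' x_i
      s <- s + beta * cw
      x <- apply(x, 2, function(col) residuals(lm(col ~ tl - 1)))
    }
    out[i, -i] <- s
  }
  sym <- (out + t(out)) / 2
  diag(sym) <- 0
  sym
}

expect_symmetric <- function(m) {
  expect_identical(m, t(m))
  expect_identical(unname(diag(m)), rep(0, nrow(m)))
}
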