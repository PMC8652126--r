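#' Fit a robust empirical null to edge t-statistics
#'
#' The observed t-statistics are modelled as a two-component mixture
#' \eqn{f = \eta_0 f_0 + (1 - \eta_0) f_1} with a central normal null
#' \eqn{f_0 = N(0, \sigma_0^2)}. The null scale is the robust half-normal
#' estimate \eqn{\sigma_0 = median(|t|) / \Phi^{-1}(0.75)}, which ignores the
#' non-null tail as long as true edges are a minority. The null proportion is
#' \eqn{\eta_0 = \min(1,\, 2\,\overline{1\{p > 0.5\}})} from the provisional
#' p-values under \eqn{N(0, \sigma_0^2)}: under a pure null half the p-values
#' exceed 0.5, so doubling that fraction estimates the null mass.
#'
#' With fewer than 50 finite t-values the estimate is unstable and the fit
#' falls back to `sigma0 = 1`, `eta0 = 1` with a warning, so toy inputs never
#' crash downstream.
#'
#' @param t_values Numeric vector of t-statistics (one per edge).
#' @return A `null_model`: list with `sigma0`, `eta0`, `n_stats`.
#' @export
fit_empirical_null <- function(t_values) {
  t_values <- t_values[is.finite(t_values)]
  n <- length(t_values)
  if (n < 50) {
    warn(paste0(
      "Only ", n, " finite t-statistics; falling back to sigma0 = 1, eta0 = 1."
    ))
    return(structure(list(sigma0 = 1, eta0 = 1, n_stats = n),
                     class = "null_model"))
  }
  sigma0 <- median(abs(t_values)) / qnorm(0.75)
  if (sigma0 == 0) {
    abort("Degenerate null: median |t| is 0 (all t-statistics identical?).")
  }
  p_prov <- 2 * pnorm(abs(t_values) / sigma0, lower.tail = FALSE)
  eta0 <- min(1, 2 * mean(p_prov > 0.5))
  structure(list(sigma0 = sigma0, eta0 = eta0, n_stats = n),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat("<null_model> sigma0 = ", signif(x$sigma0, 4),
      ", eta0 = ", signif(x$eta0, 4),
      ", fitted on ", x$n_stats, " t-statistics\n", sep = "")
  invisible(x)
}

#' Two-sided p-values under the fitted null
#'
#' \eqn{p = 2 (1 - \Phi(|t| / \sigma_0))}; monotone non-increasing in |t|.
#' Two-sided because negative scores (repression) are as meaningful as
#' positive ones.
#'
#' @param t_values Numeric vector of t-statistics.
#' @param null A `null_model` from [fit_empirical_null()].
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
p_values <- function(t_values, null) {
  stopifnot(inherits(null, "null_model"))
  if (null$sigma0 <= 0) abort("`null$sigma0` must be positive.")
  2 * pnorm(abs(t_values) / null$sigma0, lower.tail = FALSE)
}

#' Tail-area false discovery rates
#'
#' The tail-area Fdr of edge r (p-values sorted ascending) is
#' \eqn{\min(1, \eta_0\, p_{(r)} N / r)}, made monotone by the step-up
#' cumulative minimum from the largest p-value downward — the
#' Benjamini-Hochberg q-value scaled by the estimated null proportion
#' \eqn{\eta_0}. Results are returned in the original edge order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param eta0 Null proportion in \[0, 1\].
#' @return Numeric vector of fdr values in \[0, 1\], same order as `p`.
#' @export
fdr_values <- function(p, eta0 = 1) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  if (!is.finite(eta0) || eta0 < 0 || eta0 > 1) abort("`eta0` must lie in [0, 1].")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  f <- pmin(1, eta0 * p[o] * n / seq_len(n))
  f <- rev(cummin(rev(f)))
  out <- numeric(n)
  out[o] <- f
  out
}
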