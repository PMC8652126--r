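#' Fisher's combined statistic per edge
#'
#' Combines one p-value per method into
#' \eqn{F_w = -2 \sum_m w_m \ln p_m} (default weights all 1, the plain
#' Fisher combination \eqn{F_w = -2\ln(p_1 p_2 \cdots p_m)}). Computed as a
#' sum of logs, never a product, so hundreds of tiny p-values cannot
#' underflow. Zeros are floored at 1e-300 with a warning.
#'
#' @param ... Equal-length numeric vectors of p-values, one per method
#'   (at least two).
#' @param weights Optional non-negative per-method weights; default all 1.
#' @return Numeric vector of non-negative Fisher statistics.
#' @export
fisher_combine <- function(..., weights = NULL) {
  ps <- list(...)
  if (length(ps) < 2) abort("Fisher combination needs p-values from at least 2 methods.")
  lens <- lengths(ps)
  if (length(unique(lens)) != 1) abort("All p-value vectors must have equal length.")
  pm <- do.call(cbind, ps)
  if (any(pm < 0 | pm > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  if (any(pm == 0, na.rm = TRUE)) {
    warn("Zero p-value(s) floored at 1e-300 before taking logs.")
    pm[pm == 0] <- 1e-300
  }
  if (is.null(weights)) weights <- rep(1, ncol(pm))
  if (length(weights) != ncol(pm) || any(weights < 0)) {
    abort("`weights` must be one non-negative weight per method.")
  }
  drop(-2 * (log(pm) %*% weights))
}

#' Combined p-value for a Fisher statistic
#'
#' Under independent uniform per-method p-values, \eqn{F_w} is chi-square
#' with \eqn{2m} degrees of freedom (8 for the default four methods); the
#' combined p-value is the upper-tail probability. The four methods share
#' one dataset, so true independence does not hold and the combination is
#' somewhat anti-conservative — the BH adjustment in [select_significant()]
#' is the default guard.
#'
#' @param fw Numeric vector of non-negative Fisher statistics.
#' @param n_methods Number of combined methods m (default 4, i.e. 8 df).
#' @return Numeric vector of combined p-values, strictly decreasing in `fw`.
#' @export
combined_p <- function(fw, n_methods = 4) {
  if (any(fw < 0, na.rm = TRUE)) abort("Fisher statistics must be non-negative.")
  if (n_methods < 1) abort("`n_methods` must be at least 1.")
  pchisq(fw, df = 2 * n_methods, lower.tail = FALSE)
}

#' Assemble the consensus edge table
#'
#' Joins the per-method p-values, computes the Fisher statistic, its combined
#' p-value, BH-adjusted q-value, and the significance flag at level `alpha`.
#'
#' @param method_p Named list of per-method edge tibbles (each with `gene_a`,
#'   `gene_b`, `p` in identical pair order, as produced by the pipeline).
#' @param alpha Significance level in (0, 1).
#' @param weights Optional per-method weights passed to [fisher_combine()].
#' @return A tibble with `gene_a`, `gene_b`, one `p_<method>` column per
#'   method, `Fw`, `p_combined`, `q_combined`, `significant`.
#' @export
consensus_table <- function(method_p, alpha = 0.05, weights = NULL) {
  if (length(method_p) < 2) {
    abort("Consensus needs p-values from at least 2 methods (Fisher combination of one p-value is degenerate).")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  first <- method_p[[1]]
  for (m in method_p[-1]) {
    if (!identical(m$gene_a, first$gene_a) || !identical(m$gene_b, first$gene_b)) {
      abort("Per-method tables must list the same gene pairs in the same order.")
    }
  }
  short <- sub("^correlation$", "cor", names(method_p))
  out <- tibble::tibble(gene_a = first$gene_a, gene_b = first$gene_b)
  for (i in seq_along(method_p)) out[[paste0("p_", short[i])]] <- method_p[[i]]$p
  fw <- do.call(fisher_combine, c(unname(purrr::map(method_p, "p")),
                                  list(weights = weights)))
  out$Fw <- fw
  out$p_combined <- combined_p(fw, n_methods = length(method_p))
  out$q_combined <- p.adjust(out$p_combined, method = "BH")
  out$significant <- out$q_combined <= alpha
  out
}

#' Select significant consensus edges
#'
#' With `adjust = "bh"` (default) the Benjamini-Hochberg step-up is applied
#' to the combined p-values across all edges and pairs with q <= alpha are
#' kept; with `adjust = "none"` the raw combined p-value is thresholded.
#' Output is sorted by descending Fisher statistic. Lowering `alpha` never
#' adds edges.
#'
#' @param table A consensus tibble from [consensus_table()] (or `tidy()` of a
#'   [consensus_grn()] fit).
#' @param alpha Significance level in (0, 1).
#' @param adjust `"bh"` or `"none"`.
#' @return The filtered, sorted tibble (with `q_combined` and `significant`
#'   recomputed for the chosen rule).
#' @export
select_significant <- function(table, alpha = 0.05, adjust = c("bh", "none")) {
  adjust <- match.arg(adjust)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  table <- tibble::as_tibble(table)
  if (adjust == "bh") {
    table$q_combined <- p.adjust(table$p_combined, method = "BH")
    keep <- table$q_combined <= alpha
  } else {
    keep <- table$p_combined <= alpha
  }
  table$significant <- keep
  out <- table[keep, , drop = FALSE]
  out[order(-out$Fw, out$gene_a, out$gene_b, method = "radix"), ]
}
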