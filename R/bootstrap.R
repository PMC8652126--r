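#' Bootstrap replicate scores for every edge
#'
#' Draws `B` bootstrap resamples of the conditions (columns, with
#' replacement, full size n), re-standardizes the gene rows within each
#' resample, applies the chosen scorer, symmetrizes, and records the
#' unordered-pair scores. Resampling conditions is the statistically coherent
#' unit here: every edge score is a statistic computed across conditions.
#' A resample that leaves some gene constant (so it cannot be standardized)
#' is redrawn, up to 100 times per replicate.
#'
#' @param x A standardized `expression_matrix`.
#' @param method One of `"correlation"`, `"pcr"`, `"pls"`, `"ridge"`.
#' @param params A [scoring_params()] object.
#' @param B Number of bootstrap samples (>= 2).
#' @param seed Integer seed; identical inputs and seed give bitwise-identical
#'   output.
#' @return A `B` x `p(p-1)/2` numeric matrix of replicate scores, with
#'   attributes `gene_ids`, `method`, `n` (condition count) and `seed`.
#'   Columns follow [pair_index()] order.
#' @export
bootstrap_scores <- function(x, method = scorer_labels, params = scoring_params(),
                             B = 100L, seed = 1L) {
  check_standardized(x)
  method <- match.arg(method)
  B <- as.integer(B)
  if (is.na(B) || B < 2) abort("`B` must be an integer >= 2 (the SE needs B - 1 df).")
  v <- x$values
  p <- nrow(v); n <- ncol(v)
  n_edges <- p * (p - 1L) / 2L
  reps <- matrix(NA_real_, B, n_edges)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      ok <- FALSE
      for (try in seq_len(100L)) {
        idx <- sample.int(n, n, replace = TRUE)
        vb <- v[, idx, drop = FALSE]
        sds <- apply(vb, 1, sd)
        if (all(sds > 0)) { ok <- TRUE; break }
      }
      if (!ok) {
        abort(paste0(
          "Replicate ", b, ": 100 redraws all left some gene constant; ",
          "the data have too little variation to bootstrap."
        ))
      }
      vb <- (vb - rowMeans(vb)) / sds
      reps[b, ] <- upper_pairs(score_matrix(vb, method, params))
    }
  })
  structure(reps, gene_ids = x$gene_ids, method = method, n = n, seed = seed)
}

#' Summarize bootstrap replicates per edge
#'
#' Per edge, the bootstrap mean \eqn{\bar s = B^{-1}\sum_j s^{(j)}}, the
#' standard error \eqn{Se = \sqrt{(B-1)^{-1}\sum_j (s^{(j)} - \bar s)^2}},
#' and the t-statistic from [t_statistic()].
#'
#' @param replicates A `B` x edges matrix as returned by
#'   [bootstrap_scores()], or any numeric matrix with replicates in rows.
#' @param n Number of conditions (needed for the correlation t-statistic;
#'   taken from the attribute when present).
#' @param method Scorer label (taken from the attribute when present).
#' @param gene_ids Gene identifiers (attribute fallback likewise).
#' @return A `bootstrap_summary` tibble: one row per unordered pair with
#'   columns `gene_a`, `gene_b`, `mean`, `se`, `t`, plus attributes `method`,
#'   `B`, `n`.
#' @export
summarize_bootstrap <- function(replicates, n = attr(replicates, "n"),
                                method = attr(replicates, "method"),
                                gene_ids = attr(replicates, "gene_ids")) {
  if (!is.matrix(replicates) || nrow(replicates) < 2) {
    abort("`replicates` must be a matrix with B >= 2 rows (SE needs B - 1 df).")
  }
  if (is.null(n) || is.null(method)) {
    abort("`n` and `method` are required (attributes or arguments).")
  }
  B <- nrow(replicates)
  s_bar <- colMeans(replicates)
  se <- sqrt(colSums(sweep(replicates, 2, s_bar)^2) / (B - 1))
  t <- t_statistic(s_bar, se, n, method)
  if (is.null(gene_ids)) {
    p <- (1 + sqrt(1 + 8 * ncol(replicates))) / 2
    gene_ids <- paste0("g", seq_len(round(p)))
  }
  pairs <- pair_index(length(gene_ids))
  out <- tibble::tibble(
    gene_a = gene_ids[pairs$i],
    gene_b = gene_ids[pairs$j],
    mean = s_bar,
    se = se,
    t = t
  )
  structure(out, method = method, B = B, n = n,
            class = c("bootstrap_summary", class(out)))
}

#' Per-edge t-statistic
#'
#' For the regression-based scorers the statistic is the bootstrap mean over
#' its bootstrap standard error, \eqn{t = \bar s / Se}. For the correlation
#' scorer it is the usual correlation test statistic with n - 2 degrees of
#' freedom evaluated at the bootstrap mean,
#' \eqn{t = \bar s \sqrt{n - 2} / \sqrt{1 - \bar s^2}}.
#'
#' Degenerate cases are flagged with a warning: `se = 0` with a non-zero mean
#' yields a signed sentinel of \eqn{\pm 10^{12}}; a correlation mean at or
#' beyond \eqn{\pm 1} is clamped to \eqn{\pm(1 - 10^{-12})}.
#'
#' @param s_bar Numeric vector of bootstrap means.
#' @param se Numeric vector of bootstrap standard errors (ignored by the
#'   correlation branch).
#' @param n Number of conditions.
#' @param method Scorer label; `"correlation"` selects the n - 2 df form.
#' @return Numeric vector of t-statistics.
#' @export
t_statistic <- function(s_bar, se, n, method) {
  if (method == "correlation") {
    if (any(abs(s_bar) >= 1)) {
      warn("Correlation bootstrap mean at |s| >= 1; clamped to 1 - 1e-12.")
      s_bar <- pmin(pmax(s_bar, -(1 - 1e-12)), 1 - 1e-12)
    }
    s_bar * sqrt(n - 2) / sqrt(1 - s_bar^2)
  } else {
    if (any(se < 0)) abort("Negative standard error.")
    t <- ifelse(se > 0, s_bar / se, 0)
    zero_se <- se == 0 & s_bar != 0
    if (any(zero_se)) {
      warn("Zero bootstrap SE with non-zero mean; t set to signed 1e12 sentinel.")
      t[zero_se] <- sign(s_bar[zero_se]) * 1e12
    }
    t
  }
}
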