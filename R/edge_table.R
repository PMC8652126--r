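#' Unordered gene-pair index
#'
#' Enumerates the p(p-1)/2 unordered pairs in the order used throughout the
#' package: the column-major upper triangle, so that for any p x p matrix `m`,
#' `m[upper.tri(m)]` lines up with these rows.
#'
#' @param p Number of genes (>= 2).
#' @return A tibble with integer columns `i`, `j` (`i < j`).
#' @export
pair_index <- function(p) {
  stopifnot(p >= 2)
  m <- matrix(FALSE, p, p)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
}

upper_pairs <- function(m) m[upper.tri(m)]

validate_edge_table <- function(t) {
  needed <- c("gene_a", "gene_b", "score", "t", "p", "fdr")
  missing <- setdiff(needed, names(t))
  if (length(missing) > 0) {
    abort(paste0("Edge table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(t$gene_a == t$gene_b)) abort("Edge table contains self-pairs.")
  key <- paste(t$gene_a, t$gene_b, sep = "\r")
  if (anyDuplicated(key)) abort("Edge table contains duplicated gene pairs.")
  if (any(t$p < 0 | t$p > 1, na.rm = TRUE)) abort("p-values outside [0, 1].")
  if (any(t$fdr < 0 | t$fdr > 1, na.rm = TRUE)) abort("fdr values outside [0, 1].")
  invisible(t)
}

#' Write an edge table to CSV
#'
#' Writes the per-edge results of one scoring method (or the consensus) as a
#' CSV with columns `gene_a,gene_b,score,t,p,fdr`, loadable in Cytoscape as an
#' edge-attribute table. Rows are ordered by descending absolute score, ties
#' broken lexically by (`gene_a`, `gene_b`) so output is deterministic.
#' Numbers are written with full round-trip precision.
#'
#' @param t A data frame with columns `gene_a`, `gene_b`, `score`, `t`, `p`,
#'   `fdr` (extra columns are dropped).
#' @param path Output file path.
#' @return The written tibble, invisibly.
#' @seealso [read_edge_table()]
#' @export
write_edge_table <- function(t, path) {
  t <- tibble::as_tibble(t)[, c("gene_a", "gene_b", "score", "t", "p", "fdr")]
  validate_edge_table(t)
  ord <- order(-abs(t$score), t$gene_a, t$gene_b, method = "radix")
  readr::write_csv(t[ord, ], path, progress = FALSE)
  invisible(t[ord, ])
}

#' Read an edge table written by [write_edge_table()]
#'
#' @param path Path to the CSV.
#' @return A tibble with columns `gene_a`, `gene_b`, `score`, `t`, `p`, `fdr`.
#' @export
read_edge_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  t <- readr::read_csv(
    path,
    col_types = readr::cols(
      gene_a = readr::col_character(), gene_b = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  validate_edge_table(t)
  t
}
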