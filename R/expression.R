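#' Construct an expression matrix object
#'
#' An `expression_matrix` holds a genes-by-conditions matrix of finite
#' expression values together with unique gene and condition identifiers.
#' It is the sole input of the network-inference pipeline.
#'
#' @param values Numeric matrix, genes in rows and conditions in columns.
#'   Row names are taken as gene identifiers and column names as condition
#'   identifiers; both must be present and unique.
#' @param standardized Logical; `TRUE` only if every gene row already has
#'   mean 0 and sample standard deviation 1.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `gene_ids`, `condition_ids`, `values` and `standardized`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values, standardized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x conditions).")
  }
  gene_ids <- rownames(values)
  condition_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(condition_ids)) {
    abort("`values` must have row names (gene ids) and column names (condition ids).")
  }
  x <- structure(
    list(
      gene_ids = gene_ids,
      condition_ids = condition_ids,
      values = values,
      standardized = isTRUE(standardized)
    ),
    class = "expression_matrix"
  )
  validate_expression_matrix(x)
}

#' Validate an expression matrix
#'
#' Checks the structural invariants: unique identifiers, finite values,
#' at least 4 conditions (the correlation t-statistic uses n - 2 degrees of
#' freedom and the bootstrap needs variation), and — when flagged as
#' standardized — row means of 0 and sample standard deviations of 1.
#'
#' @param x An `expression_matrix`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_expression_matrix <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  dup_g <- unique(x$gene_ids[duplicated(x$gene_ids)])
  if (length(dup_g) > 0) {
    abort(paste0("Duplicate gene id(s): ", paste(dup_g, collapse = ", ")))
  }
  dup_c <- unique(x$condition_ids[duplicated(x$condition_ids)])
  if (length(dup_c) > 0) {
    abort(paste0("Duplicate condition id(s): ", paste(dup_c, collapse = ", ")))
  }
  if (ncol(x$values) < 4) {
    abort(paste0("At least 4 conditions are required; got ", ncol(x$values), "."))
  }
  bad <- which(!is.finite(x$values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0(
      "Non-finite expression value for gene '", x$gene_ids[bad[1, 1]],
      "', condition '", x$condition_ids[bad[1, 2]], "'."
    ))
  }
  if (x$standardized) {
    mu <- rowMeans(x$values)
    sds <- apply(x$values, 1, sd)
    if (any(abs(mu) >= 1e-10) || any(abs(sds - 1) >= 1e-8)) {
      abort("Matrix flagged standardized but rows are not mean-0 / sd-1.")
    }
  }
  x
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(
    "<expression_matrix> ", length(x$gene_ids), " genes x ",
    length(x$condition_ids), " conditions",
    if (x$standardized) " (standardized)", "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a gene-expression matrix from CSV/TSV
#'
#' Expects genes in rows and conditions in columns: a header row of condition
#' identifiers and a first column of gene identifiers. The delimiter is taken
#' from the file extension (`.tsv`/`.txt` mean tab, anything else comma)
#' unless given explicitly. Cells are parsed strictly: any empty or
#' non-numeric cell is an error naming its coordinates, so malformed input
#' never silently becomes `NA`.
#'
#' @param path Path to the file.
#' @param delimiter Optional single character, e.g. `","` or `"\t"`.
#' @return An `expression_matrix` with `standardized = FALSE`; row and column
#'   order are preserved from the file.
#' @examples
#' f <- system.file("extdata", "example_expression.csv", package = "grnconsensus")
#' read_expression_matrix(f)
#' @export
read_expression_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(
    path,
    delim = delimiter, col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  if (ncol(raw) < 2) abort("Input must have a gene-id column plus condition columns.")
  gene_ids <- as.character(raw[[1]])
  condition_ids <- colnames(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  parsed <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(parsed) | cells == "" | is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    val <- cells[i, j]
    abort(paste0(
      "Non-numeric or empty cell at gene row '", gene_ids[i], "', condition '",
      condition_ids[j], "'", if (!is.na(val)) paste0(" (value: \"", val, "\")"), "."
    ))
  }
  dimnames(parsed) <- list(gene_ids, condition_ids)
  expression_matrix(parsed, standardized = FALSE)
}

#' Standardize gene rows
#'
#' Centres and scales every gene row to mean 0 and sample standard deviation 1
#' (denominator n - 1). Standardization is what makes the correlation score
#' equal the Pearson correlation and puts all four scorers on a common scale;
#' it is idempotent.
#'
#' @param x An `expression_matrix`.
#' @param drop_constant If `TRUE`, genes with zero variance are removed (their
#'   names are reported in a warning) instead of raising an error. Correlation
#'   is undefined for constant genes, so they cannot be carried through.
#' @return A standardized `expression_matrix`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 2, 4, byrow = TRUE,
#'             dimnames = list(c("a", "b"), paste0("c", 1:4)))
#' standardize(expression_matrix(m))
#' @export
standardize <- function(x, drop_constant = FALSE) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  sds <- apply(v, 1, sd)
  const <- sds == 0
  if (any(const)) {
    if (drop_constant) {
      warn(paste0(
        "Dropping constant gene(s): ",
        paste(x$gene_ids[const], collapse = ", ")
      ))
      v <- v[!const, , drop = FALSE]
      sds <- sds[!const]
      if (nrow(v) < 2) abort("Fewer than 2 genes remain after dropping constant genes.")
    } else {
      abort(paste0(
        "Constant gene row(s) (sd = 0): ",
        paste(x$gene_ids[const], collapse = ", "),
        ". Use drop_constant = TRUE to remove them."
      ))
    }
  }
  v <- (v - rowMeans(v)) / sds
  expression_matrix(v, standardized = TRUE)
}
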