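#' Construct an expression matrix
#'
#' A thin container for a genes-by-samples matrix of expression intensities,
#' tagged with the scale the values live on: `"log2"` (RMA-style normalized
#' data) or `"original"` (linear intensities, strictly positive). All
#' downstream filter signals are defined relative to this tag.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, or a data
#'   frame whose first column holds gene identifiers.
#' @param scale Either `"log2"` or `"original"`.
#' @param gene_ids,sample_ids Optional identifier vectors; taken from
#'   `dimnames(values)` when absent, and generated (`g1..gN`, `s1..sM`)
#'   otherwise.
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- expression_matrix(matrix(rnorm(20, 7), 5, 4), scale = "log2")
#' n_genes(m)
#' @export
expression_matrix <- function(values, scale = c("log2", "original"),
                              gene_ids = NULL, sample_ids = NULL) {
  scale <- match.arg(scale)
  if (is.data.frame(values)) {
    if (is.null(gene_ids)) gene_ids <- as.character(values[[1]])
    values <- as.matrix(values[, -1, drop = FALSE])
    storage.mode(values) <- "double"
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix or a data frame with a gene-id first column",
         call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  if (nrow(values) < 1L) stop("expression matrix needs at least one gene", call. = FALSE)
  if (ncol(values) < 2L) stop("expression matrix needs at least two samples", call. = FALSE)
  if (anyNA(values)) stop("expression matrix contains missing values", call. = FALSE)
  if (!all(is.finite(values))) stop("expression matrix contains non-finite values", call. = FALSE)
  if (scale == "original" && any(values <= 0)) {
    stop("original-scale expression values must be strictly positive", call. = FALSE)
  }
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicated gene identifiers", call. = FALSE)
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, %s scale\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @rdname expression_matrix
#' @param m An `expr_matrix`.
#' @export
n_genes <- function(m) nrow(m$values)

#' @rdname expression_matrix
#' @export
n_samples <- function(m) ncol(m$values)

#' @rdname expression_matrix
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(m) colnames(m$values)

#' Convert between log2 and original intensity scales
#'
#' `to_original_scale()` applies the base-2 power function elementwise,
#' inverting the log2 transform applied during RMA-style normalization;
#' `to_log2_scale()` is its inverse. Converting a matrix that is already on
#' the requested scale is an error, so pipelines cannot silently
#' double-transform.
#'
#' @param m An [expression_matrix()].
#' @return An `expr_matrix` on the other scale, identifiers preserved.
#' @examples
#' m <- expression_matrix(matrix(c(0, 1, 2, 3), 2, 2), scale = "log2")
#' to_original_scale(m)$values  # 2^v elementwise
#' @export
to_original_scale <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") {
    stop("matrix is already on the original scale; expected log2 input", call. = FALSE)
  }
  expression_matrix(2^m$values, scale = "original")
}

#' @rdname to_original_scale
#' @export
to_log2_scale <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "original") {
    stop("matrix is already on the log2 scale; expected original-scale input", call. = FALSE)
  }
  expression_matrix(log2(m$values), scale = "log2")
}

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' Tidy an expression matrix into long format
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `value`.
#' @exportS3Method generics::tidy
tidy.expr_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "value")
}
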