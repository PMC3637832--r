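#' Read an expression matrix from a delimited file
#'
#' Supports plain TSV/CSV (first column gene id, header row of sample ids,
#' numeric body) and the GCT dialect (two extra header lines and a
#' `Description` column, which is ignored). Missing values in the body are an
#' error: upstream normalization is expected to have produced a complete
#' matrix.
#'
#' @param path File path.
#' @param scale Scale tag of the stored values (`"log2"` or `"original"`).
#' @param format `"auto"` sniffs GCT from the `#1.2` version line and
#'   otherwise chooses by delimiter; or force one of `"tsv"`, `"csv"`,
#'   `"gct"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, scale = c("log2", "original"),
                            format = c("auto", "tsv", "csv", "gct")) {
  scale <- match.arg(scale)
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    if (startsWith(first, "#1.")) {
      format <- "gct"
    } else if (grepl(",", first, fixed = TRUE) && !grepl("\t", first, fixed = TRUE)) {
      format <- "csv"
    } else {
      format <- "tsv"
    }
  }
  if (format == "gct") {
    df <- readr::read_tsv(path, skip = 2L, show_col_types = FALSE, progress = FALSE)
    drop <- tolower(names(df)) == "description"
    df <- df[, !drop, drop = FALSE]
  } else {
    reader <- if (format == "csv") readr::read_csv else readr::read_tsv
    df <- reader(path, show_col_types = FALSE, progress = FALSE)
  }
  expression_matrix(as.data.frame(df), scale = scale)
}

#' Write an expression matrix as TSV
#'
#' @param m An [expression_matrix()].
#' @param path Output path. First column `gene_id`, then one column per sample.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- tibble::as_tibble(m$values, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a two-group sample label file
#'
#' Two-column TSV (`sample_id`, `group`); exactly two distinct group values
#' are required.
#'
#' @param path File path.
#' @return A tibble with columns `sample_id` and `group` (factor, two levels).
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 2L) stop("labels file needs two columns: sample_id, group", call. = FALSE)
  out <- tibble::tibble(sample_id = df[[1]], group = factor(df[[2]]))
  if (nlevels(out$group) != 2L) {
    stop("labels file must contain exactly two distinct groups, found ",
         nlevels(out$group), call. = FALSE)
  }
  out
}

#' Export / import a gene filter mask
#'
#' The mask is stored as two-column TSV (`gene_id`, `retained` as 0/1) so a
#' filter can be audited and re-applied outside R.
#'
#' @param filter A gene filter tibble from e.g. [fixed_proportion_filter()].
#' @param path File path.
#' @return `write_filter()` returns `path` invisibly; `read_filter()` returns
#'   a gene filter tibble (provenance attributes are not round-tripped).
#' @export
write_filter <- function(filter, path) {
  stopifnot(is.data.frame(filter), all(c("gene_id", "retained") %in% names(filter)))
  readr::write_tsv(
    tibble::tibble(gene_id = filter$gene_id, retained = as.integer(filter$retained)),
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_filter
#' @export
read_filter <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  new_gene_filter(as.character(df$gene_id), as.logical(df$retained),
                  method = "unknown", rule = "none")
}

#' Write a differential-expression table as TSV
#'
#' @param deg A DEG result tibble from [deg_test()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  stopifnot(is.data.frame(deg))
  readr::write_tsv(deg, path, progress = FALSE)
  invisible(path)
}
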