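#' Compute a per-gene filter signal
#'
#' Reduces a genes-by-samples expression matrix to one scalar per gene — the
#' univariate signal that is later decomposed into Gaussian components. Three
#' signals are supported, following the field's filter naming:
#'
#' * `"S"` — mean of the log2 expression across all samples (requires a
#'   log2-scale matrix);
#' * `"V"` — log of the unbiased sample variance of the original-scale
#'   intensities (requires an original-scale matrix; convert with
#'   [to_original_scale()]);
#' * `"LV"` — log of the unbiased sample variance of the log2 values
#'   (requires a log2-scale matrix).
#'
#' The log transform of variances reduces the skewness of their distribution.
#' Its base only rescales the signal affinely, so the mixture structure found
#' downstream is base-invariant; base 2 is the default to keep the signal in
#' familiar log2 units. Genes whose sample variance is exactly zero have no
#' finite log variance; they are assigned the minimum finite signal minus 6
#' log-units (with a warning) so that they fall into the lowest, least
#' informative component instead of breaking the fit.
#'
#' @param m An [expression_matrix()] on the scale the method requires.
#' @param method One of `"S"`, `"V"`, `"LV"`.
#' @param log_base Base of the logarithm applied to variances (ignored for
#'   `"S"`). Default 2.
#' @return A tibble of class `filter_signal` with columns `gene_id` and `x`,
#'   and attributes `method`, `log_base` and `n_genes`.
#' @examples
#' m <- expression_matrix(matrix(c(0, 2, 1, 1), 2, 2, byrow = TRUE), scale = "log2")
#' compute_signal(m, "S")$x   # per-gene means
#' compute_signal(m, "LV")$x  # log2 of unbiased variances
#' @export
compute_signal <- function(m, method = c("S", "V", "LV"), log_base = 2) {
  stopifnot(inherits(m, "expr_matrix"))
  method <- match.arg(method)
  if (!is.numeric(log_base) || length(log_base) != 1L || log_base <= 1) {
    stop("`log_base` must be a single number > 1", call. = FALSE)
  }
  needed <- if (method == "V") "original" else "log2"
  if (m$scale != needed) {
    stop(sprintf("method %s requires a matrix on the %s scale, got %s",
                 method, needed, m$scale), call. = FALSE)
  }
  if (n_samples(m) < 2L) stop("need at least two samples", call. = FALSE)
  X <- m$values
  if (method == "S") {
    x <- rowMeans(X)
  } else {
    v <- row_vars(X)
    x <- log(v, base = log_base)
    zero <- v == 0
    if (any(zero)) {
      if (all(zero)) {
        stop("all genes have zero sample variance; variance signal undefined", call. = FALSE)
      }
      floor_x <- min(x[!zero]) - 6
      x[zero] <- floor_x
      warning(sum(zero), " gene(s) with zero sample variance assigned signal ",
              signif(floor_x, 4), call. = FALSE)
    }
  }
  new_filter_signal(gene_ids(m), x, method = method, log_base = log_base)
}

new_filter_signal <- function(gene_id, x, method, log_base = NA_real_) {
  stopifnot(length(gene_id) == length(x), all(is.finite(x)))
  out <- tibble::tibble(gene_id = gene_id, x = as.numeric(x))
  attr(out, "method") <- method
  attr(out, "log_base") <- log_base
  attr(out, "n_genes") <- length(x)
  class(out) <- c("filter_signal", class(out))
  out
}

#' @export
print.filter_signal <- function(x, ...) {
  cat(sprintf("<filter_signal> method %s, %d genes\n",
              attr(x, "method"), attr(x, "n_genes")))
  NextMethod()
}

# unbiased (M-1 denominator) row variances without forming huge intermediates
row_vars <- function(X) {
  M <- ncol(X)
  mu <- rowMeans(X)
  rowSums((X - mu)^2) / (M - 1)
}

# pull the numeric signal out of a filter_signal or plain numeric vector
signal_values <- function(signal) {
  if (inherits(signal, "filter_signal") ||
      (is.data.frame(signal) && "x" %in% names(signal))) {
    return(signal$x)
  }
  if (is.numeric(signal)) return(as.numeric(signal))
  stop("expected a filter_signal tibble or a numeric vector", call. = FALSE)
}

signal_gene_ids <- function(signal) {
  if (is.data.frame(signal) && "gene_id" %in% names(signal)) {
    return(signal$gene_id)
  }
  paste0("g", seq_along(signal_values(signal)))
}
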