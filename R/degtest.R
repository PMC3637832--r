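#' Per-gene equal-variance two-sample t-tests
#'
#' Pooled-variance t statistic per gene with `M - 2` degrees of freedom and
#' two-sided p-values, vectorized across genes. The statistic is
#' `(mean(group1) - mean(group2)) / se`, groups taken in the order of the
#' label factor levels. Genes with zero pooled variance (all values equal
#' within both groups) get `t = 0`, `p = 1` with a warning.
#'
#' @param m A log2-scale [expression_matrix()].
#' @param labels A tibble with columns `sample_id` and `group` (two levels,
#'   each with at least two samples), as from [read_labels()], or a vector of
#'   group labels ordered like the matrix columns.
#' @return A tibble with columns `gene_id`, `t`, `df`, `p`.
#' @examples
#' m <- expression_matrix(matrix(c(1, 2, 3, 4, 3, 4, 5, 6), 1), scale = "log2")
#' lab <- rep(c("a", "b"), each = 4)
#' t_test_genes(m, lab)
#' @export
t_test_genes <- function(m, labels) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("t-tests expect log2-scale expression", call. = FALSE)
  grp <- resolve_labels(m, labels)
  X <- m$values
  g1 <- grp == levels(grp)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least two samples", call. = FALSE)
  m1 <- rowMeans(X[, g1, drop = FALSE])
  m2 <- rowMeans(X[, g2, drop = FALSE])
  ss1 <- rowSums((X[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((X[, g2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  degenerate <- sp2 == 0
  if (any(degenerate)) {
    t[degenerate] <- 0
    warning(sum(degenerate), " gene(s) with zero pooled variance: t = 0, p = 1",
            call. = FALSE)
  }
  p <- 2 * stats::pt(-abs(t), df = df)
  p[degenerate] <- 1
  tibble::tibble(gene_id = gene_ids(m), t = unname(t), df = df, p = unname(p))
}

resolve_labels <- function(m, labels) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "group") %in% names(labels))) {
      stop("labels data frame needs columns sample_id and group", call. = FALSE)
    }
    idx <- match(sample_ids(m), labels$sample_id)
    if (anyNA(idx)) stop("labels missing for some samples", call. = FALSE)
    grp <- factor(labels$group[idx])
  } else {
    if (length(labels) != n_samples(m)) {
      stop("label vector length must equal the number of samples", call. = FALSE)
    }
    grp <- factor(labels)
  }
  if (nlevels(grp) != 2L) stop("exactly two groups required", call. = FALSE)
  grp
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion \eqn{\hat\pi_0} on a grid of tuning values
#' \eqn{\lambda} (default 0, 0.05, ..., 0.90) via
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))}, smoothed by
#' a cubic smoothing spline and evaluated at the largest \eqn{\lambda},
#' clipped into (0, 1]. Q-values are then
#' \eqn{q(p_{(i)}) = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)} / j}. Forcing
#' `pi0 = 1` makes the procedure identical to Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param lambda Grid for the \eqn{\pi_0} estimate.
#' @param pi0 Optional fixed null proportion overriding the estimate.
#' @return A list with `q` (q-values, in the input order) and `pi0`.
#' @examples
#' q_values(c(0.01, 0.02, 0.03, 0.8), pi0 = 1)$q
#' @export
q_values <- function(p, lambda = seq(0, 0.90, by = 0.05), pi0 = NULL) {
  if (length(p) == 0L) stop("need at least one p-value", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- estimate_pi0(p, lambda)
  }
  if (pi0 <= 0 || pi0 > 1) stop("`pi0` must lie in (0, 1]", call. = FALSE)
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, pi0 = pi0)
}

estimate_pi0 <- function(p, lambda) {
  m <- length(p)
  lambda <- sort(unique(lambda))
  if (m < 100L || length(lambda) < 4L) {
    # too little information to smooth; fall back to the conservative BH limit
    return(1)
  }
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

#' Call DEGs at an FDR constraint
#'
#' @param q Vector of q-values.
#' @param fdr_level FDR constraint (default 0.05); the call is inclusive,
#'   `q <= fdr_level`.
#' @return Logical vector of calls.
#' @export
call_degs <- function(q, fdr_level = 0.05) {
  if (length(q) == 0L) return(logical(0))
  q <= fdr_level
}

#' Two-step DEG discovery on the retained genes
#'
#' Applies the equal-variance t-test to the genes retained by `filter`, then
#' the Storey-Tibshirani q-value correction *within that retained pool* (the
#' point of two-step filtering: fewer hypotheses, more power), and calls DEGs
#' at `q <= fdr_level`.
#'
#' @inheritParams t_test_genes
#' @param filter Optional `gene_filter`; `NULL` tests every gene.
#' @param fdr_level FDR constraint for calls (default 0.05).
#' @param pi0 Optional fixed null proportion (see [q_values()]).
#' @return A `deg_result` tibble over the retained genes with columns
#'   `gene_id`, `t`, `df`, `p`, `q`, `call`, and attributes `pi0`,
#'   `fdr_level`, `n_rejections`.
#' @export
deg_test <- function(m, labels, filter = NULL, fdr_level = 0.05, pi0 = NULL) {
  tt <- t_test_genes(m, labels)
  if (!is.null(filter)) {
    stopifnot(is.data.frame(filter), all(c("gene_id", "retained") %in% names(filter)))
    keep <- filter$gene_id[filter$retained]
    tt <- tt[tt$gene_id %in% keep, , drop = FALSE]
    if (nrow(tt) == 0L) stop("filter retains no genes", call. = FALSE)
  }
  qv <- q_values(tt$p, pi0 = pi0)
  out <- dplyr::mutate(tt, q = qv$q, call = call_degs(qv$q, fdr_level))
  attr(out, "pi0") <- qv$pi0
  attr(out, "fdr_level") <- fdr_level
  attr(out, "n_rejections") <- sum(out$call)
  class(out) <- c("deg_result", class(out))
  out
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("<deg_result> %d genes tested, %d called at q <= %g (pi0 = %.3f)\n",
              nrow(x), attr(x, "n_rejections"), attr(x, "fdr_level"),
              attr(x, "pi0")))
  NextMethod()
}
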