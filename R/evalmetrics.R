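#' Sensitivity-versus-FDR operating curve
#'
#' Sweeps a significance threshold over the retained genes, ordered by
#' p-value (or any score where smaller means more significant), and records
#' the realized false discovery proportion `FDR = FP / max(1, FP + TP)` and
#' `sensitivity = TP / (number of true DEGs among ALL genes)` at every
#' threshold. Genes removed by the filter are never called, at any
#' threshold — a filter that discards true DEGs caps the attainable
#' sensitivity, which is exactly what penalizes over-filtering.
#'
#' The returned curve is the attainable frontier: for each FDR value, the
#' maximum sensitivity achievable at any threshold whose realized FDR does
#' not exceed it. Both columns are therefore non-decreasing.
#'
#' @param p Per-gene p-values (or scores, ascending = significant) covering
#'   all N genes.
#' @param truth Logical vector over all N genes, `TRUE` for true DEGs; must
#'   contain at least one positive.
#' @param retained Optional logical vector over all N genes (from a
#'   `gene_filter`'s `retained` column); `NULL` retains all.
#' @return A tibble of class `roc_curve` with columns `fdr` and
#'   `sensitivity`, starting at (0, 0).
#' @export
roc_fdr_sens <- function(p, truth, retained = NULL) {
  stopifnot(length(p) == length(truth))
  truth <- as.logical(truth)
  if (!any(truth)) stop("truth contains no positives; sensitivity undefined", call. = FALSE)
  if (is.null(retained)) retained <- rep(TRUE, length(p))
  stopifnot(length(retained) == length(p))
  total_true <- sum(truth)
  pr <- p[retained]
  tr <- truth[retained]
  o <- order(pr)
  tp <- cumsum(tr[o])
  fp <- seq_along(o) - tp
  fdr <- fp / pmax(1, fp + tp)
  sens <- tp / total_true
  # attainable frontier: max sensitivity at realized FDR <= f, monotone in both
  ord <- order(fdr, sens)
  f <- c(0, fdr[ord])
  s <- c(0, cummax(sens[ord]))
  keep <- !duplicated(f, fromLast = TRUE)
  out <- tibble::tibble(fdr = f[keep], sensitivity = s[keep])
  class(out) <- c("roc_curve", class(out))
  out
}

#' Sensitivity at an FDR constraint, read off the operating curve
#'
#' @param roc A curve from [roc_fdr_sens()].
#' @param fdr_level Constraint on realized FDR (default 0.05).
#' @return Maximum sensitivity over thresholds with realized FDR at or below
#'   `fdr_level` (0 if none), as a proportion in `[0, 1]`.
#' @export
sensitivity_at_fdr <- function(roc, fdr_level = 0.05) {
  ok <- roc$fdr <= fdr_level
  if (!any(ok)) return(0)
  max(roc$sensitivity[ok])
}

#' Partial area under the sensitivity-versus-FDR curve
#'
#' Trapezoidal area of sensitivity over FDR in `[0, fdr_cap]`, scaled by 100
#' so that a perfect detector (sensitivity 1 throughout) scores
#' `100 * fdr_cap`. The cap defaults to 0.20, the FDR range over which
#' filter comparisons are made.
#'
#' @param roc A curve from [roc_fdr_sens()] (columns `fdr`, `sensitivity`,
#'   FDR non-decreasing).
#' @param fdr_cap Upper FDR integration bound (> 0).
#' @return The percent-scaled partial area.
#' @export
partial_auc <- function(roc, fdr_cap = 0.20) {
  if (!is.numeric(fdr_cap) || fdr_cap <= 0) stop("`fdr_cap` must be > 0", call. = FALSE)
  f <- roc$fdr
  s <- roc$sensitivity
  if (f[1] > 0) { f <- c(0, f); s <- c(0, s) }
  # truncate / extend the piecewise-linear curve at the cap
  if (max(f) < fdr_cap) {
    f <- c(f, fdr_cap); s <- c(s, s[length(s)])
  } else if (!any(f == fdr_cap)) {
    s_cap <- stats::approx(f, s, xout = fdr_cap, ties = "ordered")$y
    keep <- f < fdr_cap
    f <- c(f[keep], fdr_cap); s <- c(s[keep], s_cap)
  } else {
    keep <- f <= fdr_cap
    f <- f[keep]; s <- s[keep]
  }
  100 * sum(diff(f) * (utils::head(s, -1) + utils::tail(s, -1)) / 2)
}

#' F1 measure of detection performance
#'
#' Harmonic mean of `1 - FDR` and sensitivity:
#' \eqn{F_1 = 2 (1 - FDR)\,sens / ((1 - FDR) + sens)}; equals 1 only at
#' sensitivity 1 with FDR 0, and is defined as 0 when both terms vanish.
#'
#' @param sensitivity,fdr Values in `[0, 1]` (vectorized).
#' @return The F1 value(s).
#' @export
f1_measure <- function(sensitivity, fdr) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(fdr >= 0 & fdr <= 1))
  a <- 1 - fdr
  denom <- a + sensitivity
  ifelse(denom == 0, 0, 2 * a * sensitivity / denom)
}

#' Number of rejected null hypotheses
#'
#' The truth-free comparison index: how many genes can be called DEGs in the
#' retained pool under the FDR constraint.
#'
#' @param deg A `deg_result` from [deg_test()], or a logical vector of calls.
#' @return Integer count of rejections.
#' @export
rejection_count <- function(deg) {
  if (is.data.frame(deg) && "call" %in% names(deg)) return(sum(deg$call))
  if (is.logical(deg)) return(sum(deg))
  stop("expected a deg_result or logical calls", call. = FALSE)
}
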