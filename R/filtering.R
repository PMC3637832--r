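#' Component selection rules
#'
#' Decide which mixture components hold informative genes. Components are
#' always indexed in ascending order of their means.
#'
#' `select_top3()` keeps the three components with the largest means —
#' read as high-, medium- and low-level expressed genes — and removes the
#' rest. With K of 3 or fewer there is nothing to remove and the rule
#' degenerates to no filtering (flagged via `nf_equivalent`).
#'
#' `select_kmeans2()` clusters the K parameter triples
#' \eqn{(\mu_k, \sigma_k, \alpha_k)} into two groups by k-means (squared
#' Euclidean distance on the raw, unstandardized coordinates); the cluster
#' whose centroid sits lower along the component-mean coordinate is declared
#' non-informative and its components are removed. With K at most 15 the
#' within-cluster sum of squares is minimized exactly by exhaustive search
#' over all bipartitions, so the rule has no initialization randomness.
#' `K = 1` degenerates to no filtering.
#'
#' @param fit A `gmm_fit`.
#' @param standardize_coords Standardize the three coordinates to unit
#'   variance before clustering (default `FALSE`: raw coordinates).
#' @return A `component_selection`: list with `retained` (component indices),
#'   `rule`, `nf_equivalent` flag and, for k-means, the two `centroids`.
#' @export
select_top3 <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  K <- fit$K
  if (K <= 3L) {
    return(new_component_selection(seq_len(K), "top3", nf_equivalent = TRUE))
  }
  new_component_selection((K - 2L):K, "top3", nf_equivalent = FALSE)
}

#' @rdname select_top3
#' @export
select_kmeans2 <- function(fit, standardize_coords = FALSE) {
  stopifnot(inherits(fit, "gmm_fit"))
  K <- fit$K
  if (K == 1L) {
    return(new_component_selection(1L, "kmeans2", nf_equivalent = TRUE))
  }
  pts <- cbind(mean = fit$means, sd = fit$sds, weight = fit$weights)
  coords <- if (standardize_coords) {
    s <- apply(pts, 2L, stats::sd)
    sweep(pts, 2L, ifelse(s > 0, s, 1), "/")
  } else {
    pts
  }
  part <- best_bipartition(coords)
  # order the two clusters along the component-mean coordinate of their centroids
  mean_loc <- vapply(part, function(idx) mean(pts[idx, "mean"]), numeric(1))
  low <- which.min(mean_loc)
  retained <- sort(part[[3L - low]])
  centroids <- rbind(colMeans(pts[part[[low]], , drop = FALSE]),
                     colMeans(pts[part[[3L - low]], , drop = FALSE]))
  rownames(centroids) <- c("removed", "retained")
  new_component_selection(retained, "kmeans2", nf_equivalent = FALSE,
                          centroids = centroids)
}

# exact 2-means: minimize within-cluster SS over all 2^(K-1)-1 bipartitions
best_bipartition <- function(pts) {
  K <- nrow(pts)
  stopifnot(K >= 2, K <= 25)
  best <- NULL
  best_ss <- Inf
  # fix point 1 in cluster A to enumerate each bipartition once
  for (code in 0:(2^(K - 1) - 1)) {
    inA <- c(TRUE, as.logical(bitwAnd(bitwShiftR(code, 0:(K - 2)), 1L)))
    if (all(inA)) next
    ss <- cluster_ss(pts[inA, , drop = FALSE]) + cluster_ss(pts[!inA, , drop = FALSE])
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best <- list(which(inA), which(!inA))
    }
  }
  best
}

cluster_ss <- function(p) {
  ctr <- colMeans(p)
  sum(sweep(p, 2L, ctr)^2)
}

new_component_selection <- function(retained, rule, nf_equivalent, centroids = NULL) {
  structure(list(retained = as.integer(retained), rule = rule,
                 nf_equivalent = nf_equivalent, centroids = centroids),
            class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf("<component_selection> rule %s: retain {%s}%s\n", x$rule,
              paste(x$retained, collapse = ","),
              if (x$nf_equivalent) " [equivalent to NF]" else ""))
  invisible(x)
}

new_gene_filter <- function(gene_id, retained, method, rule, P = NA_real_,
                            nf_equivalent = FALSE, fit = NULL, selection = NULL) {
  out <- tibble::tibble(gene_id = gene_id, retained = as.logical(retained))
  attr(out, "method") <- method
  attr(out, "rule") <- rule
  attr(out, "P") <- P
  attr(out, "nf_equivalent") <- nf_equivalent
  attr(out, "removed_fraction") <- 1 - mean(out$retained)
  class(out) <- c("gene_filter", class(out))
  out
}

#' @export
print.gene_filter <- function(x, ...) {
  cat(sprintf("<gene_filter> method %s, rule %s: %.1f%% of %d genes removed\n",
              attr(x, "method"), attr(x, "rule"),
              100 * attr(x, "removed_fraction"), nrow(x)))
  NextMethod()
}

#' Turn a component selection into a gene retain-mask
#'
#' A gene is retained iff its MAP component belongs to the retained set.
#'
#' @param fit A `gmm_fit` carrying per-gene MAP `assignments`.
#' @param selection A `component_selection` produced from the same fit.
#' @param signal Optional `filter_signal` supplying gene ids and assignments
#'   recomputed against the fit; defaults to the fit's own stored signal.
#' @return A `gene_filter` tibble (`gene_id`, `retained`) with provenance
#'   attributes `method`, `rule`, `removed_fraction`.
#' @export
component_filter_mask <- function(fit, selection, signal = NULL) {
  stopifnot(inherits(fit, "gmm_fit"), inherits(selection, "component_selection"))
  if (any(selection$retained > fit$K)) {
    stop("selection refers to components beyond the fit's K", call. = FALSE)
  }
  if (is.null(signal)) {
    assignments <- fit$assignments
    ids <- fit$gene_ids
    if (length(assignments) == 0L) {
      stop("fit carries no assignments; supply the signal", call. = FALSE)
    }
  } else {
    assignments <- map_assign(signal, fit)
    ids <- signal_gene_ids(signal)
  }
  new_gene_filter(ids, assignments %in% selection$retained,
                  method = fit$signal_method %||% "unknown",
                  rule = selection$rule,
                  nf_equivalent = selection$nf_equivalent)
}

#' Adaptive component-based gene filter
#'
#' Convenience wrapper chaining mixture fitting ([select_model()] or a fixed
#' K via [em_fit()]), component selection ([select_top3()] or
#' [select_kmeans2()]) and mask construction ([component_filter_mask()]).
#'
#' @param signal A `filter_signal`.
#' @param rule `"kmeans2"` or `"top3"`.
#' @param K_mode `"bic"` to select K in `1:K_max` by BIC; `"fixed"` to fit
#'   exactly `fixed_K` components.
#' @param fixed_K Component count used when `K_mode = "fixed"` (default 2).
#' @param K_max Upper end of the BIC search (default 15).
#' @param seed,n_restarts,tol,max_iter,n_bins Passed to the fitting routines.
#' @return A `gene_filter` with the fit attached as attribute `fit`.
#' @export
adaptive_filter <- function(signal, rule = c("kmeans2", "top3"),
                            K_mode = c("bic", "fixed"), fixed_K = 2L,
                            K_max = 15L, seed = 1L, n_restarts = 10L,
                            tol = 1e-8, max_iter = 1000L, n_bins = 1024L) {
  rule <- match.arg(rule)
  K_mode <- match.arg(K_mode)
  fit <- if (K_mode == "fixed") {
    em_fit(signal, K = fixed_K, seed = seed, n_restarts = n_restarts,
           tol = tol, max_iter = max_iter, n_bins = n_bins)
  } else {
    select_model(signal, K_min = 1L, K_max = K_max, seed = seed,
                 n_restarts = n_restarts, tol = tol, max_iter = max_iter,
                 n_bins = n_bins)
  }
  sel <- if (rule == "top3") select_top3(fit) else select_kmeans2(fit)
  mask <- component_filter_mask(fit, sel, signal = signal)
  attr(mask, "fit") <- fit
  attr(mask, "selection") <- sel
  mask
}

#' Fixed-proportion threshold filter
#'
#' Removes the `floor(N * P / 100)` genes with the smallest signal values —
#' the classical "filter out P% of probe sets" comparator (e.g. `S_50`,
#' `V_50`). Ties at the cut boundary break by gene order (stable sort).
#'
#' @param signal A `filter_signal`.
#' @param P Percentage of genes to remove, in `[0, 100)`.
#' @return A `gene_filter` tibble.
#' @examples
#' s <- compute_signal(
#'   expression_matrix(matrix(c(5, 5, 1, 1, 3, 3), 3, 2, byrow = TRUE), "log2"), "S")
#' fixed_proportion_filter(s, 40)$retained
#' @export
fixed_proportion_filter <- function(signal, P) {
  if (!is.numeric(P) || length(P) != 1L || P < 0 || P >= 100) {
    stop("`P` must be a percentage in [0, 100)", call. = FALSE)
  }
  x <- signal_values(signal)
  N <- length(x)
  n_remove <- floor(N * P / 100)
  retained <- rep(TRUE, N)
  if (n_remove > 0) {
    retained[order(x)[seq_len(n_remove)]] <- FALSE  # order() is stable
  }
  new_gene_filter(signal_gene_ids(signal), retained,
                  method = if (inherits(signal, "filter_signal")) attr(signal, "method") else "unknown",
                  rule = "fixed_P", P = P, nf_equivalent = P == 0)
}

#' No-filter mask
#'
#' Retains every gene; the NF baseline all filtered pipelines are compared
#' against.
#'
#' @param signal A `filter_signal` (or anything with gene ids).
#' @return A `gene_filter` with all genes retained.
#' @export
no_filter <- function(signal) {
  ids <- signal_gene_ids(signal)
  new_gene_filter(ids, rep(TRUE, length(ids)), method = "NF", rule = "none",
                  nf_equivalent = TRUE)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
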