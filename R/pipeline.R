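#' Run the two-step filter-then-test pipeline
#'
#' End-to-end driver: compute the filter signal, build the gene filter
#' (adaptive mixture-based, fixed-proportion, or none), then test the
#' retained genes (equal-variance t-test, q-value FDR correction, calls at
#' the FDR constraint).
#'
#' @param m A log2-scale [expression_matrix()].
#' @param labels Two-group sample labels (see [t_test_genes()]).
#' @param filter_method `"NF"` (no filter), `"S"`, `"V"` or `"LV"`.
#' @param rule Component-selection rule for adaptive filters (`"kmeans2"` or
#'   `"top3"`), or `"fixed"` for the fixed-proportion comparator.
#' @param P Percentage removed when `rule = "fixed"` (default 50, i.e. the
#'   classical `S_50` / `V_50` / `LV_50` filters).
#' @param K_mode,fixed_K,K_max,n_restarts,tol,max_iter,n_bins Mixture
#'   fitting controls, passed to [adaptive_filter()].
#' @param fdr_level FDR constraint for DEG calls (default 0.05).
#' @param log_base Log base for variance signals.
#' @param seed Integer seed for the mixture fitting.
#' @param pi0 Optional fixed null-proportion override for [q_values()].
#' @return A `pipeline_result` list: `filter` (gene_filter), `degs`
#'   (deg_result), `fit` (gmm_fit or NULL) and `report` (named list of run
#'   metadata sufficient to reproduce the run).
#' @examples
#' d <- simulate_expression(sim_config(n_genes = 2000, seed = 5))
#' res <- run_pipeline(d$matrix, d$labels, "S", rule = "kmeans2",
#'                     K_mode = "fixed", seed = 2)
#' res$report$removed_fraction
#' @export
run_pipeline <- function(m, labels, filter_method = c("NF", "S", "V", "LV"),
                         rule = c("kmeans2", "top3", "fixed"), P = 50,
                         K_mode = c("bic", "fixed"), fixed_K = 2L, K_max = 15L,
                         fdr_level = 0.05, log_base = 2, seed = 1L,
                         n_restarts = 10L, tol = 1e-8, max_iter = 1000L,
                         n_bins = 1024L, pi0 = NULL) {
  filter_method <- match.arg(filter_method)
  rule <- match.arg(rule)
  K_mode <- match.arg(K_mode)
  stopifnot(inherits(m, "expr_matrix"))

  fit <- NULL
  if (filter_method == "NF") {
    sig <- new_filter_signal(gene_ids(m), rep(0, n_genes(m)), method = "NF")
    filter <- no_filter(sig)
  } else {
    mm <- if (filter_method == "V" && m$scale == "log2") to_original_scale(m) else m
    sig <- compute_signal(mm, filter_method, log_base = log_base)
    filter <- if (rule == "fixed") {
      fixed_proportion_filter(sig, P)
    } else {
      adaptive_filter(sig, rule = rule, K_mode = K_mode, fixed_K = fixed_K,
                      K_max = K_max, seed = seed, n_restarts = n_restarts,
                      tol = tol, max_iter = max_iter, n_bins = n_bins)
    }
    fit <- attr(filter, "fit")
  }

  degs <- deg_test(m, labels, filter = filter, fdr_level = fdr_level, pi0 = pi0)
  report <- list(
    filter_method = filter_method,
    rule = if (filter_method == "NF") "none" else rule,
    P = if (rule == "fixed" && filter_method != "NF") P else NA_real_,
    K_mode = K_mode, K = if (is.null(fit)) NA_integer_ else fit$K,
    removed_fraction = attr(filter, "removed_fraction"),
    nf_equivalent = isTRUE(attr(filter, "nf_equivalent")),
    pi0 = attr(degs, "pi0"),
    fdr_level = fdr_level,
    n_rejections = attr(degs, "n_rejections"),
    seed = seed,
    gmm_settings = list(n_restarts = n_restarts, tol = tol,
                        max_iter = max_iter, K_max = K_max, n_bins = n_bins,
                        log_base = log_base)
  )
  structure(list(filter = filter, degs = degs, fit = fit, report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<pipeline_result> %s/%s: removed %.1f%%%s, %d rejections at q <= %g\n",
              r$filter_method, r$rule, 100 * r$removed_fraction,
              if (!is.na(r$K)) sprintf(" (K = %d)", r$K) else "",
              r$n_rejections, r$fdr_level))
  invisible(x)
}

#' Default benchmark method grid
#'
#' One row per pipeline variant: the no-filter baseline, fixed 50%
#' comparators, and the adaptive filters with fixed K = 2 or BIC-selected K
#' under the k-means rule.
#'
#' @param methods Character vector choosing rows by label; default all.
#' @return A tibble with columns `label`, `filter_method`, `rule`, `P`,
#'   `K_mode`, `fixed_K`.
#' @export
benchmark_methods <- function(methods = NULL) {
  grid <- tibble::tribble(
    ~label,      ~filter_method, ~rule,     ~P,  ~K_mode, ~fixed_K,
    "NF",        "NF",           "none",    NA,  "none",  NA,
    "S_50",      "S",            "fixed",   50,  "none",  NA,
    "V_50",      "V",            "fixed",   50,  "none",  NA,
    "AS_fixed2", "S",            "kmeans2", NA,  "fixed", 2,
    "AV_fixed2", "V",            "kmeans2", NA,  "fixed", 2,
    "AS_kmeans", "S",            "kmeans2", NA,  "bic",   NA,
    "AV_kmeans", "V",            "kmeans2", NA,  "bic",   NA,
    "AS_top3",   "S",            "top3",    NA,  "bic",   NA,
    "AV_top3",   "V",            "top3",    NA,  "bic",   NA
  )
  if (!is.null(methods)) {
    missing <- setdiff(methods, grid$label)
    if (length(missing)) stop("unknown method label(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
    grid <- grid[match(methods, grid$label), , drop = FALSE]
  }
  grid
}

#' Replicated simulation benchmark of filtering methods
#'
#' For each replicate: simulate a dataset under `cfg` (with a
#' replicate-specific child seed), run every requested pipeline variant, and
#' score it against the known truth. Per-gene t-tests are computed once per
#' replicate and shared across methods (a filter changes which genes enter
#' the multiple-testing step, not their statistics); mixture fits are cached
#' per signal and K-mode.
#'
#' Scores per replicate and method: sensitivity at the threshold giving 5%
#' (or `fdr_roc`) realized FDR, partial AUC, realized FDR / sensitivity / F1
#' of the q-value calls at `fdr_level`, the rejection count, the removed
#' fraction and the fitted K. Summarize across replicates with
#' [summarize_benchmark()] — the benchmark's headline figure is the *median*
#' sensitivity at 5% FDR.
#'
#' @param cfg A [sim_config()]; its `seed` is ignored in favor of
#'   replicate child seeds derived from `seed`.
#' @param methods A method grid from [benchmark_methods()] (or a character
#'   vector of its labels).
#' @param n_replicates Number of simulation replicates (default 50).
#' @param seed Master seed; replicate r simulates with seed `seed + r` and
#'   fits mixtures with seed `seed + 10000 + r`.
#' @param fdr_roc FDR level at which ROC sensitivity is read (default 0.05).
#' @param fdr_level FDR constraint for q-value calls (default 0.05).
#' @param fdr_cap Partial-AUC integration cap (default 0.20).
#' @param K_max,n_restarts,tol,max_iter,n_bins Mixture fitting controls.
#' @param log_base Log base for variance signals.
#' @return A tibble, one row per replicate x method, of class
#'   `benchmark_result`.
#' @export
run_benchmark <- function(cfg = sim_config(), methods = benchmark_methods(),
                          n_replicates = 50L, seed = 1L, fdr_roc = 0.05,
                          fdr_level = 0.05, fdr_cap = 0.20, K_max = 15L,
                          n_restarts = 10L, tol = 1e-8, max_iter = 1000L,
                          n_bins = 1024L, log_base = 2) {
  if (is.character(methods)) methods <- benchmark_methods(methods)
  stopifnot(is.data.frame(methods), n_replicates >= 1)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- as.integer(seed) + r
    d <- simulate_expression(cfg_r)
    gmm_seed <- as.integer(seed) + 10000L + r
    tt <- t_test_genes(d$matrix, d$labels)
    truth <- d$truth$is_deg

    signals <- list()
    fits <- list()
    get_signal <- function(method) {
      if (is.null(signals[[method]])) {
        mm <- if (method == "V") to_original_scale(d$matrix) else d$matrix
        signals[[method]] <<- compute_signal(mm, method, log_base = log_base)
      }
      signals[[method]]
    }
    get_fit <- function(method, K_mode, fixed_K) {
      key <- paste(method, K_mode, fixed_K, sep = "_")
      if (is.null(fits[[key]])) {
        sig <- get_signal(method)
        fits[[key]] <<- if (K_mode == "fixed") {
          em_fit(sig, K = fixed_K, seed = gmm_seed, n_restarts = n_restarts,
                 tol = tol, max_iter = max_iter, n_bins = n_bins)
        } else {
          select_model(sig, K_max = K_max, seed = gmm_seed,
                       n_restarts = n_restarts, tol = tol,
                       max_iter = max_iter, n_bins = n_bins)
        }
      }
      fits[[key]]
    }

    for (i in seq_len(nrow(methods))) {
      md <- methods[i, ]
      K_fit <- NA_integer_
      if (md$filter_method == "NF") {
        retained <- rep(TRUE, length(truth))
      } else if (md$rule == "fixed") {
        filt <- fixed_proportion_filter(get_signal(md$filter_method), md$P)
        retained <- filt$retained
      } else {
        fit <- get_fit(md$filter_method, md$K_mode, md$fixed_K)
        K_fit <- fit$K
        sel <- if (md$rule == "top3") select_top3(fit) else select_kmeans2(fit)
        retained <- component_filter_mask(fit, sel)$retained
      }

      roc <- roc_fdr_sens(tt$p, truth, retained)
      qv <- q_values(tt$p[retained])
      calls <- call_degs(qv$q, fdr_level)
      tp <- sum(calls & truth[retained])
      fp <- sum(calls) - tp
      fdr_call <- fp / max(1, sum(calls))
      sens_call <- tp / sum(truth)

      rows[[length(rows) + 1L]] <- tibble::tibble(
        replicate = r, label = md$label,
        filter_method = md$filter_method, rule = md$rule,
        K = K_fit, removed_fraction = 1 - mean(retained),
        sens_at_fdr = sensitivity_at_fdr(roc, fdr_roc),
        auc = partial_auc(roc, fdr_cap),
        fdr_qcall = fdr_call, sens_qcall = sens_call,
        f1 = f1_measure(sens_call, fdr_call),
        n_rejections = sum(calls), pi0 = qv$pi0
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fdr_roc") <- fdr_roc
  attr(out, "fdr_level") <- fdr_level
  attr(out, "config") <- cfg
  class(out) <- c("benchmark_result", class(out))
  out
}

#' Median benchmark summaries across replicates
#'
#' @param results A `benchmark_result` from [run_benchmark()].
#' @return A tibble, one row per method, with the across-replicate medians
#'   of sensitivity at the ROC FDR constraint (`median_sens`, percent),
#'   partial AUC, F1 and the rejection count.
#' @export
summarize_benchmark <- function(results) {
  stopifnot(is.data.frame(results))
  dplyr::summarise(
    dplyr::group_by(results, .data$label, .data$filter_method, .data$rule),
    median_sens = 100 * stats::median(.data$sens_at_fdr),
    median_auc = stats::median(.data$auc),
    median_f1 = stats::median(.data$f1),
    median_rejections = stats::median(.data$n_rejections),
    median_removed = 100 * stats::median(.data$removed_fraction),
    .groups = "drop"
  )
}
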