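#' Plot a fitted mixture over the signal histogram
#'
#' Density histogram of the filter signal with the fitted weighted component
#' densities and their sum overlaid — the standard diagnostic for judging
#' whether the decomposition separated an uninformative low-signal
#' population.
#'
#' @param object A `gmm_fit` (must carry its signal, as fits from
#'   [em_fit()] / [select_model()] do).
#' @param bins Histogram bin count (default 100).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gmm_fit <- function(object, bins = 100, ...) {
  if (length(object$x) == 0L) stop("fit carries no signal values to plot", call. = FALSE)
  df <- tibble::tibble(x = object$x)
  grid <- seq(min(object$x), max(object$x), length.out = 512)
  comp <- purrr::map_dfr(seq_len(object$K), function(k) {
    tibble::tibble(
      x = grid,
      density = object$weights[k] * stats::dnorm(grid, object$means[k], object$sds[k]),
      component = factor(k)
    )
  })
  mix <- tibble::tibble(x = grid, density = mixture_density(grid, object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", color = "grey70") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$density, color = .data$component)) +
    ggplot2::geom_line(data = mix, ggplot2::aes(y = .data$density),
                       linewidth = 0.8) +
    ggplot2::labs(x = "filter signal x", y = "density",
                  title = sprintf("Gaussian mixture decomposition (K = %d)", object$K)) +
    ggplot2::theme_minimal()
}

#' Plot sensitivity-versus-FDR operating curves
#'
#' @param ... Named `roc_curve` tibbles (from [roc_fdr_sens()]); names label
#'   the curves.
#' @param fdr_cap Upper FDR limit shown (default 0.20).
#' @return A ggplot object.
#' @export
plot_roc <- function(..., fdr_cap = 0.20) {
  curves <- list(...)
  if (is.null(names(curves)) || any(names(curves) == "")) {
    names(curves) <- paste0("curve", seq_along(curves))
  }
  df <- dplyr::bind_rows(purrr::imap(curves, function(cv, nm) {
    dplyr::mutate(tibble::as_tibble(cv), method = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fdr, y = .data$sensitivity,
                                   color = .data$method)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(xlim = c(0, fdr_cap), ylim = c(0, 1)) +
    ggplot2::labs(x = "FDR", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot benchmark sensitivities by method
#'
#' Boxplot of per-replicate sensitivity at the ROC FDR constraint for each
#' method in a benchmark run.
#'
#' @param object A `benchmark_result` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.benchmark_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$label,
                                       y = 100 * .data$sens_at_fdr)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = sprintf("sensitivity at %g%% FDR (%%)",
                                        100 * (attr(object, "fdr_roc") %||% 0.05))) +
    ggplot2::theme_minimal()
}
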