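# small builders shared across test files

# genes x samples matrix from gene rows
expr_from_rows <- function(..., scale = "log2") {
  expression_matrix(rbind(...), scale = scale)
}

# a well-separated two-component signal
two_mode_signal <- function(n_per = 250, mu = c(0, 10), sd = 1, seed = 42) {
  withr::with_seed(seed, c(stats::rnorm(n_per, mu[1], sd),
                           stats::rnorm(n_per, mu[2], sd)))
}

# hand-built gmm_fit for unit tests that need exact parameters
manual_fit <- function(weights, means, sds, x = numeric(0)) {
  K <- length(weights)
  stopifnot(length(means) == K, length(sds) == K)
  o <- order(means)
  fit <- structure(list(
    K = K, weights = weights[o] / sum(weights), means = means[o], sds = sds[o],
    logL = NA_real_, bic = NA_real_, assignments = integer(0),
    converged = TRUE, n_iter = 0L, seed = 0L, n = length(x),
    sigma_floor = 1e-9, trace = numeric(0), x = x,
    gene_ids = if (length(x)) paste0("g", seq_along(x)) else character(0),
    signal_method = "S",
    settings = list()
  ), class = "gmm_fit")
  if (length(x)) fit$assignments <- map_assign(x, fit)
  fit
}
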