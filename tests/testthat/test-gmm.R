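test_that("component density matches the Gaussian formula and integrates to one", {
  expect_equal(component_density(0, 0, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  # symmetry about the mean
  expect_equal(component_density(2 + 0.7, 2, 1.3), component_density(2 - 0.7, 2, 1.3))
  expect_error(component_density(0, 0, 0), "positive")
  # trapezoidal quadrature oracle
  g <- seq(-12, 16, length.out = 20001)
  dens <- component_density(g, 2, 1.7)
  area <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(g))
  expect_equal(area, 1, tolerance = 1e-4)
})

test_that("mixture density is the weighted component sum and integrates to one", {
  fit <- manual_fit(c(0.3, 0.7), c(-2, 3), c(1, 2))
  expect_equal(mixture_density(0, fit),
               0.3 * dnorm(0, -2, 1) + 0.7 * dnorm(0, 3, 2))
  fit1 <- manual_fit(1, 0.5, 1.2)
  expect_equal(mixture_density(1.1, fit1), component_density(1.1, 0.5, 1.2))
  # symmetric two-component mixture is symmetric about zero
  sym <- manual_fit(c(0.5, 0.5), c(-3, 3), c(1, 1))
  expect_equal(mixture_density(1.4, sym), mixture_density(-1.4, sym))
  g <- seq(-25, 30, length.out = 40001)
  dens <- mixture_density(g, fit)
  area <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(g))
  expect_equal(area, 1, tolerance = 1e-4)
})

test_that("log-likelihood matches a naive double-loop oracle", {
  expect_equal(gmm_loglik(0, manual_fit(1, 0, 1)), log(1 / sqrt(2 * pi)))
  withr::with_seed(5, {
    x <- rnorm(20, 1, 3)
  })
  fit <- manual_fit(c(0.2, 0.5, 0.3), c(-1, 0.5, 4), c(0.5, 1, 2))
  oracle <- 0
  for (xn in x) {
    total <- 0
    for (k in 1:3) total <- total + fit$weights[k] * dnorm(xn, fit$means[k], fit$sds[k])
    oracle <- oracle + log(total)
  }
  expect_equal(gmm_loglik(x, fit), oracle, tolerance = 1e-10)
  # additivity under dataset duplication
  expect_equal(gmm_loglik(c(x, x), fit), 2 * gmm_loglik(x, fit), tolerance = 1e-10)
})

test_that("BIC follows -2 logL + (3K - 1) ln N", {
  expect_equal(gmm_bic(0, 1, 1), 0)
  expect_equal(gmm_bic(-100, 2, 1000), 200 + 5 * log(1000))
  # adding a component at equal likelihood costs 3 ln N
  expect_equal(gmm_bic(-50, 4, 500) - gmm_bic(-50, 3, 500), 3 * log(500))
})

test_that("K = 1 fit is the closed-form MLE regardless of seed", {
  x <- c(1, 2, 3, 4, 10)
  f1 <- em_fit(x, 1, seed = 1)
  f2 <- em_fit(x, 1, seed = 999)
  expect_equal(f1$means, mean(x))
  expect_equal(f1$sds, sqrt(mean((x - mean(x))^2)))
  expect_equal(f1$weights, 1)
  expect_equal(f2$means, f1$means)
  expect_equal(f1$logL, gmm_loglik(x, f1))
})

test_that("EM fits are deterministic in the seed and monotone in log-likelihood", {
  x <- two_mode_signal()
  fa <- em_fit(x, 2, seed = 17, n_restarts = 3)
  fb <- em_fit(x, 2, seed = 17, n_restarts = 3)
  expect_identical(fa$means, fb$means)
  expect_identical(fa$logL, fb$logL)
  expect_true(all(diff(fa$trace) > -1e-8))
})

test_that("EM recovers a well-separated two-component mixture", {
  withr::with_seed(123, {
    x <- c(rnorm(250, 0, 1), rnorm(250, 10, 1))
  })
  fit <- em_fit(x, 2, seed = 4, n_restarts = 5)
  expect_true(fit$converged)
  expect_equal(fit$means, c(0, 10), tolerance = 0.3)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 0.05)
  expect_lt(abs(fit$logL - gmm_loglik(x, fit)), 1e-6)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  # components come out in ascending-mean order
  expect_true(!is.unsorted(fit$means))
})

test_that("EM parameters agree with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  withr::with_seed(9, {
    x <- c(rnorm(400, 0, 1), rnorm(200, 6, 1.5))
  })
  ours <- em_fit(x, 2, seed = 2, n_restarts = 5)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(ours$means, as.numeric(mc$parameters$mean), tolerance = 0.05)
  expect_equal(ours$weights, as.numeric(mc$parameters$pro), tolerance = 0.02)
  expect_equal(ours$logL, mc$loglik, tolerance = 1e-3)
})

test_that("degenerate inputs error informatively", {
  expect_error(em_fit(c(1, 2), 3, seed = 1), "at least K")
  expect_error(em_fit(rep(5, 50), 2, seed = 1), "identical")
})

test_that("BIC selection finds two components when they are well separated", {
  x <- two_mode_signal(n_per = 1000, mu = c(0, 10), seed = 99)
  fit <- select_model(x, K_max = 5, seed = 8, n_restarts = 3)
  expect_equal(fit$K, 2L)
  trace <- attr(fit, "bic_trace")
  expect_equal(trace$K, 1:5)
  expect_equal(min(trace$bic), fit$bic)
})

test_that("near-constant signals select a single component", {
  withr::with_seed(31, {
    x <- rnorm(500, 5, 0.01)
  })
  fit <- select_model(x, K_max = 4, seed = 5, n_restarts = 3)
  expect_equal(fit$K, 1L)
})

test_that("a fixed K bypasses the search", {
  x <- two_mode_signal(n_per = 100, seed = 12)
  fit <- select_model(x, K_min = 2, K_max = 2, seed = 3, n_restarts = 3)
  direct <- em_fit(x, 2, seed = 3, n_restarts = 3)
  expect_equal(fit$means, direct$means)
  expect_equal(fit$K, 2L)
})

test_that("MAP assignment matches brute-force argmax and breaks ties low", {
  fit <- manual_fit(c(0.5, 0.5), c(0, 10), c(1, 1))
  expect_equal(map_assign(1, fit), 1L)
  expect_equal(map_assign(5, fit), 1L)  # exact midpoint goes to the lower mean
  expect_equal(map_assign(5 + 1e-6, fit), 2L)
  withr::with_seed(21, {
    x <- runif(100, -5, 15)
  })
  fit3 <- manual_fit(c(0.2, 0.3, 0.5), c(0, 4, 9), c(1, 0.5, 2))
  brute <- vapply(x, function(xn) {
    which.max(fit3$weights * dnorm(xn, fit3$means, fit3$sds))
  }, integer(1))
  expect_equal(map_assign(x, fit3), brute)
  # invariance under common rescaling of all alpha_k f_k
  half <- fit3
  half$weights <- fit3$weights / 2  # no longer normalized, same argmax
  expect_equal(map_assign(x, half), map_assign(x, fit3))
})

test_that("binned and exact EM agree on large signals", {
  x <- two_mode_signal(n_per = 3000, mu = c(0, 8), seed = 77)
  binned <- em_fit(x, 2, seed = 5, n_restarts = 3, n_bins = 512)
  exact <- em_fit(x, 2, seed = 5, n_restarts = 3, n_bins = Inf)
  expect_equal(binned$means, exact$means, tolerance = 0.02)
  expect_equal(binned$weights, exact$weights, tolerance = 0.005)
  expect_equal(binned$logL, exact$logL, tolerance = 1)
  # reported logL is always the exact full-data value for the stored params
  expect_equal(binned$logL, gmm_loglik(x, binned), tolerance = 1e-8)
})

test_that("fits serialize to JSON and back", {
  x <- two_mode_signal(n_per = 100, seed = 3)
  fit <- em_fit(x, 2, seed = 6, n_restarts = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_gmm(fit, path)
  back <- read_gmm(path)
  expect_equal(back$means, fit$means)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$sds, fit$sds)
  expect_equal(back$logL, fit$logL)
  expect_equal(back$K, fit$K)
  # reread fit reproduces the MAP assignments
  expect_equal(map_assign(x, back), fit$assignments)
})

test_that("tidy and glance summarize fits", {
  x <- two_mode_signal(n_per = 50, seed = 8)
  fit <- em_fit(x, 2, seed = 1, n_restarts = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$n_genes), 100)
  gl <- glance(fit)
  expect_equal(gl$K, 2L)
  expect_equal(gl$BIC, fit$bic)
})
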