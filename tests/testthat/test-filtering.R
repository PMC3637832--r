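test_that("top3 keeps the three highest-mean components and degenerates to NF", {
  fit5 <- manual_fit(rep(0.2, 5), c(1, 3, 5, 7, 9), rep(1, 5))
  sel <- select_top3(fit5)
  expect_equal(sel$retained, 3:5)
  expect_false(sel$nf_equivalent)
  for (K in 1:3) {
    fitK <- manual_fit(rep(1 / K, K), seq_len(K), rep(1, K))
    selK <- select_top3(fitK)
    expect_equal(selK$retained, seq_len(K))
    expect_true(selK$nf_equivalent)
  }
})

test_that("2-means selection removes the lower-mean cluster", {
  # two components always split into singletons; the higher mean survives
  fit2 <- manual_fit(c(0.6, 0.4), c(0, 10), c(1, 1.2))
  expect_equal(select_kmeans2(fit2)$retained, 2L)
  # the gap dominates: components 3,4 form the high cluster
  fit4 <- manual_fit(rep(0.25, 4), c(0, 0.5, 9, 10), rep(0.5, 4))
  expect_equal(select_kmeans2(fit4)$retained, 3:4)
  # K = 1 degenerates to NF
  sel1 <- select_kmeans2(manual_fit(1, 2, 1))
  expect_equal(sel1$retained, 1L)
  expect_true(sel1$nf_equivalent)
})

test_that("exact bipartition matches the k-means objective on random component sets", {
  withr::with_seed(14, {
    for (rep in 1:20) {
      K <- sample(3:8, 1)
      pts <- cbind(runif(K, 0, 10), runif(K, 0.2, 2), runif(K, 0.05, 1))
      part <- gmmfilt:::best_bipartition(pts)
      ours <- gmmfilt:::cluster_ss(pts[part[[1]], , drop = FALSE]) +
        gmmfilt:::cluster_ss(pts[part[[2]], , drop = FALSE])
      km <- kmeans(pts, centers = 2, nstart = 50)
      expect_lte(ours, km$tot.withinss + 1e-8)
    }
  })
})

test_that("component masks follow MAP membership", {
  x <- c(-0.1, 0.1, 4.9, 5.1, 10)
  fit <- manual_fit(rep(1 / 3, 3), c(0, 5, 10), rep(0.5, 3), x = x)
  sel <- structure(list(retained = 2:3, rule = "kmeans2",
                        nf_equivalent = FALSE, centroids = NULL),
                   class = "component_selection")
  mask <- component_filter_mask(fit, sel)
  expect_equal(mask$retained, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(attr(mask, "removed_fraction"), 0.4)
  all_sel <- structure(list(retained = 1:3, rule = "top3",
                            nf_equivalent = TRUE, centroids = NULL),
                       class = "component_selection")
  expect_true(all(component_filter_mask(fit, all_sel)$retained))
  bad <- structure(list(retained = 4L, rule = "kmeans2", nf_equivalent = FALSE,
                        centroids = NULL), class = "component_selection")
  expect_error(component_filter_mask(fit, bad), "beyond")
})

test_that("fixed-proportion filter removes exactly floor(N P / 100) smallest-signal genes", {
  sig <- gmmfilt:::new_filter_signal(paste0("g", 1:5), c(5, 1, 4, 2, 3), "S")
  f40 <- fixed_proportion_filter(sig, 40)
  expect_equal(f40$retained, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(attr(f40, "removed_fraction"), 0.4)
  expect_equal(sum(!fixed_proportion_filter(sig, 50)$retained), 2)  # floor(2.5)
  expect_true(all(fixed_proportion_filter(sig, 0)$retained))
  expect_error(fixed_proportion_filter(sig, 100), "percentage")
  withr::with_seed(3, {
    x <- rnorm(200)
  })
  sig2 <- gmmfilt:::new_filter_signal(paste0("g", 1:200), x, "S")
  for (P in c(10, 25, 50, 90)) {
    expect_equal(sum(!fixed_proportion_filter(sig2, P)$retained), floor(200 * P / 100))
  }
})

test_that("fixed filters are nested: a harsher cut retains a subset", {
  withr::with_seed(8, {
    x <- rnorm(300, 7)
  })
  sig <- gmmfilt:::new_filter_signal(paste0("g", 1:300), x, "S")
  prev <- fixed_proportion_filter(sig, 10)$retained
  for (P in c(30, 50, 70, 90)) {
    cur <- fixed_proportion_filter(sig, P)$retained
    expect_true(all(!cur | prev))  # cur => prev
    prev <- cur
  }
})

test_that("adaptive masks retain exactly the high-mean components when separation is large", {
  x <- two_mode_signal(n_per = 400, mu = c(0, 12), sd = 1, seed = 5)
  mask <- adaptive_filter(x, rule = "kmeans2", K_mode = "fixed", seed = 2,
                          n_restarts = 3)
  fit <- attr(mask, "fit")
  sel <- attr(mask, "selection")
  # every retained component mean exceeds every removed component mean
  removed <- setdiff(seq_len(fit$K), sel$retained)
  expect_true(min(fit$means[sel$retained]) > max(fit$means[removed]))
  # the mask splits at the modes: low half removed
  expect_equal(mask$retained, x > 6, ignore_attr = TRUE)
})

test_that("filter masks ignore class labels entirely", {
  d <- simulate_expression(sim_config(n_genes = 1500, seed = 44))
  sig <- compute_signal(d$matrix, "S")
  mask <- adaptive_filter(sig, rule = "kmeans2", K_mode = "fixed", seed = 9,
                          n_restarts = 3)
  # permuting sample columns (hence any label assignment) leaves the mask unchanged
  perm <- withr::with_seed(1, sample(n_samples(d$matrix)))
  mperm <- expression_matrix(d$matrix$values[, perm], "log2")
  sig_p <- compute_signal(mperm, "S")
  mask_p <- adaptive_filter(sig_p, rule = "kmeans2", K_mode = "fixed", seed = 9,
                            n_restarts = 3)
  expect_equal(mask$retained, mask_p$retained)
})

test_that("filter masks round-trip through TSV", {
  sig <- gmmfilt:::new_filter_signal(paste0("g", 1:6), c(3, 1, 2, 6, 5, 4), "S")
  f <- fixed_proportion_filter(sig, 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_filter(f, path)
  back <- read_filter(path)
  expect_equal(back$gene_id, f$gene_id)
  expect_equal(back$retained, f$retained)
})
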