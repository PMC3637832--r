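#' Configuration for the two-group expression simulator
#'
#' Describes a simulated two-group microarray experiment on the log2 scale:
#' `n_genes` genes by `2 * n_per_group` samples, a fraction `prop_eeg` of
#' equally expressed genes (EEGs), the rest true DEGs. Gene baselines are
#' bimodal — an unexpressed/background mode and an expressed mode — because
#' that is the structure adaptive mean filtering exploits on real arrays;
#' per-gene noise standard deviations are lognormal; DEG effects are uniform
#' log2 fold changes with random sign, applied to group 2. True DEGs are
#' drawn only from the expressed mode. Under `dependence = "clumpy"`,
#' consecutive blocks of `block_size` genes share a per-sample Gaussian
#' effect of standard deviation `block_sd`, inducing within-block
#' correlation, and DEG labels are assigned blockwise so that DEGs co-occur
#' in clumps.
#'
#' Defaults (5 vs 5 samples, 50,000 genes, 85% EEGs, clumpy blocks of 50)
#' mirror the benchmark conditions this package is evaluated under; all
#' distribution parameters are exposed. See the methods vignette for how the
#' defaults were chosen and what they approximate.
#'
#' @param n_genes Number of genes (default 50000).
#' @param n_per_group Samples per group (default 5).
#' @param prop_eeg Proportion of equally expressed genes in `[0, 1]`
#'   (default 0.85); the DEG count is `round(n_genes * (1 - prop_eeg))`.
#' @param dependence `"clumpy"` (default) or `"independent"`.
#' @param block_size Genes per dependence block (default 50).
#' @param block_sd Standard deviation of the shared per-(block, sample)
#'   effect (default 0.2 log2 units; 0 disables the dependence).
#' @param p_unexpressed Probability that an EEG gene belongs to the
#'   unexpressed baseline mode (default 0.85, consistent with the large
#'   removed fractions adaptive filters produce on real arrays).
#' @param unexpressed_mean,unexpressed_sd Baseline log2 mean distribution of
#'   unexpressed genes (defaults 4 and 1).
#' @param expressed_mean,expressed_sd Baseline distribution of expressed
#'   genes (defaults 9 and 1).
#' @param sd_meanlog,sd_sdlog Lognormal parameters of the per-gene noise sd
#'   (defaults give a median sd of 0.58 log2 units).
#' @param effect_range Range of absolute DEG effect sizes in log2 units
#'   (default `c(1, 2)`), sign random.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 50000L, n_per_group = 5L, prop_eeg = 0.85,
                       dependence = c("clumpy", "independent"),
                       block_size = 50L, block_sd = 0.2,
                       p_unexpressed = 0.85,
                       unexpressed_mean = 4, unexpressed_sd = 1,
                       expressed_mean = 9, expressed_sd = 1,
                       sd_meanlog = log(0.58), sd_sdlog = 0.2,
                       effect_range = c(1, 2), seed = 1L) {
  dependence <- match.arg(dependence)
  stopifnot(n_genes >= 1, n_per_group >= 2, prop_eeg >= 0, prop_eeg <= 1,
            block_size >= 1, block_sd >= 0, p_unexpressed >= 0,
            p_unexpressed <= 1, unexpressed_sd > 0, expressed_sd > 0,
            sd_sdlog > 0, length(effect_range) == 2,
            effect_range[1] > 0, diff(effect_range) >= 0)
  structure(list(
    n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
    prop_eeg = prop_eeg, dependence = dependence,
    block_size = as.integer(block_size), block_sd = block_sd,
    p_unexpressed = p_unexpressed,
    unexpressed_mean = unexpressed_mean, unexpressed_sd = unexpressed_sd,
    expressed_mean = expressed_mean, expressed_sd = expressed_sd,
    sd_meanlog = sd_meanlog, sd_sdlog = sd_sdlog,
    effect_range = as.numeric(effect_range), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a two-group expression dataset with known truth
#'
#' Generates a log2-scale expression matrix plus ground-truth DEG labels
#' under the scenario described by [sim_config()]. Sample values are
#' `baseline + group effect + block effect + noise`, all Gaussian on the
#' log2 scale.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_dataset`: list with `matrix` (an [expression_matrix()]),
#'   `truth` (tibble: `gene_id`, `is_deg`, `expressed`, `baseline_mean`,
#'   `noise_sd`, `effect`), `labels` (tibble: `sample_id`, `group`) and
#'   `config`.
#' @examples
#' d <- simulate_expression(sim_config(n_genes = 500, seed = 3))
#' sum(d$truth$is_deg)
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  N <- cfg$n_genes
  M <- 2L * cfg$n_per_group
  n_deg <- as.integer(round(N * (1 - cfg$prop_eeg)))

  withr::with_seed(cfg$seed, {
    # 1. truth labels
    is_deg <- rep(FALSE, N)
    if (n_deg > 0) {
      if (cfg$dependence == "clumpy") {
        n_blocks <- ceiling(N / cfg$block_size)
        block_of <- rep(seq_len(n_blocks), each = cfg$block_size)[seq_len(N)]
        block_order <- sample.int(n_blocks)
        picked <- unlist(lapply(block_order, function(b) which(block_of == b)))
        is_deg[picked[seq_len(n_deg)]] <- TRUE
      } else {
        is_deg[sample.int(N, n_deg)] <- TRUE
      }
    }

    # 2. gene-level parameters: DEGs always come from the expressed mode
    expressed <- is_deg | (stats::runif(N) > cfg$p_unexpressed)
    baseline <- ifelse(expressed,
                       stats::rnorm(N, cfg$expressed_mean, cfg$expressed_sd),
                       stats::rnorm(N, cfg$unexpressed_mean, cfg$unexpressed_sd))
    noise_sd <- stats::rlnorm(N, cfg$sd_meanlog, cfg$sd_sdlog)
    effect <- numeric(N)
    if (n_deg > 0) {
      effect[is_deg] <- stats::runif(n_deg, cfg$effect_range[1], cfg$effect_range[2]) *
        sample(c(-1, 1), n_deg, replace = TRUE)
    }

    # 3. sample values
    group2 <- c(rep(0, cfg$n_per_group), rep(1, cfg$n_per_group))
    X <- baseline + outer(effect, group2) +
      matrix(stats::rnorm(N * M), N, M) * noise_sd
    if (cfg$dependence == "clumpy" && cfg$block_sd > 0) {
      n_blocks <- ceiling(N / cfg$block_size)
      block_of <- rep(seq_len(n_blocks), each = cfg$block_size)[seq_len(N)]
      B <- matrix(stats::rnorm(n_blocks * M, 0, cfg$block_sd), n_blocks, M)
      X <- X + B[block_of, , drop = FALSE]
    }
  })

  gid <- sprintf("g%06d", seq_len(N))
  sid <- sprintf("s%02d", seq_len(M))
  labels <- tibble::tibble(
    sample_id = sid,
    group = factor(rep(c("group1", "group2"), each = cfg$n_per_group))
  )
  m <- expression_matrix(X, scale = "log2", gene_ids = gid, sample_ids = sid)
  structure(list(
    matrix = m,
    truth = tibble::tibble(gene_id = gid, is_deg = is_deg, expressed = expressed,
                           baseline_mean = baseline, noise_sd = noise_sd,
                           effect = effect),
    labels = labels,
    config = cfg
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d genes x %d samples, %d true DEGs (%.1f%%), %s dependence, seed %d\n",
              n_genes(x$matrix), n_samples(x$matrix), sum(x$truth$is_deg),
              100 * mean(x$truth$is_deg), x$config$dependence, x$config$seed))
  invisible(x)
}
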