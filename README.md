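# gmmfilt

Adaptive nonspecific gene filtering for two-group differential expression
studies, by Gaussian mixture decomposition of per-gene summary signals.

## The problem

With tens of thousands of genes and a handful of samples per group,
FDR control makes differential expression calls expensive: every
uninformative probe set carried into the multiple-testing step costs
sensitivity. Two-step procedures first remove a pool of non-informative
genes using a statistic that is blind to the class labels (so FDR control
on the survivors remains valid), then test only the retained pool. The
classical filters cut a *fixed* proportion — usually the 50% of genes with
the smallest mean or variance — although the right amount to cut differs
from dataset to dataset.

`gmmfilt` makes the cut adaptive. The per-gene filter signal
(`S` = mean of log2 expression, `V` = log variance on the original scale,
`LV` = log variance on the log2 scale) is decomposed into a univariate
Gaussian mixture

$$f(x) = \sum_{k=1}^{K} \alpha_k\, f_k(x;\mu_k,\sigma_k), \qquad \sum_k \alpha_k = 1,$$

fitted by EM, with the number of components chosen by minimizing
$\mathrm{BIC} = -2\log L + (3K-1)\ln N$ over $K = 1\ldots15$. Each gene is
assigned to a component by the MAP rule
($\arg\max_k \alpha_k f_k(x_n)$), and whole low-signal components are
removed by one of two rules:

* **top3** — keep the three components with the largest means
  (equivalent to no filtering when $K \le 3$);
* **k-means** — split the component parameter triples
  $(\mu_k, \sigma_k, \alpha_k)$ into two clusters and drop the cluster
  lying lower along the mean coordinate.

Downstream, the retained genes get an equal-variance two-sample t-test and
Storey–Tibshirani q-value FDR correction, with calls at $q \le 0.05$. The
package also ships the fixed-proportion comparators (`S_50`, `V_50`, …),
sensitivity-versus-FDR ROC evaluation with partial AUC and F1, a
two-group microarray simulator (independent or clumpy-dependent genes)
with known truth, and a replicated benchmark driver.

## Worked example

```r
library(gmmfilt)

d <- simulate_expression(sim_config(n_genes = 20000, seed = 42))
d
#> <sim_dataset> 20000 genes x 10 samples, 3000 true DEGs (15.0%), clumpy dependence, seed 42

res <- run_pipeline(d$matrix, d$labels, filter_method = "S",
                    rule = "kmeans2", K_mode = "bic", seed = 7)
res
#> <pipeline_result> S/kmeans2: removed 72.4% (K = 2), 2590 rejections at q <= 0.05

tidy(res$fit)
#> # A tibble: 2 x 5
#>   component weight  mean    sd n_genes
#>       <int>  <dbl> <dbl> <dbl>   <int>
#> 1         1  0.723  4.01  1.01   14486
#> 2         2  0.277  9.02  1.18    5514
```

BIC found two components in the mean signal: an unexpressed mode around
4 log2 units holding 72% of the genes and an expressed mode around 9. The
k-means rule removed the low cluster, and the q-value step then tested
only the 5,514 survivors — 2,590 DEG calls at 5% FDR, versus 1,626 for the
same data unfiltered:

```r
run_pipeline(d$matrix, d$labels, "NF")
#> <pipeline_result> NF/none: removed 0.0%, 1626 rejections at q <= 0.05
```

Against the known truth, filtering raises the sensitivity attainable at
5% realized FDR from 47% to 84%:

```r
tt <- t_test_genes(d$matrix, d$labels)
sensitivity_at_fdr(roc_fdr_sens(tt$p, d$truth$is_deg, res$filter$retained))
#> [1] 0.8443333
sensitivity_at_fdr(roc_fdr_sens(tt$p, d$truth$is_deg))
#> [1] 0.474
```

`autoplot(res$fit)` draws the signal histogram with the fitted components;
`run_benchmark()` / `summarize_benchmark()` repeat the whole exercise over
replicated simulations and report median metrics per filtering method. A
command-line wrapper with `fit` / `filter` / `degs` / `simulate` /
`benchmark` subcommands is installed at `inst/cli/gmmfilt.R`.

Real datasets load with `read_expression()` (TSV/CSV/GCT; values must
already be RMA-style normalized, log2 scale) and `read_labels()`.

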