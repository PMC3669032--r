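# bihemi

Bilateral transcriptomic response analysis after unilateral brain injury.

Unilateral traumatic brain injury triggers a strong local (ipsilateral)
pro-inflammatory transcriptional program and a distinct, largely suppressive
remote response in the opposite (contralateral) hemisphere. `bihemi` is an R
implementation of the screening-and-ranking workflow used to dissect such
three-group designs (ipsilateral, contralateral, naive; typically n = 3
each), for analysts working with MAS5-style summarized microarray signals
and detection calls — or with the package's own synthetic data.

## What it computes

Given a signal matrix with Present/Marginal/Absent calls:

1. **Screening** — a gene is *changed* in a contrast
   (TBI-I = ipsilateral vs naive, TBI-C = contralateral vs naive) when its
   signed fold change fc (magnitude ≥ 1, sign = direction; −4 means 4-fold
   down) satisfies |fc| ≥ 2 and the gene is called Present in all samples of
   at least one hemisphere.
2. **Bilateral classification** — genes changed on both sides get the
   piecewise fold ratio

   r = ℓ(fc_I)/ℓ(fc_C),  where ℓ(x) = x for x ≥ 1 and 1/|x| for x ≤ −1,

   which reduces to fc_I/fc_C (both up), 1/(fc_I/fc_C) (both down) and
   fc_I·|fc_C| (up ipsi / down contra). r > 1.75 (strict) means the gene
   "changed differently" across hemispheres. All changed genes fall into a
   common/unique-per-side × up/down partition with summary percentages.
3. **Functional overlap** — per-function overlap percentage with an
   inflammatory-response (IR) gene set, the pooled cumulative overlap, and a
   one-sided hypergeometric (Fisher's exact) enrichment p-value.
4. **Gene interaction hierarchy (GIH)** — genes of interest (GOI) are tiered
   by their number of direct (1st-order) connections with the other GOI in
   an interaction network: >10 primary, 5–10 secondary, 1–4 peripheral,
   0 orphan.

I/O covers the standard plain-text formats: paired signal/call TSV, GMT gene
sets, SIF or two-column edge lists, and TSV result tables. Curated example
tables from a published rat controlled cortical impact study are bundled
(`example_divergent_genes()`, `example_function_overlaps()`,
`example_goi_hierarchy()`), and synthetic generators with known ground truth
(`simulate_expression()`, `simulate_network()`) make the whole pipeline
testable offline.

## Worked example

```r
library(bihemi)

# ratios for three reported divergent genes: up/down, down/down, up/down
round(fold_ratio(c(4.22, -4.00, 2.31), c(-3.77, -7.97, -3.28)), 2)
#> [1] 15.91  1.99  7.58

# a study-shaped synthetic experiment: 1000 genes, 3 x 3 samples,
# 372 planted responsive genes in the reported class sizes
sim <- simulate_expression(seed = 17)
records <- fold_change_records(sim$dataset, threshold = 2)
classes <- classify_bilateral(records)
summarize_partition(classes)
#> <partition_summary>
#>   changed genes: 372 (common 144, ipsi-unique 190, contra-unique 38)
#>   common: 76% similar (55% up, 21% down), 24% different
#>   ipsi-unique: 95% up / 5% down; contra-unique: 26% up / 74% down
```

At the default noise (multiplicative, sd 0.1 on the log scale) the recovered
breakdown sits within a couple of genes of the planted 146/188/38 split; with
`noise_sd = 0` recovery is exact. The hierarchy side:

```r
net <- simulate_network(seed = 17)           # planted tiers 20/34/41/19
gih <- build_gih(net$network, net$truth$symbol)
attr(gih, "tier_totals")
#>    primary  secondary peripheral     orphan
#>         20         34         41         19
attr(gih, "n_connected")
#> [1] 95

cumulative_overlap(example_function_overlaps())
#> [1] 39.3
```

The tier totals and the 95 interconnected genes are recovered exactly from
the noise-free generated network, and the pooled overlap of the 14 bundled
function sets with the IR set is 39.3%.

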