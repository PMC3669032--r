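---
title: "Bilateral transcriptomic analysis: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral transcriptomic analysis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bihemi)
```

## The analysis in one paragraph

A unilateral brain injury (e.g. controlled cortical impact in rat) produces a
local molecular response at the impact site and a distinct remote response in
the opposite hemisphere. Given a three-group expression experiment —
ipsilateral, contralateral and naive tissue, typically three replicates
each — this package screens genes by detection-call presence and a 2-fold
change criterion in the two contrasts TBI-I (ipsilateral vs naive) and TBI-C
(contralateral vs naive), classifies genes changed on *both* sides by how
differently the two hemispheres responded, quantifies how much candidate
biological functions overlap an inflammatory-response (IR) gene set, and
finally ranks genes of interest (GOI) into a gene interaction hierarchy
(GIH) by the number of direct connections each has with the other GOI in an
interaction network.

## Differential screening

Signals are MAS5-style positive intensities, assumed already normalized
across arrays. Replicates are summarized by the arithmetic mean
(`summary = "geomean"` switches to the geometric mean); the chip-level
summarization that produced the signals is upstream of this package, and
whether fold changes are computed per chip and averaged or from averaged
signals is a genuine free choice — we compute them from averaged signals and
state it here.

The signed fold change of case mean $a$ over control mean $b$ is

$$\mathrm{fc}(a,b) \;=\; \begin{cases} a/b & a \ge b \\ -\,b/a & a < b,\end{cases}$$

so magnitudes are always $\ge 1$ and the sign is the direction
($-4$ = 4-fold decrease). Equal means give $+1$ by convention. A gene is
*changed* in a contrast when $|\mathrm{fc}| \ge 2$ (the boundary is
inclusive: "2-fold or more") **and** it passes the presence rule: called
Present in *all* ipsilateral samples or in *all* contralateral samples.
Marginal calls count as not-present — the strict reading of "present". No
p-values enter gene selection; that mirrors the screening design this
pipeline implements, not a statistical recommendation.

## The TBI-I/TBI-C fold ratio

For a gene changed on both sides, divergence between hemispheres is measured
by a piecewise ratio. Writing $\ell(x) = x$ for $x \ge 1$ and $1/|x|$ for
$x \le -1$ (the linear expression ratio a signed fold change encodes), the
three documented sign cases — both up, $\mathrm{fc_I}/\mathrm{fc_C}$; both
down, $1/(\mathrm{fc_I}/\mathrm{fc_C})$; up-ipsilateral/down-contralateral,
$\mathrm{fc_I} \cdot |\mathrm{fc_C}|$ — are all exactly
$\ell(\mathrm{fc_I})/\ell(\mathrm{fc_C})$, and `fold_ratio()` is implemented
as that single expression.

The fourth sign case (down ipsilaterally, up contralaterally) has no
documented formula and does not occur in the study data. The faithful
linear-scale extension $\ell(\mathrm{fc_I})/\ell(\mathrm{fc_C})$ is the
default; it is always $< 1$ for this case, hence "similar". Because a gene
suppressed locally but induced remotely is arguably the *most* divergent
pattern, `mode = "symmetric"` instead returns $\max(r, 1/r)$ so divergence
in either direction exceeds the threshold. Faithfulness wins as the default;
the semantic alternative is opt-in.

A gene "changed differently" when its ratio is **strictly** greater than
1.75; a ratio of exactly 1.75 is "similar". Classification always uses
unrounded ratios; the two-decimal rendering in output tables is display
only (half-up). On the bundled table of 37 divergent genes, ratios
recomputed from the printed two-decimal fold changes agree with the printed
ratios to within ±0.03 — the drift of rounding fold changes before taking
their ratio — and exactly at two decimals for several rows (STAT3, TGFB2,
CBL, CCND1, RASA1).

```{r}
div <- example_divergent_genes()
head(cbind(div[, c("symbol", "fc_ipsi", "fc_contra", "ratio")],
           recomputed = round(fold_ratio(div$fc_ipsi, div$fc_contra), 2)))
```

Changed genes partition into eight categories — common-similar-up/down,
common-different, unique per side up/down, unchanged — and
`summarize_partition()` reports the percentages with the denominators used
in the original breakdown: similar/different and similar-up/down over the
common total, unique up/down over each side's unique total, integers rounded
half-up. Zero denominators yield `NA` rather than an error.

## Functional overlap

`overlap_percent()` divides the IR intersection by the *function set's*
size (the IR set itself is not a row), rounding half-up to integers; the
printed values cannot distinguish half-up from truncation, and half-up is
consistent with every row (e.g. 216/231 = 93.5% → 94%). The cumulative
overlap is the pooled-count ratio $\sum \mathrm{overlap} / \sum
\mathrm{unique}$ to one decimal — the only definition that reproduces the
reported 39.3% from the per-function counts (2675/6804). `enrichment_pvalue()`
is the one-sided hypergeometric tail $P[X \ge k]$ (Fisher's exact test for
over-representation); the gene universe is the analyst's choice, and a
sensible default is the number of genes passing the presence filter.

## The gene interaction hierarchy

The GOI subnetwork keeps only direct (1st-order) edges between GOI; GOI
absent from the supplied network are retained as isolated nodes. A gene's
connection count is its number of distinct neighbours, self excluded. Tiers:
more than 10 connections, primary; 5–10, secondary; 1–4, peripheral; none,
orphan. "Orphan" means degree zero in the induced subnetwork, not "outside
the largest component": connections were counted by selecting nearest
neighbours, i.e. by degree. Within a tier, entries are laid out by cellular
compartment (extracellular space, plasma membrane, cytoplasm, nucleus,
unknown), then molecule type, then symbol — a deterministic emulation of the
conventional table layout. Group/complex nodes in a user-supplied network
are treated as ordinary nodes; expanding them would require a proprietary
knowledge base, and this approximation is documented rather than hidden. The
bundled 114-gene GOI table (`example_goi_hierarchy()`) supports
demonstration runs against any public interaction network.

```{r}
sim <- simulate_network(seed = 7)
gih <- build_gih(sim$network, sim$truth$symbol)
attr(gih, "tier_totals"); attr(gih, "n_connected")
```

## What the generators emulate — and what they do not

`simulate_expression()` emulates the structure of a three-group,
three-replicate microarray experiment: log-normal baseline signals (defaults
meanlog 6, sdlog 1, i.e. median ≈ 400, right-skewed and positive as MAS5
signals are), multiplicative log-normal replicate noise (default sd 0.1 on
the natural-log scale), and planted signed effects per class. Default class
sizes mirror the bilateral IR partition of the emulated study — 146 common
genes (109 similar: 79 up, 30 down; 37 different), 188 ipsilateral-unique
(179 up, 9 down), 38 contralateral-unique (10 up, 28 down) — so
demonstration output is shaped like the published breakdown, with the
remaining genes null. Planted "similar" pairs keep their fold ratio at or
below 1.4 and "different" pairs at or above 2.2, placing both classes safely
away from the 1.75 boundary so that zero-noise recovery is exact by
construction. Detection calls derive from an absolute signal floor (default
30) rather than a simulated detection test: the floor reproduces the
behaviour the presence filter must exercise without modelling probe-level
machinery. Null genes receive forced-Absent calls at a configurable rate.
Baselines of changed genes are lifted to at least four times the floor times
their largest planted down-fold, so down-regulated genes remain detectable.

Not emulated: probe-level intensities, mean–variance trends, spatial chip
artifacts, batch effects, and correlated genes. Passing tests on this
generator therefore show the *pipeline logic* is correct under the stated
noise model — not that any biological conclusion transfers to real arrays.

`simulate_network()` draws per-tier target degrees (primary 11–20, secondary
5–10, peripheral 1–4, orphan 0 by default, tier sizes 20/34/41/19), fixes
parity inside a tier range, verifies the sequence is graphical, and realizes
it as a simple undirected graph — a uniform connected realization where the
sampler accepts the sequence, otherwise a deterministic Havel–Hakimi
construction. The connected realization also reproduces the single
95-node interconnected component of the emulated study. Optional
per-edge rewiring noise degrades tier recoverability gracefully.

## Numerical and scale choices

* PCA (`pca_scores()`) is a QC tool: gene-wise mean-centering of
  `log2(signal + 1)` (the transform is standard practice and can be
  disabled), SVD, sample scores from the right singular vectors scaled by
  the singular values, variance fractions from squared singular values.
  Component signs are fixed by making each component's largest-magnitude
  gene loading positive. A constant matrix returns zero fractions, not
  `NaN`. Published variance-explained figures from other software are not
  reproducible without the original preprocessing, which is why this module
  makes no such claim and is used only to confirm that samples cluster by
  group.
* Integer percentages round half away from zero everywhere; `base::round()`
  half-to-even would disagree at ties (20.5, 37.5).
* Ties in `signed_fold_change()` (equal means) return +1, a deterministic
  tie-break.
* Symbols are matched case-sensitively after whitespace stripping; no alias
  resolution is attempted.
* Test suites and examples use simulations of roughly 300–1000 genes, nine
  samples and ~114-node networks — the scale of the emulated study design —
  which keeps every check well under a second.

## Known limitations

The pipeline consumes summarized signals and calls; it does not summarize
probes, normalize arrays, fetch public repositories, or score networks. Each
input row is treated as one gene (no probe-to-gene collapsing beyond "first
annotation wins"). The curated GOI list is reproducible only as a bundled
table, since deriving it required proprietary pathway-analysis overlays; the
hierarchy *logic* is fully reproducible against any user-supplied edge list.
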