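---
title: "Choosing stable RT-qPCR reference genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing stable RT-qPCR reference genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgstab)
```

# The problem

Relative RT-qPCR quantification divides a target gene's signal by that of
one or more reference ("housekeeping") genes, on the assumption that the
references are expressed at a constant level in every sample. That
assumption fails often enough — classic references such as actins drift
across tissues and developmental stages — that candidate reference genes
are routinely screened empirically: a panel of candidates is measured by
qPCR across the sample set of interest, each candidate's expression
stability is scored by several statistics, and the scores are aggregated
into a consensus ranking. `rgstab` implements that entire workflow on
quantification-cycle (Ct) tables, plus the two computations that surround
it in practice: amplification-efficiency estimation from dilution series,
and normalization of a target gene to the chosen reference set.

A Ct value is the PCR cycle at which fluorescence crosses threshold; one
cycle corresponds to roughly a doubling of template, so *lower* Ct means
*higher* expression and differences in Ct are log-scale quantities.

# Data model

The package's central container is the `ct_matrix`: genes × samples ×
technical replicates of Ct values on the raw cycle scale, with optional
per-sample group labels (tissue classes). All transforms are explicit:

* `collapse_replicates()` averages technical replicates per well
  (arithmetic mean of Ct by default, median as a robust alternative).
  Averaging on the cycle scale is the convention of the classical stability
  tools; it corresponds to a geometric mean on the linear scale.
* `to_relative_quantity()` maps Ct to linear relative quantities
  $Q_{gs} = E_g^{\min_s Ct_{gs} - Ct_{gs}}$, where $E_g$ is gene $g$'s
  per-cycle amplification factor ($E = 2$ at 100% efficiency). Each gene's
  best-expressed sample is the calibrator, so $\max_s Q_{gs} = 1$.

Missing wells are tolerated by the data model (real plates have dropouts)
but rejected by the stability statistics rather than imputed: silent
imputation changes the standard deviations that the statistics are made of,
and there is no principled default rule. The caller decides whether to drop
samples or genes.

# The four stability statistics

**Comparative delta-Ct** (`deltact_stability`). For every ordered pair of
genes $(j,k)$, the standard deviation across samples of
$Ct_j - Ct_k$; the stability of $j$ is the mean over partners $k \ne j$.
Shared per-sample effects (cDNA input, loading) cancel in the difference.
Units: cycles.

**geNorm** (`genorm_m_values`, `genorm_ranking`). On relative quantities,
the pairwise variation $V_{jk} = \mathrm{sd}_s\,\log_2(Q_{js}/Q_{ks})$ and
$M_j = \mathrm{mean}_{k \ne j} V_{jk}$. With all efficiencies equal to 2,
$\log_2(Q_j/Q_k)$ differs from $Ct_j - Ct_k$ only by a constant, so $M$
equals the delta-Ct statistic exactly — a cross-check the test suite
asserts. The ranking procedure iteratively removes the gene with the
largest $M$ and recomputes, until two genes survive; those two cannot be
ordered against each other (a pair's $M$ values are identical), so both
receive rank 1 and the next-best gene rank 3. Ties in the elimination step
are broken deterministically by removing the later gene in input order, and
the tie is reported. `genorm_pairwise_variation` reports the
$V(n/n+1)$ series that guides how many reference genes to use; the classic
0.15 screening threshold is deliberately *not* applied automatically.

**NormFinder** (`normfinder_stability`). A model-based decomposition of
$y = \log_2 Q$ into gene effects, sample effects and gene-specific error:
$y_{gs} = \alpha_g + \beta_s + \varepsilon_{gs}$,
$\mathrm{Var}(\varepsilon_{gs}) = \sigma_g^2$. Double centering gives
residuals whose expected sums of squares mix all genes' variances; with $G$
genes and $S_g = \mathrm{RSS}_g/(n-1)$, the unbiased estimate is
$$\hat\sigma_g^2 = \frac{G}{G-2}\Big(S_g - \frac{\sum_h S_h}{G(G-1)}\Big),$$
floored at zero before taking the square root (the stability value). With
sample groups, the intragroup variance $\hat\gamma_{gk}^2$ is estimated the
same way within each group $k$, the intergroup bias $d_{gk}$ is the
gene-by-group mean doubly centered for gene and group effects and shrunk by
its own sampling variance ($\tilde d^2 = \max(0, \hat d^2 -
\hat\gamma^2/n_k)$), and the stability value averages
$|\tilde d_{gk}| + \sqrt{\hat\gamma_{gk}^2/n_k}$ over groups. Grouped and
ungrouped stability values differ; because whether to declare groups is a
study-design decision the pipeline default is **ungrouped**, with grouping
one switch away.

**BestKeeper** (`bestkeeper_stats`, `bestkeeper_ranking`). Descriptive
statistics on raw Ct: per gene the SD about the arithmetic mean, the
coefficient of variation $100 \cdot \mathrm{SD}/\mathrm{mean}$ (percent of
mean Ct) and the geometric-mean Ct; per sample the BestKeeper index (the
geometric mean of all genes' Ct); per gene the Pearson correlation with
that index. Because it works on raw Ct, BestKeeper — unlike the other
three — *sees* shared per-sample effects; that difference is asserted in
the invariance tests. The ranking criterion defaults to SD, with CV as a
configurable alternative since published reports are ambiguous about which
they used; the two orders genuinely differ when genes with similar SD sit
at different expression levels.

# Consensus ranking

Within each method, genes are ranked by ascending stability value with
competition ("1224") ranks: ties share the minimum rank and the next
distinct value skips accordingly. `geometric_mean_ranks()` aggregates the
gene × method rank matrix as
$G_g = (\prod_m r_{gm})^{1/M}$ — the plain unweighted geometric mean of
ranks, the arithmetic the consensus-ranking web tools describe — and orders
genes by the unrounded score, again with competition ranks. Display values
are rounded half away from zero to 2 decimals (base `round()` rounds half
to even, which would disagree with published tables). The package bundles
the per-method ranks of a published 11-gene loquat candidate panel
(`loquat_panel_ranks()`); aggregating them reproduces that survey's printed
comprehensive scores at 2-decimal precision for every internally consistent
cell, which the acceptance tests pin down. One printed cell (the
floral-tissue BestKeeper rank of *UGPase*) contradicts its own printed
comprehensive score and is excluded; likewise two all-samples genes share a
rank product, where the source printed an arbitrary tie-break and the
package reports a genuine tie.

# Efficiency and target normalization

`fit_standard_curve()` regresses Ct on $\log_{10}$ template amount and
converts the slope with $E(\%) = (10^{-1/slope} - 1) \times 100$; a
non-negative slope flags the curve invalid rather than reporting a
meaningless efficiency. The slope↔efficiency mapping is exactly invertible
(tested to $10^{-9}$ relative).

`normalization_factor()` is the geometric mean of the reference set's
relative quantities per sample; `relative_expression()` divides the
target's efficiency-corrected quantity by it and summarizes biological
replicates by mean ± SD, optionally rescaled to a named calibrator sample.
With efficiency fixed at 2 and a single reference this reduces to the
classic $2^{-\Delta\Delta Ct}$ computation.

# The synthetic generator

`generate_ct_dataset()` draws Ct data from
$$Ct_{gsr} = \mathrm{baseline}_g + \mathrm{shift}_{gs} + \mathrm{load}_s +
\mathrm{noise}_{gsr}$$
with normal noise on the cycle scale (the conventional qPCR error model):
tissue shifts $\sim N(0, \mathrm{instability\_sd}_g)$ drawn per gene ×
group when groups exist (an "unstable" gene then moves coherently within a
tissue class) or per gene × sample otherwise; a loading effect
$\sim N(0, \mathrm{loading\_sd})$ shared by all genes of a sample; and
technical noise per well. The default configuration mirrors a typical
multi-tissue candidate survey of a fruit tree: 11 genes × 23 samples (five
subsets: fruit stages, floral tissues, ovules/seeds, vegetative tissues,
all) × 4 technical replicates, baselines spread over 17–25 cycles, loading
SD 1.0, technical SD 0.15, instability SDs from 0.15 to 1.2 cycles. The
sample sheet itself is synthetic — invented names in a realistic design.

The generator is what makes the pipeline testable end to end: loading
effects it injects must cancel exactly in delta-Ct/geNorm/NormFinder (and
must *not* cancel in BestKeeper SD); its instability order must be
recovered by the methods' rankings (at 5 genes with instability SDs
0.05–0.8, 30 samples, loading SD 1.0, technical SD 0.1 and 4 collapsed
replicates, the mean Spearman correlation over 20 seeded runs exceeds 0.9
for delta-Ct, geNorm and NormFinder, and the comprehensive top gene is the
truly most stable one in 90% of runs); and a target spiked with
`spike_target()` carrying a single-peak profile must have its peak position
recovered after normalization to a zero-instability reference set, while a
high-instability set yields a strictly larger mean absolute log2 error.
What the generator does **not** emulate: amplification-efficiency drift,
inhibition, fluorescence-curve artifacts, Cq-calling, or non-normal error;
passing these tests therefore demonstrates the arithmetic and the
statistical behavior under the assumed model, not robustness to every
failure mode of real plates.

# Numerical choices

* Log base 2 throughout; any fixed base yields identical rankings.
* Min-Ct calibration and default efficiency 2.0 in the quantity transform;
  measured per-gene efficiencies can be supplied (the bundled
  `loquat_panel_efficiencies()` is an example).
* Sample SDs everywhere are the $n-1$ denominator form.
* NormFinder variance estimates are floored at 0 before square roots.
* Degenerate inputs: a constant gene is legal (stability 0; its BestKeeper
  index correlation is `NA` with a warning); fewer than 2 genes, 2 samples,
  or 3 genes for NormFinder/geNorm elimination raise errors.
* Validation problem sizes: oracle equivalence is checked on 200 random
  instances up to 6 genes × 10 samples against loop-written brute-force
  implementations at $10^{-10}$ tolerance; recovery experiments use 20
  seeded replicates of the configurations above.

# Known limitations

* Stability statistics refuse missing cells; there is no imputation.
* The grouped NormFinder combination of bias and imprecision follows the
  published model's implementation as documented above; other software may
  differ in the shrinkage details.
* BestKeeper is implemented in its descriptive SD/CV form about the
  arithmetic mean; tools that rank by mean absolute deviation will order
  borderline genes differently.
* Error bars in `relative_expression()` are SDs over biological
  replicates; technical-replicate error is not propagated through the
  normalization factor.
```{r demo}
d <- generate_ct_dataset(synthetic_config(), seed = 1)
res <- evaluate_subset(collapse_replicates(d$ct), "All samples")
head(res$comprehensive, 4)
```
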