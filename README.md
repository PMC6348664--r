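# rgstab

Selecting stable reference (housekeeping) genes for RT-qPCR normalization.

Relative qPCR quantification divides a target gene's signal by that of
reference genes assumed to be constant across samples — an assumption that
fails often enough (actins drifting across tissues and developmental
stages, for instance) that candidate references are screened empirically.
`rgstab` implements the standard screening workflow on
quantification-cycle (Ct) tables:

* **Four stability statistics.** Comparative delta-Ct (mean pairwise SD of
  per-sample Ct differences), **geNorm** (M value
  `M_j = mean_k sd_s log2(Q_j/Q_k)` with iterative elimination of the least
  stable gene and the `V(n/n+1)` pairwise-variation series), **NormFinder**
  (model-based stability value from the additive model
  `y_gs = gene_g + sample_s + e_gs` on `y = log2 Q`, grouped and ungrouped
  variants), and **BestKeeper** (SD and CV of raw Ct, geometric-mean index,
  per-gene correlation with the index).
* **Consensus ranking.** Competition ("1224") ranks per method, aggregated
  as the unweighted geometric mean of ranks
  `G_g = (prod_m r_gm)^(1/M)`; lower means more stable.
* **Quantification support.** Standard-curve fitting with
  `E(%) = (10^(-1/slope) - 1) × 100`, geometric-mean multi-reference
  normalization factors, and efficiency-corrected relative expression of a
  target gene (mean ± SD over biological replicates, optional calibrator).
* **A seeded synthetic Ct generator** with known per-gene instability,
  shared per-sample loading effects and technical noise, providing ground
  truth for parameter-recovery validation of every stage.
* **An end-to-end pipeline** (`run_pipeline()`, plus a thin CLI at
  `inst/cli/rgstab.R`) producing per-subset stability tables, comprehensive
  rankings and `value (rank)` report tables, deterministically.

The package also bundles the per-method stability ranks and amplification
efficiencies published for an 11-gene loquat (*Eriobotrya japonica*)
candidate panel over five sample sets (`loquat_panel_ranks()`,
`loquat_panel_efficiencies()`) as a worked example and regression anchor
for the aggregation arithmetic.

## Worked example

```r
library(rgstab)

# a synthetic 11-gene x 23-sample x 4-replicate candidate panel
d <- generate_ct_dataset(synthetic_config(), seed = 1)
m <- collapse_replicates(d$ct)
res <- evaluate_subset(m, "All samples")
cat(format_report_table(res, "All samples"), sep = "\n")
```

```
== All samples ==
Method         RPL4      RPL18     HIS3      TUA3      SAMDC     TIP41     UGPase    18S       GAPDH       PIP2      ACT
Delta CT       0.49 (2)  0.50 (4)  0.49 (3)  0.48 (1)  0.73 (9)  0.52 (5)  0.60 (6)  0.67 (7)  0.90 (10)   0.69 (8)  1.68 (11)
BestKeeper     0.88 (5)  0.84 (1)  0.87 (3)  0.86 (2)  1.06 (9)  0.90 (6)  0.96 (8)  0.93 (7)  1.17 (10)   0.87 (4)  1.61 (11)
NormFinder     0.07 (4)  0.00 (1)  0.06 (2)  0.06 (3)  0.57 (9)  0.15 (5)  0.42 (7)  0.42 (8)  0.79 (10)   0.35 (6)  1.65 (11)
geNorm         0.15 (1)  0.21 (4)  0.15 (1)  0.16 (3)  0.55 (8)  0.25 (5)  0.33 (6)  0.45 (7)  0.78 (10)   0.58 (9)  1.68 (11)
Comprehensive  2.51 (4)  2.00 (1)  2.06 (2)  2.06 (2)  8.74 (9)  5.23 (5)  6.70 (7)  7.24 (8)  10.00 (10)  6.45 (6)  11.00 (11)
```

Each cell is `stability value (rank)`: delta-Ct and BestKeeper values are
in cycles, geNorm M and NormFinder SV are dimensionless, and the
comprehensive row is the geometric mean of the four ranks. The default
configuration assigns the smallest instability SDs to the first four genes
and the largest (0.9–1.2 cycles) to `GAPDH`, `PIP2` and `ACT`; the
consensus ranking recovers exactly that split, with the top four positions
taken by `RPL18`, `HIS3`, `TUA3` and `RPL4` and the bottom by the unstable
trio.

Aggregating the bundled published loquat ranks:

```r
rk <- loquat_panel_ranks()
head(geometric_mean_ranks(rk[["All samples"]], subset = "All samples"), 5)
#>    gene geomean final_rank
#> 1  RPL4    1.78          1
#> 2 RPL18    2.21          2
#> 3  HIS3    2.45          3
#> 4  TUA3    2.63          4
#> 5 SAMDC   11.00         11
```

A dilution-series standard curve:

```r
fit_standard_curve(0:-4, c(18.1, 21.5, 24.8, 28.2, 31.5))
#> <standard_curve>
#>   slope -3.3500 cycles/log10, intercept 18.12, R^2 1.0000
#>   efficiency 98.84% (amplification factor 1.9884)
```

See `vignettes/reference-gene-stability.Rmd` for the statistical models,
default parameters, and the design decisions behind the package.

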