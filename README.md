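# ionomeNet

Differential correlation network analysis for multi-group, multi-time-point
elemental profiling (ionomics) data.

## The problem

ICP-MS ionome studies of disease models measure a panel of elements (here a
15-element brain panel: Se, Fe, Zn, Cu, Mg, Hg, Ca, Cr, V, Mn, Cd, Co, Pb,
As, Bi) in small groups of animals — typically *n* = 6 per group per age —
across several groups (wild type, a disease model, a treated disease model)
and ages. Two questions matter:

1. **Which elements change?** Differentially changed elements (DCEs) between
   two groups at each age, tested nonparametrically because small ICP-MS
   samples are often non-normal.
2. **Which element–element relationships change?** Within each group × age
   cell, the Spearman correlation coefficient (SCC) of every element pair
   (105 pairs for 15 elements) defines a correlation network. Edges are
   called significant when |SCC| exceeds a null threshold *τ*; a pair whose
   correlation differs between groups by more than a second threshold
   (|ΔSCC| > *τ*Δ) is a differentially changed correlation (DCC). DCCs that
   are significant in both the disease-vs-control and treatment-vs-disease
   comparisons with opposite signs are *reversed*: the treatment pushes the
   correlation back toward the control state.

At *n* = 6 the permutation null of the Spearman statistic is coarse and
discrete, so the thresholds are estimated by simulation: each run draws
1000 correlations between independent random permutations of the ranks
1..6 and takes the empirical 95th percentile (linear interpolation); the
run is repeated to give a point estimate and a confidence half-width. This
protocol yields *τ* ≈ 0.749 ± 0.028 for a single SCC and *τ*Δ ≈ 1.050 ±
0.036 for the difference of two SCCs, and the package also provides the
exact enumeration of all *n*! permutations (*n* ≤ 8) as an oracle for the
simulation.

Around this core the package implements the standard ionome workflow:
Dixon's Q outlier screen with mean replacement, Lilliefors/KS normality
checks, Wilcoxon DCE scans with direction, two-way group × time ANOVA,
z-scored hierarchical clustering of element profiles, decision-tree /
naive-Bayes / random-forest group classification with feature importances,
group-specific edges, and Cytoscape-compatible SIF/GraphML export. A
Gaussian-copula synthetic-data generator reproduces the three-group study
design (102 animals; planted mean shifts, rank correlations and gross
outliers), so the entire pipeline is testable without access to raw
measurements.

## Worked example

```r
library(ionomeNet)

cfg   <- default_config()                 # three-group study-design mirror
brain <- generate_dataset(cfg, seed = 1)  # 102 animals x 15 elements
qc    <- qc_scan(brain)                   # Dixon Q + normality screen
qc
#> <ionome_qc> 255 cells screened, 40 outlier(s) replaced (Dixon Q, alpha = 0.05)
#>   cells rejecting normality at 0.05: 3.5%

dce_table(dce_scan(qc$data, reference = "AD", comparison = "Se"))
#> # A tibble: 5 x 3
#>   time_months increased decreased
#>         <dbl> <chr>     <chr>
#> 1           4 Se        ""
#> 2           6 Co, Se    "Hg"
#> 3           8 Se        "Cd, Fe, Mn, Pb, Zn"
#> 4          10 Se        "Bi, Cd, Fe"
#> 5          12 Se        "Fe"
```

Selenium rises in the treated group from 4 months, and the AD-elevated
metals — iron above all — fall back from 8 months: the planted treatment
signature, recovered by the scan.

```r
simulate_scc_threshold(6, inner_reps = 1000, outer_reps = 1000, seed = 1)
#> <threshold_estimate> scc at n = 6, alpha = 0.05
#>   point = 0.744, central-95% half-width = 0.029 (1000 x 1000 draws)

ad_wt <- dcc_scan(qc$data, "AD", "WT", tau_dcc = 1.05)
se_ad <- dcc_scan(qc$data, "Se", "AD", tau_dcc = 1.05)
res   <- overlap_and_reversed_dccs(ad_wt, se_ad)
res$reversed
#> # A tibble: 10 x 6
#>   element_a element_b time_months delta_a delta_b reversed
#>   <chr>     <chr>           <dbl>   <dbl>   <dbl> <lgl>
#> 1 Fe        Ca                  4   -1.2     1.43 TRUE
#> 2 Mg        V                   4    1.14   -1.43 TRUE
#> 3 Zn        As                  4    1.6    -1.31 TRUE
#> 4 Fe        Zn                  6    1.83   -1.09 TRUE
#> # i 6 more rows
```

Every DCC shared between the two comparisons in this run flips sign — the
treated group's correlation changes run opposite to the disease-associated
ones. `run_pipeline(outdir = "out", seed = 1)` performs all stages at once
and writes the TSV/SIF/GraphML/JSON bundle; `autoplot()` methods and
`plot_element_profiles()` give ggplot views of each result type. A thin
command-line wrapper with the same stages as subcommands is installed at
`inst/scripts/ionome-pipeline.R`.

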