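# chipdyn

Window-based ChIP-seq enrichment calling and differential histone-mark
dynamics between two biological conditions, with per-gene integration
against expression changes.

The package is for analysts comparing a histone modification (say H3K4me3
or H3K27me3) between two states of the same tissue — two developmental
stages, treated vs. control — from mapped single-end reads. It answers, per
gene: *is the mark there at each condition*, *where did its level change
significantly*, and *do those changes track the gene's expression change*.

## The model

**Enrichment calling.** Unique reads are deduplicated (one per chromosome,
start, strand), extended 150 bp past their 3′ end, and counted on 100-bp
windows; a window counts every overlapping fragment. The input library,
scaled to the IP total, provides the per-window Poisson expectation λ
(windows with zero scaled input take the genome-wide mean). A window is
significant when

&nbsp;&nbsp;&nbsp;&nbsp;P(X ≥ k), X ~ Poisson(λ) &nbsp;&lt;&nbsp; α = 10⁻⁶,

and runs of significant windows merge into peak regions. The error rate is
estimated empirically: peaks called from one input library against the
other, divided by observed peaks (the input-vs-input FDR).

**Differential detection** between the two conditions' IP libraries is
two-stage on 200-bp bins: stage 1 retains bins significantly above a
library's genome-wide mean (Poisson tail < 0.01) and not flagged by the
input-based bias rule; stage 2 quantile-normalizes the retained bins
(two-sample rank-mean) and labels a bin differential when the pseudocounted
fold (a′+1)/(b′+1) reaches τ = 2.0 in either direction. Same-direction runs
merge into regions with a signed mean log₂ fold. Swapping the conditions
flips every direction exactly.

**Integration.** A mark is present on a gene when a peak overlaps the
gene's territory [TSS − 500 bp, TES]; presence at the two conditions gives
the four-way category (K4-K4, K4-None, None-K4, None-None). Genes rank by
log₂((e_B+1)/(e_A+1)) into five equal groups A–E, cross-tabulated against
the categories; differential regions also land in strand-aware 200-bp bins
relative to the nearest TSS. A bivalency table classifies genes carrying
both marks at condition A by their condition-B outcome.

A fully seeded synthetic-study generator (genome, genes, planted mark
states, coupled expression, Poisson reads for six libraries) with a truth
table backs the test suite end-to-end.

## Worked example

```r
library(chipdyn)

sim <- simulate_chipseq(sim_config(seed = 42))   # 2 x 2 Mb, 400 genes

fit <- call_peaks(sim$reads$ip_k4_a, sim$reads$input_a, sim$genome)
fit
#> <peak_calls>
#>   windows tested: 40000 (width 100 bp)
#>   significant windows (p < 1e-06): 1312
#>   peak regions: 426

cn <- chipnorm(sim$reads$ip_k4_a, sim$reads$input_a,
               sim$reads$ip_k4_b, sim$reads$input_b, sim$genome)
cn
#> <chipnorm_fit>
#>   bins: 20000 (200 bp), retained: 1625
#>   differential bins: 201 at tau = 2
#>   regions: 112 (higher_in_A: 50, higher_in_B: 62)

peaks_b <- tidy(call_peaks(sim$reads$ip_k4_b, sim$reads$input_b, sim$genome))
states <- mark_state_table(sim$genes, tidy(fit), peaks_b, "K4", sim$genome,
                           diff_regions = tidy(cn))
groups <- partition_expression_groups(sim$expression)
tab <- crosstab_states_by_group(states, groups, "K4")
tidyr::pivot_wider(tab[, c("group", "category", "n")],
                   names_from = category, values_from = n)
#> # A tibble: 5 x 5
#>   group `K4-K4` `K4-None` `None-K4` `None-None`
#>   <chr>   <int>     <int>     <int>       <int>
#> 1 A          37        16         1          26
#> 2 B          57         2         2          19
#> 3 C          52         2         1          25
#> 4 D          53         2         1          24
#> 5 E          52         1         8          19
```

Reading the table: group A holds the genes most expressed at condition A,
group E at condition B. Genes that *lost* the mark (K4-None, 16 of them in
group A) concentrate where expression fell, and genes that *gained* it
(None-K4, 8 in group E) where expression rose — the planted coupling,
recovered by the full pipeline. `plot_state_crosstab(tab, "K4")`,
`autoplot()` on TSS profiles and histograms, and `tidy()`/`glance()` on
fitted objects give the standard views.

The same analysis runs from the shell over files (BED6/GFF3/TSV) via a YAML
config: `run_pipeline("pipeline.yaml", "out/")` or the thin CLI in
`inst/scripts/chipdyn`; outputs include bedGraph tracks, peak and
differential BEDs, the state/bivalency/crosstab tables, and a manifest with
all parameters and checksums that makes a rerun bit-identical.

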