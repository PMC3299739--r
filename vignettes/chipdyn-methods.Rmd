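---
title: "Methods: window-based enrichment calling and differential histone-mark analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based enrichment calling and differential histone-mark analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipdyn)
```

# Scope

chipdyn analyses histone-modification ChIP-seq (e.g. H3K4me3, H3K27me3)
between two biological conditions, A and B. It answers three questions per
gene: is the mark present at each condition; where did the mark level change
significantly between conditions; and how do those changes relate to the
gene's expression change. The package consumes already-mapped, unique-hit
reads (BED6), chromosome sizes, gene models (GFF3), and a two-condition
expression table. All internal coordinates are 0-based half-open (BED
convention); GFF3's 1-based closed coordinates are converted at the I/O
boundary.

# Per-condition enrichment model

Reads are deduplicated — at most one read per (chromosome, start, strand);
the strand is part of the key because the same 5' position on opposite
strands represents distinct fragments (a `ignore_strand` flag gives the
stricter position-only key). Deduplication precedes extension; since
extension is deterministic the order is immaterial for this key. Each read
is then extended by 150 bp beyond its 3' end (an approximation of the
sequenced fragment), and the genome is tiled with 100-bp windows anchored at
coordinate 0; a window gains one count for every fragment overlapping it by
at least 1 bp. Chromosome-tail windows are truncated but kept: there is no
reason to discard tails.

The input library is the background model. Its window counts are scaled so
its total equals the IP total, and the scaled count of each window is the
Poisson expectation $\lambda_w$ for the IP count $k_w$; windows whose scaled
input is exactly zero take the genome-wide mean over all windows (zeros
included — the literal inclusive mean; a per-chromosome variant is
available). The per-window p-value is the inclusive upper tail
$P(X \ge k_w),\ X \sim \mathrm{Poisson}(\lambda_w)$, and a window is
significant iff $p < \alpha$ with $\alpha = 10^{-6}$ (strict comparison).
The inclusive tail is the probability of observing a count at least as
extreme as the one seen; the strict tail differs negligibly at this
threshold and is available as a flag. Runs of significant windows (with a
configurable merge gap, default 0) become peak regions.

No multiple-testing correction is applied beyond the fixed threshold.
Instead, an *empirical* false discovery rate is estimated exactly as in the
window model's original use: call "peaks" treating one input library as IP
against the other input, and divide the null peak count by the observed
peak count. Merged regions (not windows) are counted, since regions are the
reported unit; a flag counts windows instead. On real libraries this
estimate absorbs overdispersion the Poisson model ignores; on synthetic
Poisson reads it is near zero, so the package reports the estimate and never
asserts any particular value on simulated data.

## Calibration and the plug-in expectation

Two distinct properties matter here and are tested separately:

* **p-value calibration.** When the expectation track is the *true* rate
  field, $P(p < \alpha) \le \alpha$ per window (Poisson tails are
  super-uniform), so a million null windows at $\alpha = 10^{-6}$ should
  yield at most a handful of significant calls. The null-calibration check
  therefore draws IP reads from the background model and supplies the known
  background expectation (rate × (read + extension + window − 1) bp).
* **plug-in noise.** In practice $\lambda_w$ is estimated from a finite
  input library. A window where the input happens to be shallow (count 1-2)
  gets a small $\lambda_w$, and moderate IP noise can then cross
  $10^{-6}$; this inflates null calls well above $\alpha \times$ windows
  and is exactly what the empirical input-vs-input FDR measures. Deeper
  input libraries shrink this effect. The two views are kept distinct on
  purpose: conflating them would make the calibration test assert something
  that is false for any finite input.

# Two-stage differential detection

Differential regions between the two conditions' IP libraries of one mark
are found on a 200-bp bin grid (fragments counted directly at 200 bp — the
sum of two adjacent 100-bp windows is *not* the same quantity, because a
fragment straddling the interior boundary would be counted twice; a
`rebin_track()` helper with sum semantics exists for coverage-style
aggregation and documents this).

**Stage 1** removes bins that carry no usable signal: a bin is retained iff
at least one IP library's count is significantly above that library's
genome-wide mean bin count (Poisson upper tail < 0.01), and the bin is not
flagged as locally biased — both scaled inputs above 5× their genome-wide
means. The noise test, its level, and the bias rule are this package's
concrete reading of "remove stochastic background noise and local genomic
bias"; each is independently configurable and the bias filter can be
disabled (`bias_filter = FALSE`) to reproduce an IP-only reading. Because
the mean bin count includes the enriched mass, the implied count threshold
sits well above the true background rate, which keeps the retained set
essentially signal-only.

**Stage 2** quantile-normalizes the retained bins of the two conditions with
the two-sample rank-mean construction: both vectors are mapped rank-wise to
the mean of the two order statistics, so their sorted values become
identical; ties receive the mean of the reference values over the tied
ranks, which keeps the map deterministic and permutation-equivariant (with
unequal tie patterns the sorted outputs can then differ slightly — the
price of a well-defined tie rule). A bin is called differential when the
pseudocounted fold change $(a'+1)/(b'+1)$ reaches $\tau = 2.0$ in either
direction; the pseudocount (default 1, the smallest standard stabilizer)
avoids division by zero on retained-but-asymmetric bins. Same-direction runs
merge into regions carrying the mean signed log2 fold; opposite directions
never merge. The whole procedure is antisymmetric: swapping the two
conditions yields the identical region set with directions flipped,
exactly.

**Depth dependence of the fold rule.** A hard ratio threshold has a
depth-dependent false rate: for bins with ~20 counts the binomial noise of
a 2-fold ratio is ~2 standard deviations, so a few percent of null retained
bins cross $\tau$; at ~80 counts the rate drops below 1%. The package's
null-behaviour property test therefore asserts the sub-1% rate at 4× the
default simulated depth (the regime closer to real ~20M-read libraries) and
a looser bound at the scaled-down default depth. Users analysing shallow
libraries should expect single-bin differential calls at enrichment-region
edges and treat `n_bins = 1` regions accordingly.

# Gene-state integration

Presence of a mark on a gene at one condition means: any peak region of
that condition overlaps the gene's *territory* by at least 1 bp. The
territory is the strand-aware interval from TSS − 500 bp to the TES,
clipped to the chromosome; one territory serves both marks because H3K4me3
sits at/just downstream of the TSS and H3K27me3 covers gene bodies (the
upstream margin is configurable per analysis). Per-gene presence at the two
conditions gives the four-way category (e.g. K4-K4, K4-None, None-K4,
None-None). Overlap with a direction-consistent differential region is
recorded separately as `diff_supported` rather than folded into the
category, since presence calls and differential regions are different
statistics; a stricter analysis can filter on it.

Genes bivalent at condition A (both marks present) are classified by their
condition-B outcome: lost both, retained K27 only, retained K4 only, or
retained both.

Expression integration ranks genes by
$\log_2\!\big((e_B + \delta)/(e_A + \delta)\big)$ with $\delta = 1$
expression unit, breaking ties by gene identifier so the partition is
deterministic and order-independent, and cuts the ranking into five
contiguous groups A-E of near-equal size (earlier groups absorb the
remainder). Group A holds the genes most strongly expressed at condition A,
group E at condition B. Cross-tabulating the mark categories against the
groups (zero-filled, with per-group proportions) reproduces the standard
view relating mark turnover to up-/down-regulation.

For the positional view, each differential region is assigned by its
midpoint to the nearest TSS within 10 kb and tallied into strand-aware
200-bp bins: bin +1 is [TSS, TSS+200) in the direction of transcription,
bin −1 the first upstream bin, no bin 0. Regions with no TSS in range are
counted as unassigned, never silently dropped.

# The synthetic study

The generator builds the whole study in silico, with a truth table for
scoring. Defaults are the reference conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| genome | 2 × 2 Mb | two chromosomes |
| genes | 400 | uniform placement, ≥ 2 kb spacing, lengths 1-4 kb |
| K4 states both/none/a\_only/b\_only | .60/.35/.025/.025 | per-gene planted state |
| K27 states both/none/a\_only/b\_only | .04/.90/.05/.01 | |
| enrichment fold | 8 | IP rate multiplier in planted intervals |
| differential fold | 4 | planted between-condition fold |
| background rate | 0.007 reads/bp | ≈ 2 fragments per 100-bp window |
| read length | 36 bp | single-end era |
| expression effect | ±2 log2 | shift for mark gain/loss |
| expression noise | 0.5 log2 | per condition |

K4-like intervals occupy the first kilobase downstream of the TSS; K27-like
intervals the whole gene body. A gene whose mark belongs to one condition
only gets the full 8× rate on the mark-bearing side and 8/4 = 2× on the
other, so the planted between-condition fold is 4 while the weak side stays
below the presence-calling threshold, consistent with its planted "None"
state. Expression is coupled to the planted changes with activating sign
for K4 (gain → up at B) and repressive sign for K27. Reads are placed by a
Poisson process with uniform strands; input libraries are unbiased unless a
shared bias field is requested (`n_bias_regions`), which multiplies the
rate of *every* library alike and exercises the stage-1 bias filter. A
`dup_rate` option plants PCR-style duplicates for the deduplication path.
Everything is deterministic given the seed, down to byte-identical output
files.

The background depth deserves a note: 0.007 reads/bp makes the expected
fragment count of a 100-bp window ≈ 0.007 × (36 + 150 + 100 − 1) ≈ 2,
the regime in which the window caller's behaviour is cleanly separated
(8× enrichment is unmissable, background essentially never crosses
$10^{-6}$). Real libraries of ~20M reads on a ~120-Mb genome are ~25×
deeper; the simulation is a deliberately scaled-down study, not a depth
match.

**What the generator does not emulate:** mappability and GC bias,
overdispersion beyond Poisson (biological replicates, clonal structure
beyond the optional duplicates), fragment-length variation, chromatin
domains broader than single genes, and expression measurement error
structure beyond log-normal noise. Passing recovery tests on this generator
therefore demonstrates the pipeline's correctness under its own model, not
performance on real libraries — which is why the real study's genome-wide
percentages are treated as generator defaults and qualitative shape checks,
never as assertions.

# Problem sizes and numerical choices in the test suite

The suite runs the calibration check on one million windows (one 100-Mb
chromosome at default depth), recovery checks on the default 4-Mb / 400-gene
study, a ten-seed panel for the integrated state recovery, and the
TSS-histogram shape check on an 800-gene / 8-Mb variant with equal K4
gain/loss proportions (0.20 each): the top-five-bins statistic needs a few
hundred planted differential regions before its fifth rank clears the
partial-bin edge noise at bins −1/+6. Binomial checks of the generator's
state marginals use family-wise 99% bounds (Bonferroni over the eight
state comparisons).

Other numerical conventions: window grids anchor at 0; significance and
fold thresholds compare strictly (`p < alpha`) and inclusively
(`fold >= tau`, `fold >= threshold` in the qPCR filter) as their
definitions state; Poisson tails delegate to R's `ppois` and are verified
against an independent log-space series summation to 10 significant figures
over k ≤ 200, λ ≤ 50; the TSS profile takes each bin's value from the
window containing the bin midpoint and drops off-chromosome bins from the
per-bin mean; empty inputs (no peaks, no labeled bins, no regions) yield
empty, correctly-typed results rather than errors.

# Known limitations

* The Poisson window model ignores overdispersion; on real data the
  empirical input-vs-input FDR is the honest error measure, and it is
  sensitive to input depth.
* The fold-change rule has no variance model; shallow bins produce edge
  artifacts (see above).
* Presence calling is binary with a single territory; marks with unusual
  spatial distributions would need a per-mark territory (supported via the
  `upstream` argument but not auto-tuned).
* The generator's uniform background makes stage-1's bias filter a no-op
  unless a bias field is requested.
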