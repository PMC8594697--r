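---
title: "Replicate-aware DMR calling and methylation-transcription integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-aware DMR calling and methylation-transcription integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylgraft)
library(data.table)
```

## The problem

Whole-genome bisulfite sequencing of plants yields, per biological
replicate, a table of cytosines with methylated and total read counts in
three sequence contexts (CG, CHG, CHH; H = A, T or C). Comparing two
conditions — for instance clonally propagated grafts of different ages, or
grafts against seedlings — requires deciding which genomic regions are
differentially methylated (DMRs) in a way that respects the biological
variation between replicates, and then asking where those regions fall
relative to genes and transposable elements and whether they track
transcriptional changes. CHH methylation deserves particular attention in
this setting: it is maintained de novo by the RNA-directed DNA methylation
pathway and is the context in which age- and propagation-related
differences concentrate.

`methylgraft` implements this analysis as a reusable, tested pipeline with
a built-in synthetic methylome generator, so that every stage can be
validated on data with known ground truth.

## The sliding-window model

The genome is tiled with windows of `window_size` = 200 bp advanced in
`step` = 100 bp increments (each interior base is covered by exactly two
windows; trailing windows are truncated at the chromosome end). Within a
window, for one replicate and one context, the methylation level is the
*unweighted mean of per-site ratios* `n_meth / n_total` (in %), over sites
with coverage at least `min_site_coverage` = 3 reads. The unweighted mean
is deliberately robust to single high-coverage cytosines; a pooled-count
alternative exists for the per-window test (`test = "fisher"`).

A window enters testing only when **all** replicates of both conditions
have a defined level there. Three statistics describe each tested window:

* `delta_mC` — difference of condition means, test minus reference, in
  percentage points (pp). Negative values mean the test condition is
  *hypomethylated* relative to the reference.
* `SDA` — the standard deviation of the per-replicate window averages
  within a condition, a direct measure of replicate reproducibility.
* a p-value from a two-sample test on the replicate levels.

A window is called a DMR when `p <= p_threshold` (default 0.01), both
conditions' SDA are at or below the context-specific cap, and
`|delta_mC| >= min_abs_delta`. Each significant window is reported as one
DMR; overlapping significant windows are not merged (a post-hoc merge of
same-direction runs is available but off by default, so that summary
counts remain window-level quantities).

### Choice of the per-window test

The default test is the pooled-variance two-sample Student t on the
per-replicate window means. With the typical 3 replicates per condition,
the unequal-variance (Welch) statistic is identical for equal group sizes
but its estimated degrees of freedom fall between 2 and 4, making it
conservative and numerically fragile on near-constant windows. The pooled
test with 4 degrees of freedom is exactly calibrated on simulated null
methylomes (rejection rate 0.049 at nominal 0.05 over ~24,000 windows;
this is recomputed by the test suite and by `scripts/acceptance.R`). Welch
(`test = "welch"`) and a pooled-count Fisher exact test
(`test = "fisher"`) remain available. Windows where both groups are
constant receive p = 1 when the means agree and p = 0 otherwise, a
limiting convention for a noiseless window.

### Minimum sites per window

`min_sites_per_window` defaults to 10. At 14x coverage a single
cytosine's ratio has binomial noise up to ~13 pp (sd at 50% methylation),
so a window averaging only 4 sites carries ~6.5 pp of noise in its
*window mean* — as large as the effect sizes of interest. Such windows
produce statistically significant but scientifically meaningless calls:
because the t-test is calibrated, 1% of them pass any raw p cutoff, and
since significance itself selects for low within-group variance, neither
the SDA cap nor the `min_abs_delta` floor removes them. Requiring at
least 10 measurable cytosines keeps window-mean noise near 4 pp and
restricts testing to windows that can actually support a claim. Sparse
windows are reported as *undefined*, never as zero.

### SDA thresholds

The SDA caps (defaults CG 10, CHG 10, CHH 5 pp) are reproducibility
filters meant to be fitted per data set — on real data, windows with
large replicate scatter are usually artefacts of mapping or coverage.
The defaults are reasonable starting points for a plant methylome and
make no claim of matching any particular published setting; they must be
reviewed against the observed replicate noise (as a rule of thumb, the
cap should sit a few pp above the binomial noise floor of a typical
window in that context).

### Minimum effect size

`min_abs_delta` defaults to 5 pp: differences smaller than the smallest
mean within-DMR methylation change that is biologically interpretable at
this coverage are not reported, and the floor removes most of the raw-p
false calls a genome-wide scan at p = 0.01 necessarily produces. Set it
to 0 to mirror a pure p + SDA filter.

No multiple-testing correction is applied to window p-values by default
(raw p plus the SDA filter is the reporting convention this pipeline
follows); `p_adjust = "BH"` enables Benjamini-Hochberg if desired.

## Summaries

`summarize_dmrs()` tabulates DMRs by context and direction and derives
three share tables (direction within context, context of total, direction
of total); `direction_share()` pools arbitrary context subsets (e.g. the
hypermethylated share of CG+CHG DMRs). It accepts either one row per DMR
or a pre-tabulated count column, so printed count tables can be fed in
directly. Printed-style rounding uses `round_half_out()`
(half-away-from-zero, the convention of typeset percentage tables, unlike
base R's round-half-even). `dmr_density()` counts DMR starts per 50-kb
bin per context and flags hotspot bins at the 0.99 quantile of nonzero
bin counts.

## Feature association

`associate_dmrs()` links every DMR to every gene or TE whose interval
overlaps it or lies within `flank` = 2000 bp (closest-edge distance).
Position classes are strand-aware: the promoter is the 2000-bp region 5'
of the gene start, the terminator 3' of the gene end; on the minus strand
the promoter therefore lies at higher coordinates. A DMR touching several
regions is resolved promoter > body > terminator — the tie-break favours
the region most likely to matter for transcription. The same flank width
is used for association and for the promoter/terminator definition. A DMR
linked at exactly the flank distance touches no region interior and is
assigned the flank class of its side. TE links use the labels
flank5/body/flank3. `dedupe_per_feature()` keeps, per feature, the DMR
with the largest |delta_mC| (ties: smaller start, then lexicographic
context), so downstream joins see at most one DMR per feature.

## Differential transcripts, bins and enrichment

`select_dets()` filters a normalized differential-transcription table at
p <= 1% (inclusive) and splits genes (DTGs) from TEs (DTTEs).
Functional-bin analysis consumes a Mercator-style map; transcripts mapping
to several bins keep the deepest (most specific) code, unassigned
transcripts are excluded, and reporting can pool bins under 5% into an
"Other class". Enrichment per bin is the one-sided hypergeometric
over-representation test against the platform background
(`stats::phyper`), BH-corrected over all tested bins
(`stats::p.adjust`); the count-based test was chosen because it is
parameter-free and reproducible from the bin assignments alone.
`compare_contrasts()` intersects two DET sets and counts concordant and
opposite regulation within the common set.

`ddct_quantify()` implements relative qPCR quantification: per-gene
quantity `efficiency^(Ct_cal - Ct_sample)` (efficiency 2.0 by default,
i.e. perfect doubling, overridable per assay), a normalization factor as
the geometric mean of the reference-gene quantities, and normalized
expression as target quantity over that factor. The calibrator comes out
at exactly 1, and a constant Ct shift on a whole sample cancels.

## Integration

`join_dtg_dmr()` inner-joins DTGs with deduplicated gene links, keeping
CHH-context DMRs (the context filter default, since CG/CHG Gene-DMRs are
too few to analyse separately) and |log2 ratio| >= 1.5.
`quadrant_summary()` reports the share of records in each (sign delta_mC
x sign ratio) quadrant per position class; `correlation_test()` regresses
ratio on delta_mC and reports R², r = sign(slope)·√R² (identical to
Pearson's r), t = r·√((n−2)/(1−R²)) and its two-sided p-value. With
n < 50 an F-ratio between the variances of the two plotted variables is
reported alongside as a small-sample annotation; it never gates the
correlation result — the two variables are on different scales, so this
variance comparison is descriptive, not inferential.

## The synthetic methylome generator

`sim_spec()` fixes the simulated study conditions:

| parameter | default | rationale |
|---|---|---|
| context densities | CG 0.02, CHG 0.02, CHH 0.10 per position | CHH ≈ 71% of cytosines, the CHH-dominant composition of plant genomes |
| baselines | CG 60, CHG 40, CHH 10 % | typical plant genome-wide context averages |
| coverage | zero-truncated Poisson, mean 14 | sites with zero reads would simply be absent from a call file |
| replicates | 3 per condition | the minimum that makes an SDA meaningful plus one |

Per site, replicate and condition, the methylated count is
Binomial(depth, level/100); inside an injected region of matching
context, the *test* condition's level is baseline + delta clipped to
[0, 100] — e.g. a −30 pp injection on the 10% CHH baseline saturates at
level 0, an effective −10 pp, which is precisely the regime where the
SDA/window machinery has to work. Each generator output uses one seeded
random stream ordered by genomic coordinate (`seed`, `seed + 1`,
`seed + 2` for methylomes, features and expression), so outputs are
byte-identical across reruns and independent of each other.

The expression generator couples genes planted downstream of injections:
the reported log2 ratio is `-effect x (promoter CHH delta / 100)` plus
gene-level noise, and p-values come from a pooled t-test on simulated
replicate expression values centred on that coupling signal — so with
`effect = 0` the p-values are exact nulls and stay calibrated.

What the simulator does *not* model: biological (extra-binomial)
replicate variance, bisulfite conversion error, mapping bias, strand or
positional autocorrelation of methylation, and realistic TE sequence
content. Consequently, passing recovery tests demonstrate the
correctness and calibration of the machinery under ideal noise, not
performance on real libraries — in particular the SDA filter is nearly
inert on simulated data (replicate scatter is uniformly binomial) even
though it is the decisive filter on real data.

## Problem sizes used in validation

The packaged checks run the null calibration on a 2 x 1.2-Mb genome
(~24,000 tested windows) and the recovery study on a 2 x 1-Mb genome with
200 injected 500-bp CHH DMRs at −30 pp (3 replicates, 14x, seed 7), where
the caller at default parameters attains sensitivity 1.0 and precision
0.996 (917 of 921 called windows overlap an injection; values pinned in
the test suite). These sizes give stable rates while keeping the whole
suite fast; scaling the genome up changes nothing structurally.

## Numerical conventions and degenerate inputs

* All internal intervals are 0-based half-open; call files are 1-based
  positions and GFF3 is 1-based inclusive — both converted exactly once
  at the I/O boundary. Strands are kept as separate records; CG-pair
  symmetry is never collapsed.
* Undefined states (window with too few sites, context with no covered
  site, empty position class, zero-variance correlation input) are
  represented as flagged NA, never as 0.
* Rounding for printed-style percentages is half-away-from-zero.
* Ties in per-feature dedupe and position classification are broken by
  documented deterministic rules, so all outputs are byte-stable.

## Known limitations

Single-cytosine resolution (DMP calling) and HMM-style segmentation are
out of scope; DMR boundaries are window-quantized. The caller requires at
least two replicates per condition — SDA is undefined otherwise. The
qPCR module assumes one efficiency per run rather than per primer pair
unless overridden. Conversion-efficiency filtering of calls (e.g. against
chloroplast reads) is not implemented; calls are taken at face value.
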