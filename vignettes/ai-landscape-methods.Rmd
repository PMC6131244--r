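---
title: "Methods: allelic-imbalance landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allelic-imbalance landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiscape)
library(dplyr)
```

## The problem

Colorectal and other carcinomas acquire chromosomal gains and losses that
dwarf their point-mutation burden, but a single arm-level event spans
thousands of genes, so the targets of selection are hard to name. When many
tumors are profiled, however, the loci where gains or losses recur most
sharply become narrow: stacking per-tumor allelic-imbalance (AI) calls into a
cohort count profile and reading off its most *prominent* local maxima
pinpoints candidate driver genes at near-gene resolution. `aiscape`
implements that analysis end to end — from per-SNP tumor signals to ranked
recurrence peaks and the cross-sectional statistics built on them — together
with a synthetic-cohort generator with known ground truth against which every
stage is validated.

## Signal model

At a germline-heterozygous SNP the tumor sample is modeled as a mixture of
normal diploid cells (fraction $1-\rho$, genotype AB) and tumor cells
(fraction $\rho$, the purity), of which a fraction $f$ (the clonality) carry
the local aberration leaving $c_t$ total and $b_t$ B-allele copies. The
expected B-allele frequency and log R ratio are

$$
E[\mathrm{BAF}] \;=\; \frac{(1-\rho) + \rho\,[(1-f) + f\,b_t]}
                           {2(1-\rho) + \rho\,[2(1-f) + f\,c_t]},
\qquad
E[\mathrm{LRR}] \;=\; \alpha \,\log_2 \frac{2(1-\rho) + \rho\,[2(1-f) + f\,c_t]}{2}.
$$

The BAF mixture is the standard two-population model that purity-corrected
BAF (cBAF) clonality estimation presupposes; the attenuation factor
$\alpha$ (default 0.55) reflects the intensity compression of SNP arrays,
whose true value is platform-specific and therefore configurable. Balanced
heterozygous sites give BAF 0.5; analysis runs on the mirrored BAF
$m = |\mathrm{BAF} - 0.5|$ so the identity of the lost or gained parental
allele is irrelevant.

Both relations are exactly invertible, which the pipeline uses twice:
`estimate_clonality()` solves the BAF model for $f$ given $\rho$
(copy-neutral LOH model $\hat f = 2\Delta/\rho$ when $|LRR|$ is near 0; the
one-copy-deletion model otherwise), and `lrr_to_copies()` solves the LRR
model for $c_t$, which feeds the per-copy mutation-rate fit.

## Segmentation and classification

Per sample and chromosome, changepoints in mirrored BAF are found by
penalized least-squares search (binary segmentation on segment means; a
split is accepted when it reduces the residual sum of squares by more than
$3\,\hat\sigma^2\log n$, with $\hat\sigma$ estimated robustly from first
differences). A segment is called AI when its mean mirrored BAF reaches
0.07 with at least 10 probes — a sensitivity chosen to approximate
established BAF-segmentation tools; both knobs sit in `ai_config()`.
Called segments are classified by mean LRR: gain above +0.10, otherwise
loss, *including* copy-neutral LOH, whose LRR is neutral while the BAF is
imbalanced. Homozygous deletions are invisible to BAF (the residual signal
comes from contaminating normal cells, which are balanced), so they are
called separately as runs of at least 5 probes with LRR below −1.0. That
threshold is purity-limited: with the attenuated-log model a two-copy loss
only drops below −1.0 when $\rho \gtrsim 0.7$, a limitation shared by real
arrays.

Sub-threshold detail: interior segment boundaries are placed midway between
flanking probes; adjacent same-class AI segments closer than 1 Mb are
merged, pooling probe-weighted means; chromosomes with fewer than 20 probes
are skipped.

## Count tracks, peaks, prominence

For each class, `build_count_track()` counts distinct tumors whose segments
cover each interval between the sorted unique segment endpoints (a sample's
overlapping segments are unioned first). The track is smoothed with a
**max filter over 10 consecutive inter-breakpoint intervals** — window in
intervals, not basepairs, so smoothing adapts to breakpoint density.
The window is centered ($i-\lceil w/2\rceil+1 \dots i+\lfloor w/2\rfloor$,
clipped at chromosome ends); a trailing variant is available because the
choice is not forced by anything in the method, and both are exposed via
`ai_config(smooth_align=)`.

Peaks are maximal equal-value runs of the smoothed track strictly greater
than both flanks (runs touching a chromosome end qualify against their
single inner neighbor). Each apex is then scored on the *unsmoothed* track
by topographic prominence: the height of the peak above the lowest contour
line that surrounds it and does not contain a higher peak. Two independent
implementations ship — the outward walk used by the pipeline and a
descending flood fill (`prominence_oracle()`) kept solely to cross-check
the walk — and the test suite proves them identical on an exhaustive
enumeration of small tracks and on random ones. Conventions worth stating:

* sea level is 0 beyond both chromosome ends, so the highest peak of a
  chromosome has prominence equal to its height;
* walks anchor at the raw summit inside the apex run, because a smoothed
  plateau can straddle raw dips;
* a constant nonzero chromosome yields one apex spanning it, flagged
  `spans_chromosome = TRUE` — such an apex carries no positional
  information and is excluded from locus-level claims;
* ties in the prominence ranking break by height, then genomic order.

Peaks with prominence below 15 tumors are not reported. Gene assignment
takes the genes overlapping the smoothed apex plateau; an empty plateau
falls back to the nearest gene on each side.

## Isochromosome calls and co-occurrence

A sample is called isochromosome-like on a chromosome when at least 80% of
at least one arm (by bp of the union of the sample's AI segments, any
class) is AI *and* the arms' mean probe LRR differs by at least 0.2. A
p-arm deficit yields `i(q)`; the mirrored form yields `i(p)`, flagged as
the generalization it is. The within-chromosome gain/loss co-occurrence
scan lays a 1-Mb grid (the resolution is a free choice) and reports log2
odds ratios per (gain locus, loss locus) pair, Haldane–Anscombe-corrected
for zero cells; the exact test at the maximal pair uses the uncorrected
table.

## Mutations versus copy number

Under the neutral model — each chromosomal copy mutates independently at a
constant rate per replicated basepair — a segment's SNV count is Poisson
with mean $\mu\, c_t \cdot$ (callable Mb). `fit_per_copy_rate()` inverts
segment LRR to $\hat c_t$ and fits the Poisson regression with
$\log(\hat c_t \cdot \text{Mb})$ as offset; the intercept is $\log\hat\mu$
(the MLE is total counts over total copy-Mb) with profile-likelihood
intervals. Raw-LRR density and VAF curves with lowess guides are reported
as well, because the copy-number inversion needs $\alpha$ and $\rho$ while
the raw curves do not. Segments with under 0.5 callable Mb are dropped —
their densities are shot-noise.

## What the simulator emulates, and what it does not

`simulate_cohort()` draws purity from Beta(5, 3), MSI status at 15%, and
per-sample events: background chromosomal-instability aneuploidies
(Poisson, mean 6 for MSS vs 1.5 for MSI samples — the designed MSS ≫ MSI
AI burden), a six-driver catalog at 10–60% recurrence whose event
intervals always contain the driver locus but vary in extent, an
isochromosome (p-arm loss + q-arm gain with a retained 1–5 Mb p-terminal
stub) on a designated chromosome in 20% of samples, MSI-enriched focal
fragile-site deletions (0.1–1 Mb; probability ×6 in MSI), and rare focal
homozygous deletions. MSI samples receive drivers at a quarter rate,
mirroring the chromosomal stability of MSI tumors away from fragile sites.
SNVs accrue per copy at $\mu = 0.05$/Mb with multiplicity 1; read depth is
negative binomial with mean proportional to local DNA content, which is
precisely what makes the mutated-read count per SNV flat across copy
states while density rises. Expression for planted genes follows
`slope * LRR + 0.5 * purity + noise`.

Two structural choices deserve their rationale:

* **Events within a sample are spatially exclusive.** Focal and recurrent
  events are drawn first; background aneuploidies are rejected on overlap.
  A region of one clone carries one aberration; composing, say, a gain over
  a lost chromosome would really produce copy-neutral LOH, i.e. a *loss*
  call, not a superposition. Exclusivity keeps planted recurrences exactly
  binomial at their catalog probabilities and keeps cohort tracks flat away
  from planted loci, which is what makes planted-peak recovery a sharp
  test.
* **Background events span whole chromosomes.** Partial-arm background
  events would stack into random plateaus whose prominence equals their
  height on any chromosome lacking a driver of that class — structural
  false peaks that say nothing about the method. Whole-chromosome
  background contributes a flat, positionless elevation instead; arm-scale
  asymmetry enters through the isochromosome events where it belongs.

The simulator does not emulate: GC waves or other array artifacts beyond
i.i.d. Gaussian noise, germline genotyping error, subclonal phylogenies
beyond a single clonal fraction per event, mutation multiplicity above 1
(pre-gain mutations), or chromothripsis-like complexity. Passing tests
therefore demonstrate correctness of the analysis under its own signal
model, not robustness to platform pathology.

## Numerical and testing choices

Coordinates are 0-based half-open everywhere, including the BED-like
interchange files. All randomness flows from one seed set at entry to
`simulate_cohort()`; identical seeds give byte-identical cohorts. The
validation suite runs at deliberately desk-sized problems: a 5 × 100 Mb
genome at 100 het-SNPs/Mb, 300-sample cohorts for peak recovery, 50 + 50
samples for isochromosome operating characteristics (sensitivity ≥ 0.9,
specificity ≥ 0.95), ≥ 2000 segments for µ recovery within 10%, purities
0.4–0.8 for boundary (≤ 5 probe spacings) and clonality (bias ≤ 0.05)
recovery, 200 replicates for logistic null calibration and 500 genes for
expression FDR calibration. Separated logistic fits fall back to a
Firth-penalized solver written here because small per-peak counts make
separation routine at these sizes.

## Known limitations

Purity estimation (`estimate_purity()`) is the simple inversion
$\hat\rho = 2\Delta_{max}$ from the strongest near-neutral segment assumed
to be clonal cn-LOH; it has no ploidy grid search and is overridden by
metadata purity whenever available. Homozygous-deletion calling is
threshold-based and purity-limited as noted. The co-occurrence scan treats
loci marginally (no conditioning on total instability); the
burden-controlled logistic models exist for exactly that purpose. Gene
assignment knows nothing of regulatory elements — a peak 17 kb from a
gene's coding sequence will name its flanking genes, which is the intended
behavior of the flanking rule, not gene-body resolution.
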