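---
title: "Measuring single-cell DNA replication speeds: models and methods"
author: "replifork"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-cell DNA replication speeds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replifork)
```

# Overview

`replifork` analyzes single-cell EdU pulse-labeling sequencing
(scEdU-seq) data.  During S phase, thousands of replication forks copy
the genome; a short pulse of the thymidine analog EdU marks the DNA each
fork synthesizes during the pulse.  After capture and sequencing, a cell
is represented as a *molecule table*: the genomic positions (NlaIII
restriction sites, ~250 bp apart) of its deduplicated labeled reads.
From these point patterns the package estimates, per cell:

* **where** replication is running (track segmentation),
* **when** in S phase the cell is (ordering), and
* **how fast** forks move (double-pulse speed estimation).

This vignette records the models, the tunable parameters, the
numerical choices, and what the simulators do and do not emulate.

# Quality control

Cells are filtered on the average count per 100-kb bin (zero bins
included), with inclusive mode-specific thresholds: 0.37–2.72 reads per
bin for single-pulse cells and 0.08–12.18 for double-pulse cells.
The second gate uses deviance from Poisson behavior,

$$\log(\mathrm{CV}) > -\tfrac12 \log(\text{mean}) + 0.1,$$

with natural logarithms on both sides.  A homogeneous Poisson point
pattern has $\mathrm{CV} \approx 1/\sqrt{\text{mean}}$, i.e.
$\log \mathrm{CV} = -\tfrac12\log(\text{mean})$.  A genuine S-phase
cell concentrates its reads in replication tracks tens of kb long, so
its binned coverage is strongly over-dispersed and sits *above* that
line; coverage that is Poisson-flat is ambient background (leaky
capture, non-S-phase DNA) rather than replication signal.  Cells are
therefore **kept** when they exceed the line by the 0.1 margin and
removed otherwise.  Cells with fewer than two nonzero bins have an
undefined CV, cannot be assessed, and fail with a warning.  Both
filters run before foreground selection, and failing cells are removed
rather than flagged.

## Foreground selection

Within a passing cell, reads inside replication tracks sit a few
hundred bp to a few kb apart, while background reads (ambient DNA,
mis-assigned molecules) are megabases from their neighbors.  A
two-component exponential mixture is fitted by EM to the distances
between successive reads (all chromosomes pooled; at most 200
iterations, relative tolerance $10^{-8}$, initialized by splitting the
distances at their median).  Each read is then scored by the posterior
probability of the short-distance component evaluated at its *distance
to the first neighbor*, the smaller of its two flanking gaps (chromosome
ends use the single available gap); reads with posterior > 0.5 are kept.
The nearest-gap reading makes the per-read posterior well defined while
fitting on successive-read distances.  If the EM does not converge the
cell is flagged and all reads kept, which errs toward retaining data.

# S-phase ordering

Cells at similar S-phase stages replicate similar genomic regions, so
profile overlap orders cells along S phase.

1. **Smoothing.** Each foreground read contributes a unit-mass Gaussian
   with sd 8,333.333 bp, evaluated on a 2,500-bp grid per chromosome
   (about sd/3.3, fine enough to resolve the kernel).
2. **Overlap.** For cells $a, b$ the per-chromosome overlap coefficient
   is the Szymkiewicz–Simpson score on the nonnegative profiles,
   $\sum_i \min(a_i, b_i) / \min(\sum a, \sum b)$ — the standard
   normalization of "overlap coefficient"; smoothed densities are used
   directly, without thresholding to supports.
3. **Distance.** $\min(1/\text{score} - 1, 1000)$, averaged over
   chromosomes.  A zero score (disjoint cells, or a chromosome with an
   all-zero profile) takes the cap 1000 so a single empty chromosome
   cannot produce infinities.
4. **Embedding.** The distance matrix is embedded in one dimension with
   UMAP (n_neighbors 15, min_dist 0.1, precomputed distances), 100
   times with distinct seeds; each axis is z-scored.  Runs are retained
   by mutual consistency: the run with the lowest mean absolute
   Spearman correlation against the current set is dropped until every
   remaining run clears 0.85 (a single-pass mean is easily poisoned by
   a few degenerate runs, which would discard everything).  Fewer than
   50% surviving runs is a hard failure.  Retained runs are sign-aligned
   to the first retained run.
5. **Consensus.** Per cell, sorted placements split into clusters at
   successive gaps ≥ 0.1 (z units, since clustering operates on the
   z-scored axes); the cell is kept when its largest cluster holds at
   least 80% of retained runs, and its consensus is the cluster mean.
   Consensus values are rank-rescaled to S-phase progression in [0, 1].

The direction of the axis is not identifiable from overlap alone.  When
a reference timing track is available, `earlyFraction()` anchors the
axis so that progression 0 is early S (cells whose reads concentrate in
the earliest-replicating decile get low positions); otherwise the
orientation is arbitrary and reported as such.

# Track segmentation (hidden semi-Markov model)

Inter-read distances per chromosome are modeled with a two-state
explicit-duration hidden semi-Markov model: exponential emission
distributions (foreground = short gaps inside a track, background =
long gaps between forks), a gamma sojourn distribution per state with
durations counted in gaps, and forced state alternation.  Each
chromosome is one observation sequence; all of a cell's chromosomes
share one model.

Numerical choices:

* Emission means are initialized at the 10th/90th percentiles of the
  gaps (scale-free); sojourns start at shape 2, scale 2.5 (mean dwell
  5 gaps); EM runs at most 200 iterations to relative tolerance
  $10^{-6}$.
* The gamma sojourn is discretised by normalizing its density on
  durations 1..Dmax (Dmax = 300 gaps or the sequence length) and is
  updated by method of moments inside the M-step (closed form, stable).
* The final sojourn of each sequence is treated as uncensored; the
  exhaustive-enumeration oracle in the tests uses the same convention.
* Viterbi ties resolve toward background (conservative track calling).
* If the two emission means collapse (ratio < 1.2), the model falls
  back to a quantile-threshold segmentation (gaps below the 25th
  percentile are foreground) with a warning.

Maximal runs of foreground gaps become *tracks*: the reads flanking the
run were laid down by one polymerase.  The observed width $w$ (first to
last read) underestimates the labeled stretch; in analogy to estimating
the range of a uniform sample, the corrected width is $w + w/(n-1)$ for
a track with $n$ reads.  The width-based (single-pulse) speed is the
corrected width divided by the 15-min pulse length, summarized per cell
by the median.  For the fork-versus-depth sensitivity analysis the
model is *refit* at each downsampling fraction, since a cell's gap
distribution changes with depth.

# Double-pulse speed estimation

With two EdU pulses separated center-to-center by $\Delta t$ (45, 75 or
105 min), each fork leaves two labeled patches a distance
$\Delta x = v\,\Delta t$ apart.  The *pair correlation* — all
within-chromosome pairwise distances between a cell's reads, truncated
at 400 kb — then shows three features: short intrapulse distances, an
interpulse peak near $\bar{\Delta x}$, and a flat interfork background.
Distances must be computed within single cells: pooling cells adds
cross-cell pairs that bury the interpulse peak.

A four-component mixture (uniform on (0, 400 kb], exponential,
half-normal anchored at 0, normal) is fitted to the raw distances by EM
with soft labels: weighted means update the exponential and normal
components, weighted variances the half-normal and normal.  The
exponential mean is constrained above 1,000 bp and its weight above
0.01, projected each iteration, preventing it from absorbing the
sub-restriction-fragment scale.  Iteration stops at relative tolerance
$10^{-8}$ or 100 iterations.  Initialization: exponential mean 5 kb,
half-normal sd 10 kb, uniform weights, and the normal mean seeded at
the mode of the 5-kb-binned distance density beyond 20 kb, which avoids
label switching between the intrapulse and interpulse scales; a
collapsing normal component triggers up to three restarts from
perturbed seeds.  The per-cell speed is
$\bar{\Delta x} / \Delta t$, with percentile bootstrap intervals
(B = 100, a cost/precision compromise) from refits on resampled
distances.

## Sampling-bias correction

Sequencing samples labeled DNA roughly uniformly per kb, so faster
forks — which lay longer labeled patches — contribute proportionally
more read pairs.  Pooled over forks with heterogeneous speeds, the
fitted interpulse mean is biased upward (weight roughly $\propto s^2$
for a fork with speed factor $s$, as both pulses lengthen).

The correction is simulation-based.  For each (mean $\mu$, sd $\sigma$)
of a truncated-normal speed-factor distribution, forks are simulated as
Poisson(80) candidate reads uniform on ±200 kb, retained inside the
scaled windows $(-45s, -30s) \cup (30s, 45s)$ (windows centered ±37.5,
i.e. 75 kb apart at $s = 1$: 1 kb/min at $\Delta t$ = 75 min); pooled
within-fork distances are fitted with the mixture, giving the measured
(mean, sd) for that ground truth.  Local quadratic regressions (span
0.75, direct surface) of $\mu$ and $\sigma$ on the fitted (mean, sd)
invert the mapping; `applyCorrection()` predicts ground truth from
measured values, clamping out-of-hull queries to the grid boundary with
a flag.  In the constant-per-kb ("equal intensity") regime the retained
read count scales with $s$ and the bias appears; the alternative
"unequal" mode, which scales the candidate support by $s$ so every fork
retains the same expected count, is provided as the unbiased control.
At $\sigma = 0$ all forks share one speed, no reweighting is possible,
and the correction is the identity up to simulation noise.

The default grid is $\mu \in \{0.4, \ldots, 2.0\}$ kb/min (step 0.2),
$\sigma \in \{0, \ldots, 0.6\}$ (step 0.1), 2,000 forks per point,
bracketing observed mammalian fork speeds; the test suite uses a
reduced 4 × 3 grid at 250 forks per point, which bounds the surface
build below a minute while preserving both qualitative checks.

# Annotation-conditioned analyses

* **RT score.** Replication timing per 10-kb bin from early/late
  fractions: $(\text{early} - \text{late})/(\text{early} + \text{late})$,
  undefined (excluded) when both are zero.
* **Initiation-zone correlation.** Cells are ordered, their 100-kb
  binned reads accumulated prefix by prefix, and each prefix correlated
  (Pearson) with an origin-mapping signal; cohorts replicating out of
  genuine origins correlate most strongly in the earliest prefixes.
* **Expression transform.** Gene counts become
  $\mathrm{round}(\log_{10}(\text{counts}+1))$; overlapping genes are
  resolved by giving the higher raw count priority on the shared
  stretch, ties to the earlier interval start (determinism).  The
  S-phase pseudo-bulk gate on cell-cycle scores is implemented as the
  conjunction 0.333 < score < 0.75 — the only reading under which the
  gate selects a subset.
* **Region-weighted speed densities.** Each pairwise distance defines
  the genomic span between its two reads; its weight inside a region
  class is (fractional span overlap) × (mixture posterior of the
  interpulse component at that distance), the complement weighting the
  outside density.  Densities over implied speeds (distance/$\Delta t$)
  are max-normalized; significance uses 10,000 resamples per density
  and a two-sided t-test, Bonferroni-corrected across region classes
  by the caller.

# The simulators, and what passing tests show

Three generators, all bit-reproducible under a seed:

* `simulatePulseTracks()` — independent tracks, Poisson reads per pulse
  placed uniformly in windows of length pulse_len × speed (1 unit =
  15 kb at 1 kb/min, making the ground truth explicit in physical
  units); single tracks rather than fork pairs.  This is the design
  used to compare the width-based and cross-pulse estimators.
* `simulatePairCorrCell()` — the per-fork windowed-retention design
  described under the bias correction.
* `simulateWholeCell()` — bidirectional origins on a genome (two
  divergent forks each, sharing a firing age drawn uniformly up to
  60 min pre-pulse so sister forks separate), truncated-normal per-fork
  speeds, uniform read sampling within labeled windows at a density
  expressed as the recovered fraction of 250-bp restriction fragments,
  plus uniform background.  An optional replication-timing function
  with a per-cell stage weights origin placement
  ($\exp(-(\tau - \text{stage})^2 / 2\,(0.08)^2)$), giving cohorts the
  S-phase structure ordering needs.  Cohort tests use 2 × 20-Mb
  genomes with 60 forks per cell; the ordering recovery test uses 100
  cells, the bootstrap-coverage experiment 100 replicates of 2,000
  distances — sizes chosen so each suite run stays lightweight while
  the statistics remain well-resolved.

The simulators emulate uniform within-track sampling, fork-speed
heterogeneity, background reads and stage-structured origin firing.
They do **not** emulate restriction-site spacing (reads are uniform,
not on a ~250-bp lattice), mappability or copy-number variation,
sequencing error, fork stalling, or origin firing during/between the
pulses.  Passing tests therefore demonstrate correctness of the
estimators under the stated sampling model, not robustness to every
artifact of real libraries; the package's QC and the HSMM's background
state carry that burden on real data.

# Known limitations

* Tracks from two young sister forks of one origin merge when the
  origin fired shortly before labeling; the model cannot split them
  (nor resolve initiation sites within a zone).
* The width-based single-pulse speed degrades at low read depth even
  with the $w + w/(n-1)$ correction — the motivation for the
  double-pulse design.
* The mixture's exponential/half-normal split of intrapulse distances
  is a descriptive decomposition; only the normal (interpulse)
  component is interpreted quantitatively.
* The interpulse-component sd (`normal_sd`, and its corrected value)
  is the closest available proxy for within-cell speed variability.
* Axis orientation requires external timing information; without it,
  progression is defined up to a flip.
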