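---
title: "Quantifying live microbial load in longitudinal saliva samples"
author: "microload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying live microbial load in longitudinal saliva samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microload)
```

## The measurement problem

Amplicon sequencing of a saliva sample returns relative abundances: it says
nothing about how many microbial cells the sample contained, and it counts
DNA from dead or lysed cells ("relic DNA") alongside DNA from living ones.
`microload` implements a workflow that measures both missing quantities.
Each timed, unstimulated saliva collection is split into a *raw* aliquot and
an aliquot treated with propidium monoazide (PMA), a dye that crosslinks and
destroys DNA not protected by an intact membrane. Both aliquots are stained
with a DNA dye and counted by flow cytometry against a spike of counting
beads, and both are sequenced. The PMA arm therefore reports *live* cells
and *live* composition; the raw arm reports totals; their difference is the
dead (relic) signal.

The package covers four analysis stages, plus a synthetic-cohort generator
that makes every stage testable end to end without any external data:

1. **cytometry** — gate event tables into bacterial singlets and beads,
   convert to absolute concentration;
2. **viability** — paired raw/PMA live/dead/percent-live metrics, salivary
   flow rates, baseline-normalised trajectories, qPCR standard curves;
3. **composition** — feature-table QC and collapse, centred log-ratio and
   Aitchison distance, unweighted UniFrac, Faith's phylogenetic diversity
   with rarefaction, principal coordinates;
4. **dispersion statistics** — per-participant convex-hull volumes in
   ordination space, within/between distance groupings, and a permutation
   Kruskal–Wallis test for grouped distances.

## Gating model

Events arrive as per-event intensities
(`FL1_A/FL1_H/FL1_W/FL4_A/FSC_A/BSC_A`). The composed gate
(`gateEvents()`) applies three stages in a fixed order:

1. *DNA-positive gate*: events with `FL1_A >= fl1Min` are DNA-positive;
   among them, `FL4_A >= fl4BeadMin` identifies counting beads. Beads are
   identified **before** cell counting so they can never contaminate the
   cell gate.
2. *Doublet exclusion*: the FL1 pulse height/width ratio of aggregates
   departs from the singlet linear trend. We keep events within a relative
   band (default ±30%) of the **median** ratio — a robust, parameter-light
   alternative to fitting the trend by regression. Instrument conventions
   differ on whether height-vs-width or height-vs-area carries the trend,
   so both axes are carried in the event schema and `doubletDenominator`
   selects one ("width" by default).
3. *Scatter gate*: events with forward or back scatter above the configured
   ceilings (human cells, large debris) are excluded. All threshold
   comparisons are inclusive.

The gates are rectangular thresholds rather than kernel-density polygons:
published instrument settings are percentile-based and machine-specific, so
the thresholds are user configuration, with defaults matched to the
synthetic event clouds. The five resulting counts (cells, beads, doublets,
large, sub-threshold) always partition the event total exactly — this is a
class invariant of `GatedCounts`, not just a convention.

Absolute concentration follows the counting-bead rule
\[
\mathrm{cells/\mu l} = \frac{n_{cells}}{n_{beads}} \cdot
\frac{\mathrm{beads\ added}}{\mathrm{sample\ volume\ (\mu l)}},
\]
scaled by 1000 and the dilution factor to give cells per ml of neat saliva.
A zero gated bead count signals a failed bead spike and raises an error
rather than returning an infinite concentration.
`glycerolDilutionFactor()` reconstructs the dilution for samples drooled
onto a glycerol cushion and later diluted in PBS.

## Viability metrics

`pairViability()` takes the matched raw/PMA records: live = PMA count,
total = raw count, dead = total − live floored at 0, percent live capped at
100. The floor and cap exist because two independent Poisson-noise
measurements can put the PMA count above the raw count; a percentage above
100 is a measurement artefact, not information. A zero total leaves percent
live missing rather than dividing by zero. Trajectories are normalised to
the first collection of each participant (`normalizeToBaseline()`), so a
value of 100 means "unchanged from baseline".

qPCR loads are estimated from a ten-fold serial-dilution standard ladder
(default 1.3 to 1.3e7 copies, 8 levels): `fitStandardCurve()` averages
replicate Cq values per level, fits Cq on log10(copies) by least squares
and reports amplification efficiency \((10^{-1/slope}-1)\times 100\);
`copiesFromCq()` inverts the line. Load–flow correlations use Pearson's r
on log10 concentration; zero or negative values are dropped before the log
with a reported exclusion count rather than pseudocounted, since a zero
cytometric load means the sample failed quantification.

## Compositional analyses

Feature tables are stored as a `SummarizedExperiment` subclass with taxa in
rows, a taxonomy string per taxon and sample metadata in `colData`.
Quality control mirrors standard amplicon practice: drop samples under a
minimum depth (inclusive boundary), then remove chloroplast and
mitochondrial taxa by case-insensitive substring match — the matching is
deliberately loose to absorb differing taxonomy-database label dialects.
`chloroplastSummary()` quantifies food-derived chloroplast contamination
(prevalence and mean relative abundance) stratified by after-meal status
and processing arm before it is filtered away.

The distance stages follow their standard definitions: clr with a
pseudocount (default 1 on count tables; zeros with a zero pseudocount are
an error rather than silently dropped), Aitchison distance as Euclidean
distance on clr rows, unweighted UniFrac as unique-over-covered branch
length on presence/absence (presence = count ≥ 1, applied after
rarefaction when rarefying), Faith's PD as the spanning branch length
including the path to the root, and PCoA as classical metric scaling.
Negative PCoA eigenvalues are discarded without correction and proportions
explained are relative to the positive eigenvalue mass. Matrix-completion
variants of Aitchison ordination are not reimplemented; clr-PCA on
pseudocounted data is the Aitchison-space ordination offered, and
UniFrac-PCoA is what the hull analysis consumes.

UniFrac and Faith's PD run on a tips-by-edges incidence matrix built in a
single postorder pass, so all pairwise comparisons reduce to vectorised
branch-length sums. Both are checked in the test suite against independent
oracles: exhaustive branch-set enumeration for UniFrac on all tree sizes up
to six tips, and an established phylogenetic-diversity implementation for
Faith's PD.

## Dispersion statistics

**Convex hulls.** A participant's temporal dispersion is the volume of the
convex hull of their samples in the first three principal coordinates.
Because no 3-D hull backend is available as a dependency, the hull is
implemented in-package as an incremental (beneath-beyond) construction:
maintain an outward-oriented facet list, and for each new point replace the
facets it can see with the fan over its horizon edges; the volume is the
sum of signed tetrahedra around an interior reference point. Point sets
with fewer than four points or with affine rank below three (detected by
singular values, relative tolerance 1e-10) return volume 0 with a
`degenerate` flag instead of erroring, so participants with few samples
remain comparable in paired analyses. The tests verify exact closed forms
(unit tetrahedron 1/6, unit cube 1), rigid-motion invariance at 1e-9,
cubic scaling, monotonicity under added points, and equality with an
independent brute-force supporting-plane oracle on random point sets.
Matched raw/PMA hull volumes are compared with a two-sided paired t-test
(`pairedHullTest()`).

**Permutation Kruskal–Wallis.** Grouped pairwise distances are not
independent observations, so group differences are tested by label
permutation: compute the tie-corrected H on the observed labels, shuffle
labels uniformly `nPermutations` times (sampling shuffles with replacement
from the permutation group), and report
\(p = (\#\{H_{perm} \ge H_{obs}\} + 1)/(n_{perm}+1)\).
The exceedance is inclusive (≥) under the add-one convention; the smallest
attainable p is exactly \(1/(n_{perm}+1)\) and all-tied data give H = 0 and
p = 1. The test shuffles the labels of the distance observations themselves
(the natural unit for pre-grouped distances), not of the underlying
samples. The suite checks the sampled p against exhaustive enumeration of
all 20 assignments of a 3+3 toy and verifies super-uniformity of the null
p distribution over 500 simulated datasets.

## The synthetic cohort generator

`simulateCohort()` emulates the two study designs the analysis targets:
*daily dynamics* (10 participants × 9 timepoints through one day) and
*acute perturbation* (28 participants × 3 timepoints — baseline, 15 min,
2 h — balanced over water, antiseptic mouthwash, alcohol-free mouthwash and
soda). All defaults are the study conditions; every stage draws from a
named substream of one master seed so cohorts, event tables, count tables
and qPCR readouts can be regenerated independently and reproducibly.

*Loads.* Live load per 5-minute collection is a log-normal random walk:
participant baselines log10 ≈ 8.35 ± 0.6 (about 2×10⁸ cells, spanning more
than three orders of magnitude across a cohort), within-day steps of 0.4
log units so a day spans at least tenfold. The waking sample carries the
participant's daily maximum. Collection volumes derive from a log-normal
flow-rate distribution (clipped to 0.02–1.56 ml/min, mean ≈ 0.48); because
concentration is collected cells over collected volume, the negative
load–flow coupling emerges from dilution rather than being imposed.

*Perturbation kernels* are multiplicative factors on the live (L) and relic
(R) pools: tooth-brushing multiplies both pools by 0.3 (physical removal);
alcohol-free mouthwash multiplies L by 0.05 at the 15-minute sample and
moves the killed cells into R (totals conserved — kill without removal),
with full return of L to baseline at 2 h; antiseptic mouthwash applies its
kill (0.3) only at the 2-hour sample (delayed action); water and soda are
null kernels. The generative model is the package's own choice — the
underlying study reports observed ranges, not a model — and "full return to
baseline" is modelled literally.

*Compositions.* A fixed cohort base composition gives 16 dominant oral
genera (Streptococcus, Prevotella, Veillonella, …) across five phyla ~93%
of the mass on a gentle geometric decay, with a low-abundance tail that
includes exactly one Treponema ASV outside the five dominant phyla. Each
participant perturbs the base log-normally (SD 0.6); each timepoint
perturbs the participant's live composition log-normally (SD 1.0). The
relic composition is the participant composition tilted toward the
designated dead-associated taxon (Treponema, natural-log fold 2) and held
constant over time. These three SDs encode the structure the analysis is
meant to detect: core genus ranks conserved across people, strong
within-day turnover of the live pool, and a temporally stable relic pool.
Raw samples draw reads from the live/relic mixture weighted by pool sizes,
so the stable relic pool damps apparent raw-arm variation — which is why
per-participant hulls grow when the relic signal is removed, and why
within-participant Aitchison distances stay below between-participant
distances in both arms.

*Contamination.* Post-meal raw samples receive a chloroplast taxon at 0.6%
relative abundance with high probability (0.8); PMA samples at a quarter of
that prevalence; off-meal backgrounds are 0.16/0.04 at trace abundance.

*Event clouds.* `simulateEvents()` emits log-normal clusters for bacteria,
debris, human cells, doublets (pulse width inflated 2.2×) and beads, with
event counts proportional to concentration × acquired volume (Poisson, or
exact rounded expectations with `exact = TRUE` for noise-free closed-loop
tests). The generator writes a ground-truth `population` label per event
that the gating code never reads; tests use it to score misclassification.

What the generator does **not** emulate: sequencing error and chimeras,
spectral spillover and fluorescence drift, compositional interactions
between taxa, participant covariates (age, sex), or any real phylogenetic
signal (the tree is random). Passing tests therefore demonstrate that the
pipeline recovers what the generative model encodes — kernel arithmetic,
absolute quantification, dispersion contrasts — not that it would recover
them from any particular real data set.

## Numerical choices and problem sizes

- Gate thresholds are inclusive; gating is order-stable under event
  permutation.
- clr requires a positive pseudocount whenever zeros are present; zero-sum
  samples are errors.
- Distance matrices are validated for symmetry (1e-12), zero diagonal and
  finiteness on construction; PCoA rejects non-symmetric input.
- Hull degeneracy uses a relative singular-value tolerance of 1e-10;
  facet visibility a relative tolerance of 1e-9 of the point-cloud
  diameter.
- Permutation ties in the exceedance comparison are counted inclusively
  with a 1e-12 guard.
- The test and acceptance runs use desk-scale problem sizes chosen to keep
  the full suite under a minute while leaving comfortable statistical
  margins: cohorts of 2–20 participants, sequencing depths of 1500–20000
  reads, event streams of 2000–50000 events, 100–10000 permutations.

## Known limitations

- The hull statistic is volume in exactly three ordination axes; axes
  beyond the third are ignored, as in the analysis it reproduces.
- The permutation test treats distance observations as exchangeable under
  the null; residual dependence between pairs sharing a sample is ignored,
  exactly as in the procedure it implements.
- `rarefyTable()` subsamples without replacement per sample; diversity
  metrics on unrarefied tables remain depth-confounded and are the user's
  responsibility.
- The event simulator's clusters are well separated by construction;
  threshold sensitivity on real instruments will be larger than the
  misclassification rates the tests report.
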