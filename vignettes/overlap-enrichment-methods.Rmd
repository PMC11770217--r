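---
title: "Gene-overlap enrichment: model, null, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-overlap enrichment: model, null, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlapenrich)
```

This vignette is the package's account of the statistics it implements:
what is being estimated, under what assumptions, which knobs matter, and
where the design was genuinely open and a choice had to be made.

## The estimand and its assumptions

For a trait with a set of independent genome-wide significant loci, the
pipeline asks whether the *genes* those loci implicate overlap a genomic
annotation more than random placement would predict. The unit of evidence
is the gene (full gene-body span), not the variant: a trait whose
associated genes sit disproportionately inside, say, fast-evolving
regions is called enriched regardless of where within those genes the
lead variants fall. This is deliberately complementary to
heritability-partitioning methods, which weight every variant and are
unreliable for annotations covering few common SNPs.

Assumptions worth stating explicitly:

* **Loci are independent.** LD clumping happens upstream; the package
  treats each hit as one draw. Correlated hits would overcount evidence.
* **Gene length is the dominant confounder.** The null matches the
  element set's length profile but nothing else (no GC, gene-density or
  chromosome matching). Annotations that cluster near long genes for
  reasons other than length will look enriched.
* **The annotation is unstranded merged intervals.** All interval
  arithmetic ignores strand, and annotations are merged before use so a
  base pair is counted once.

## Element sets

Each hit maps to the closest feature within `dist_bp` (default 5,000 bp,
window inclusive) whose biotype is on a whitelist (default: the
protein-coding-like labels, from `protein_coding` through the
immunoglobulin/T-cell-receptor segment genes to `polymorphic_pseudogene`;
fully overridable). Distance is the number of bases between the variant
base and the nearest feature base, zero inside the feature. Ties — two
whitelisted features equidistant from a hit — are broken by smaller start
coordinate, then lexicographic feature id; the tie-break is arbitrary but
fixed, because mapping must be deterministic for reproducible runs.

Mapped features are deduplicated; traits with fewer than
`min_set_size = 50` unique elements are rejected (a typed outcome, not an
error, so batch drivers can log them). 40 is kept as a documented laxer
preset; both thresholds appear in the literature of this method family
and neither is canonical here.

## The length-matched null and the Weibull tail

The test statistic is intersections per base pair: the number of elements
with any overlap, divided by the element set's total length. Gene lengths
are roughly log-normal, so the null matches length by deciles: the
element lengths are sorted and cut into 10 contiguous index groups (group
k spans indices `floor((k-1)N/10) .. floor(kN/10)-1`), and each group
contributes `n_k` random intervals of the group's mean length (rounded to
1 bp). Placement is uniform over the genome with chromosome probability
proportional to the number of valid start positions; background intervals
may overlap each other or real genes — no masking, since the observed
statistic is computed on an unmasked genome too.

One seed drives all replicates: the placements for all `n_reps` (default
1,000) background sets are drawn in a single vectorised pass and
intersected with the annotation in one sweep, so a fixed seed reproduces
the background exactly and a full study stays inside desk-scale runtimes.

A two-parameter Weibull is fitted to the positive replicate values by
maximum likelihood (moment-based initialisation; the sample is rescaled
by its median before fitting because intersections-per-bp values of order
1e-5 underflow the optimiser, and the Weibull family is scale-equivariant
so the scale estimate maps back exactly). The p-value is the upper tail
`exp(-(x/scale)^shape)`. Zero-valued replicates are excluded from the fit
(Weibull support is positive); if more than half the replicates are zero,
or the background is degenerate (constant), the p-value falls back to the
empirical rank `(1 + #{values >= x}) / (n_reps + 1)` and the result row
says so in `fit_note`.

### What the Weibull approximation can and cannot deliver

The background statistic is a scaled count, so its distribution is
discrete — at desk scale (60-element sets, 5% annotation coverage) it has
perhaps 15–20 atoms. An exact upper-tail p-value on a discrete statistic
is *conservative between atoms*: its distribution under the null sits at
or below uniform, never above. Simulation with the package's own
generator shows type-I error at nominal 0.05 of about 0.04–0.06, but a
Kolmogorov–Smirnov test of p-value uniformity across hundreds of null
traits sits near the rejection boundary and fails at some seeds — and
replacing the Weibull with the exact Poisson-binomial null makes the
conservatism *worse*, so this is a property of exact tail p-values on
discrete counts, not a fitting defect. Users should treat the p-values as
mildly conservative at small counts; with larger element sets or broader
annotations the statistic becomes effectively continuous and the issue
vanishes.

## Enrichment, FDR, and concordance

The reported effect is the percent difference
`I = (observed - mean(bg)) / mean(bg) * 100`. Both the per-bp statistic
(primary) and the raw overlap count enter this formula in the output
(`I_percent`, `I_percent_count`); they differ only because background
sets match total length approximately (decile means), and on synthetic
data the two agree closely. `I` is undefined when the background mean is
zero — flagged rather than reported. BH adjustment runs over all rows of
an invocation by default; a per-annotation family is available because
which family is "the" family is a genuine modelling choice that depends
on how results are reported.

Concordance between two methods' results tables (e.g. this method versus
a heritability-partitioning run) ranks each table independently, pairs on
(trait, annotation), and applies a two-sided Wilcoxon signed-rank test to
the paired rank differences (zeros dropped, ties mid-ranked, exact null
up to 25 informative pairs). One structural caveat documented on the
function: both rank vectors are permutations of 1..n, so the paired
differences always sum to zero and the test only detects *asymmetric*
disagreement; a perfectly reversed ranking yields p near 1. It answers
"is one method systematically ranking some results much higher than the
other", not "are the rankings correlated".

## Meta-analysis by trait category

Categories of traits (skeletal, psychiatric, ...) are summarised by a
random-effects model that must respect the genetic correlation among the
traits' GWAS: `y = mu·1 + u + e`, `Cov(e) = diag(s) R diag(s)`,
`Cov(u) = tau² I`. The source material for this design does not state
where the correlation matrix enters the error structure, so that choice
was open: this package puts `R` in the *sampling* covariance (correlated
GWAS errors, independent trait-level deviations) and offers
`struct = "tau2R"` (correlated random effects) behind a switch rather
than presenting either as canonical. `tau²` is REML-estimated by bounded
1-D optimisation on `[0, 10·var(y)]`; `mu` by GLS; non-positive-definite
`R` inputs are repaired by eigenvalue clipping at 1e-8 and rescaling to
unit diagonal.

Inference uses a Student-t reference with `n - 1` degrees of freedom by
default rather than the normal. This is a deliberate design choice:
categories hold a handful of traits, `tau²` is estimated from those same
few values, and in the package's own recovery simulations (8 traits per
category, exchangeable correlation 0.5) the normal reference covers a
true summary effect at only ~89% for a nominal 95% interval, while the t
reference restores ~93–97%. The implementation was cross-checked against
an independent multivariate meta-analysis routine, which agrees on the
point estimate, standard error and `tau²` to numerical precision — the
undercoverage is a property of the z reference, not of the estimator.
`ref = "z"` restores the plain normal reference.

## Perturbation robustness

Annotations produced by computational pipelines are uncertain at the base
pair level, so results should not hinge on exact boundaries.
`perturbation_study()` reruns the whole enrichment stage under (a) random
90% subsets of regions (3 replicates), and (b) every region shrunk or
extended by 5% of its own length at each end (so total length changes by
about 10%), then reports Pearson correlations of the enrichment vector
and of the −log10 p vector against the original run. Per-trait background
seeds are reused across perturbations so the correlation isolates the
annotation change; recomputing backgrounds per perturbation would fold
Monte-Carlo noise into r. A caveat that follows from "5% of the region's
own length": extend-then-shrink does not return exactly to the original
(the second step sees a longer region), but to within
`~2·0.05²·length` bp.

## The synthetic-data generator

`simulate_study()` emulates the study conditions the pipeline is designed
for: equal-length chromosomes (default 2 × 10 Mb), log-normal gene
lengths (median 2 kb, sigma 0.5 — a realistic shape for gene bodies at
this scale), 80% protein-coding genes, a clustered annotation grown from
log-normal regions (median 1 kb) to a 5% merged genome fraction, and 60
significant loci per trait placed within half the mapping window of their
source gene. Planted enrichment is gene-level: with probability `rho` a
hit's source gene is drawn from genes overlapping the annotation. The
planted truth is therefore interpretable in the same currency the
statistic counts — overlapping elements — and `rho = 0` is an exact null.

What it does *not* emulate, and what passing tests therefore do not show
about real data: LD structure among loci, allele frequencies and
effect-size architecture, GC/repeat content, chromosome-scale
heterogeneity of gene density, and any correlation between annotation
placement and gene features beyond length. One mapping subtlety is
deliberate: because hits land in gene flanks, closest-gene mapping can
capture a near neighbour of the planted gene on dense synthetic genomes,
so recovered overlap fractions at `rho = 1` are high but not exactly 1 —
the same attenuation a real nearest-gene assignment suffers.

Problem sizes used by the validation suite and the acceptance script —
chosen as comfortable desk-scale settings — are 500 null traits (type-I
and uniformity checks, 200 background replicates each), 30 traits per arm
over `rho` in {0, 0.2, 0.5, 0.8}, 200 simulated 8-trait categories for
meta-analysis recovery, and 30 traits for the perturbation study.

## Numerical and degenerate-input policy

* Coordinates are BED-convention 0-based half-open everywhere internally;
  1-based inputs (gene TSVs, variant positions) convert at the parser
  boundary, once.
* Book-ended intervals merge; chromosome order is natural-sorted; all
  writers emit sorted output with fixed 6-decimal formatting so reruns
  under one seed are byte-identical.
* Overlap counting is element-wise (an element counts once no matter how
  many annotation intervals it touches); pair counting is available as a
  sensitivity mode.
* Empty annotations, whole-genome annotations, all-zero backgrounds and
  single-region perturbations are all defined, flagged outcomes rather
  than errors; division-by-zero cases (empty element set, zero background
  mean) raise immediately with a message naming the quantity.
* p-values are clamped into `(0, 1]`; Weibull underflow for extreme
  observations cannot produce a reported zero.
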