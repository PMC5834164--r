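---
title: "Reference-gene stability: models, conventions and simulation design"
author: "refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability: models, conventions and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

# The problem

A qRT-PCR fold change is only as good as its normalizer. Every sample
carries a multiplicative technical factor — RNA input, reverse
transcription yield, pipetting — which on the Cq (quantification
cycle) scale is an *additive per-sample offset*: one PCR cycle is one
doubling, so Cq is a negative log2 expression measure up to a
constant. Normalizing against reference genes subtracts that offset
out, provided the references really are constant across conditions.
`refstab` implements the four standard statistics used to test that
assumption, aggregates them into a single ranking, and validates the
chosen set on targets with known expression patterns. The motivating
application is a developmental time-course in potato cyst nematodes
(dry cyst through hatching stimulation to infective J2 larvae), a
regime where classical housekeeping genes (actin, translation factors)
are known to wander.

# Data model

`CqExperiment` and `CountExperiment` extend `SummarizedExperiment`:
genes in rows, replicate samples in columns, with mandatory
`condition` and `replicate` column metadata. Replicates enter all
analyses as independent samples (e.g. 8 conditions × 3 replicates = 24
samples) rather than being averaged per condition: averaging first
would discard the within-condition variance that several of the
statistics estimate. Whether replicates are technical or biological is
not encoded; the model treats them uniformly.

Missing Cq cells are allowed on input (`NA`); each method applies its
own policy:

* geNorm / comparative ΔCt: pairwise-complete (a sample is dropped
  only for pairs it is missing in), requiring ≥ 3 complete samples per
  gene pair;
* BestKeeper: per-gene listwise (each gene uses its non-missing
  samples; the index uses the genes available per sample);
* NormFinder: complete samples only — the per-sample mean across genes
  is the estimated sample effect, which couples genes within a sample,
  so partially observed samples are excluded rather than distorting
  the effect estimate.

# The four stability statistics

All four treat Cq as log2-scale expression. An optional per-gene
amplification efficiency E ∈ (1, 2] (`geneEfficiencies`) rescales Cq
by log2(E) in the pairwise kernel and in 2^−ΔΔCt; the default is E = 2
throughout (perfect doubling), the convention under which the classic
2^−ΔΔCt method is derived and under which Cq differences are exactly
log2 ratios. Efficiencies estimated from amplification curves
(typically reported as 80–100 %) can be supplied but do not change any
rank-based conclusion in the regimes the tests cover.

**Pairwise kernel.** V<sub>jk</sub> = SD over samples of
(Cq<sub>j</sub> − Cq<sub>k</sub>) (sample SD, n − 1 divisor). A
per-sample loading offset added to *all* genes cancels in the
difference — this invariance is the reason difference-based statistics
target exactly the stability that matters for normalization, and it is
asserted to 1e−9 cycles in the tests. BestKeeper's raw-Cq SD does
*not* have this invariance; that asymmetry is inherent to the method
and preserved here.

**geNorm.** M<sub>j</sub> is the mean of V<sub>jk</sub> over the
current candidate set; the gene with the largest M is excluded
(ties: the alphabetically last of the tied genes, a deterministic
convention) and M recomputed until two genes remain. The final pair is
indistinguishable by construction — M is defined against other genes —
so both genes are reported at rank 1 and the next gene at rank 3
(competition ranking). The first-pass M equals the comparative-ΔCt
statistic exactly (machine precision, an algebraic identity checked on
100 random tables).

**Comparative ΔCt.** Mean of V<sub>jk</sub> over k ≠ j, no iteration;
exact ties get fractional ranks.

**BestKeeper.** Per-gene SD and CV% of raw Cq (sample convention,
n − 1; the original description uses the population divisor — the
choice affects all genes by the same factor and no rank), plus Pearson
r against the per-sample geometric mean of all candidates' Cq. Ranked
by SD, ties by higher r. Requires strictly positive Cq (geometric mean).

**NormFinder.** On y = −Cq, the per-sample across-gene mean is removed,
then per gene i and condition group g the intergroup bias
d<sub>ig</sub> (deviation of the group mean residual from the gene's
across-group mean; Σ<sub>g</sub> d<sub>ig</sub> = 0) and intragroup SD
s<sub>ig</sub> are computed; stability = mean over groups of
(|d<sub>ig</sub>| + s<sub>ig</sub>). This is the transparent
bias-plus-variance form; the original model's small-sample shrinkage
of the variance estimates is deliberately not reproduced, so absolute
values are not comparable across software while orderings are. Every
group needs ≥ 2 samples; a single group degrades gracefully (bias ≡ 0,
warning).

`cqSpread` supplies the descriptive counterpart: per-gene box-plot
statistics (type-7 linear-interpolation quartiles, whiskers at 1.5 IQR,
outliers, total span). Span ordering is a useful first look but is not
a stability statistic — a gene with narrow spread can still covary
with treatment.

# Comprehensive ranking

Following the RefFinder approach, the per-method "weights" are the
ranks themselves, and a gene's comprehensive score is the geometric
mean of its M ≥ 2 ranks. Conventions, frozen after checking them
against published panels bundled in `inst/extdata`:

* method ranks use ascending competition ranking ("1223"), with
  geNorm's tied final pair contributing ranks (1, 1, 3, …) — the
  competition form, not the dense (1, 1, 2, …) form, is what
  reproduces the published comprehensive orders;
* exact geometric-mean ties are broken by the arithmetic mean of
  ranks, then gene name, and are annotated.

The bundled *G. rostochiensis* RNA-Seq and qRT-PCR panels are
reproduced exactly, full order, by this aggregation. For the bundled
*G. pallida* panel the published middle positions (3rd–5th) are not
recoverable from its printed per-method columns under either tie
convention — the aggregation here yields aaRS before PMP-3 and mce1 —
so only the extreme positions (most stable: AMA-1; least stable:
Act-1) are asserted in tests and recomputed by
`scripts/acceptance.R`. The discrepancy is reported rather than
patched.

Two comprehensive rankings over the same panel (e.g. RNA-Seq and
qRT-PCR) are combined by `aggregateAcrossDatasets`, which sums both
the geometric-mean scores and the final ranks.

# RNA-Seq screen

`normalizeCounts` scales each library so its factor (total count, or
upper quartile of nonzero counts) equals the geometric mean of all
factors; `screenCandidates` scores log2(x + 1) expression by SD across
all samples, with the range of per-condition means as tie-breaker —
dispersion "through treatments" and overall dispersion in one
ordering. Replicate-level SD (not SD of condition means) is the
primary score: with two replicates per condition, condition means are
noisy, and the replicate-level SD uses all information. The zero
filter runs on *raw* counts at the *condition* level: a gene whose
counts sum to zero in any whole condition is excluded (a single
zero replicate is not disqualifying), and the pseudocount can never
mask absence. The log2(x + 1) pseudocount keeps zeros representable;
its price is that library-scaling invariance is exact only up to
~1e−3 on scores at realistic depths (the tests assert this tolerance
and identical selections).

`countsToCq` maps normalized log2 expression to a pseudo-Cq scale
(Cq = 30 − log2 expr; offset chosen to keep values positive and in
instrument range) so the four Cq statistics can run on RNA-Seq data.
This is an interpretation layer — differences, not absolute values,
carry the information.

# Validation: 2^−ΔΔCt and Tukey letters

The reference index per sample is the arithmetic mean of the reference
genes' Cq (= geometric mean of linear-scale quantities under E = 2).
Per replicate, ΔCt = Cq<sub>target</sub> − index and ΔΔCt = ΔCt −
mean(ΔCt over calibrator replicates); the condition summary is the
arithmetic mean and SEM of the replicate fold changes 2^−ΔΔCt, the
estimator behind conventional bar-plot displays. Two exactness notes:

* At zero noise the calibrator's mean fold change is exactly 1 and a
  planted ΔCt drop of log2(10) yields exactly 10-fold (closed forms,
  tested).
* With noise, centring makes mean ΔΔCt = 0 exactly — the *geometric*
  mean of calibrator fold changes is 1 to machine precision, while the
  arithmetic mean exceeds 1 by Jensen's inequality. The arithmetic
  estimator is reported because it is what the field's error-bar plots
  show.

Significance letters come from one-way ANOVA + Tukey HSD at α = 0.05
*on the replicate ΔCt values*, not on fold changes: Cq-scale residuals
are far closer to homoscedastic normal than the exponentiated values,
and this choice is stated rather than assumed from any source. The
compact-letter display uses the insert-and-absorb algorithm; letters
are ordered so "a" belongs to the condition with the highest mean fold
change. The degenerate all-zero-variance case is handled exactly
(unequal means ⇒ all pairs different). The display is cross-checked
against `multcomp::cld` in the suite. Statistics are per target gene;
no multiplicity correction is applied across targets.

# Synthetic data: what it emulates

The generative model for Cq
(`simulateCq`): Cq(g, s) = μ<sub>g</sub> − Δ<sub>g</sub>(c(s)) +
L<sub>s</sub> + ε, with per-sample loading offsets L<sub>s</sub> ~
N(0, σ<sub>load</sub>) and technical noise ε ~ N(0,
√(σ<sub>tech</sub>² + extraNoise<sub>g</sub>²)). The loading offset is
the key structural ingredient: it is precisely the variation that
reference-gene normalization exists to remove, and it makes BestKeeper
(not offset-invariant) behave differently from the other three — as it
does on real data. Counts (`simulateCounts`) are negative binomial
with mean libsize · q<sub>g</sub>/Σq and a configurable dispersion;
dropout-role genes are forced to zero in designated conditions to
exercise the filter.

`hatchingScenario()` freezes the study design the package targets: 8
conditions (dry cyst, hydrated cyst, 1 h–7 d of hatching-stimulant
exposure, J2), 3 qPCR / 2 RNA-Seq replicates, 14 genes — 3 stable
references (Δ ≡ 0), 6 mildly variable candidates (condition effects of
SD 0.3–0.35 cycles, the "not perfect but usable" middle class), one
high-variance candidate (0.8-cycle extra noise), one drifting
pseudo-reference with a 2.0-cycle monotone trend *and* 2.0-cycle
replicate noise, and three pulse targets (10-, 6.5- and 4-fold at
specific stages). σ<sub>tech</sub> = 0.15 cycles and σ<sub>load</sub> =
0.3 cycles are typical instrument/preparation magnitudes. The drift
gene's dispersion is set so its overall Cq spread exceeds the largest
target effect (log2(10) ≈ 3.3 cycles): that is the regime in which
normalizing by the drifting gene alone genuinely abolishes the
target's significance — the actin failure mode — rather than merely
attenuating it. A deterministic trend alone cannot produce this
failure (it shifts group means without inflating within-group
variance), which is why the pseudo-reference is both drifting and
noisy.

What the simulation does **not** emulate: real count distributions of
any particular dataset, gene-length or GC effects, amplification-curve
noise, inter-run plate effects, or correlated condition responses
across genes. Passing the planted-truth tests therefore shows the
statistics recover the right genes *under the stated generative
model*, not that any particular empirical panel is correct.

# Problem sizes and determinism

The suite's stochastic experiments use fixed seed grids chosen to keep
the whole suite under a minute: 20 seeds for the planted-truth
recovery runs (stable references in the comprehensive top 4, drift
gene in the bottom 2, abolition/retention of Tukey separation), 20
seeds for the 500-gene screen recovery, 100 random tables for the
geNorm/ΔCt identity, 50 for the brute-force oracle comparisons.
Simulations restore the caller's RNG state (`simulateCq(cfg, seed =)`
is referentially transparent), and pipeline outputs are byte-stable:
result TSVs are written with fixed 6-significant-digit formatting and
re-read bit-identically at that precision.

# Known limitations

* NormFinder values are on the simplified bias + variance scale;
  compare ranks, not magnitudes, across software.
* BestKeeper's SD responds to loading offsets by design; with large
  preparation variation its ranking can legitimately disagree with the
  difference-based methods.
* geNorm's pairwise-variation criterion for *how many* references to
  use (the V(n/n+1) statistic) is not implemented; the recommended-set
  size is a parameter (default 3).
* The 2^−ΔΔCt machinery assumes E = 2 unless per-gene efficiencies are
  supplied; strongly divergent efficiencies warrant the corrected mode.
* Tukey letters assume approximately normal, equal-variance ΔCt
  residuals within conditions; n = 3 replicates gives limited power,
  so absence of letter separation is weak evidence of equality.
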