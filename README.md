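# refstab

Selection and validation of qRT-PCR reference (housekeeping) genes.

Relative gene-expression analysis by qRT-PCR needs an internal control:
target Cq values are normalized against reference genes assumed to be
constantly expressed, which removes the sample-to-sample variation
introduced during RNA extraction and cDNA synthesis. A reference gene
that itself responds to the experimental conditions silently distorts
every fold change computed with it — classic housekeeping genes such as
actin are known offenders. `refstab` implements the standard workflow
for choosing and validating a reference set, as used across the
qRT-PCR literature (here motivated by developmental time-courses in
potato cyst nematodes, *Globodera* spp.):

1. **RNA-Seq screen** (`screenCandidates`) — library-size-normalize a
   count matrix, drop genes with zero counts in any whole condition,
   and rank the rest by the SD of their log2 expression across all
   samples (tie-break: range of per-condition means). The top *k*
   genes become qPCR candidates.
2. **Four stability statistics** on a replicate-level Cq table:
   - *geNorm* (`geNorm`): M<sub>j</sub> = mean over k≠j of
     V<sub>jk</sub>, where V<sub>jk</sub> = SD over samples of
     (Cq<sub>j</sub> − Cq<sub>k</sub>); the worst gene is excluded and
     M recomputed until two genes remain, which are reported tied at
     rank 1.
   - *Comparative ΔCt* (`deltaCtStability`): the same mean pairwise SD
     without iteration.
   - *BestKeeper* (`bestKeeper`): per-gene Cq SD and CV%, plus the
     Pearson correlation with the BestKeeper index (per-sample
     geometric mean of all candidates' Cq).
   - *NormFinder* (`normFinder`): on −Cq with the per-sample mean
     removed, stability = mean over condition groups of
     (|intergroup bias d<sub>g</sub>| + intragroup SD s<sub>g</sub>).
3. **Comprehensive ranking** (`comprehensiveRanking`) — RefFinder
   style: each gene's score is the geometric mean of its four
   per-method ranks, (Π<sub>m</sub> rank<sub>m</sub>)<sup>1/M</sup>;
   two such rankings from different platforms can be summed
   (`aggregateAcrossDatasets`).
4. **Validation by 2<sup>−ΔΔCt</sup>** (`deltaDeltaCt`) — targets with
   known expression patterns are quantified against the geometric mean
   of the chosen references (arithmetic mean on the Cq scale), relative
   to a calibrator condition, with SEM error bars and Tukey HSD
   compact-letter groups (`tukeyLetters`) from one-way ANOVA on the
   replicate ΔCt values.

A seeded generator (`simulateCq`, `simulateCounts`,
`hatchingScenario`, `screenScenario`) produces Cq tables and
negative-binomial count matrices with known ground truth — planted
stable references, stage-specific pulse genes, a drifting actin-like
pseudo-reference, per-sample loading offsets — so the whole pipeline
is testable end to end. Cq and count data live in
`SummarizedExperiment`-derived containers (`CqExperiment`,
`CountExperiment`) with plain-text TSV readers/writers.

## Worked example

```r
library(refstab)

sim <- simulateCq(hatchingScenario(), seed = 7)   # 14 genes x 24 samples
run <- runPipeline(sim$cq, targets = c("NEP-1", "cht-2", "eng"),
                   calibrator = "dry_cyst")
rankingTable(run@stages$comprehensive)
```

```
        gene deltaCt BestKeeper NormFinder geNorm geomean final_rank
1         GR       2          2          1      1   1.414          1
2       aaRS       1          4          3      1   1.861          2
3      CSQ-1       4          1          4      4   2.828          3
4      PMP-3       3          5          2      3   3.080          4
...
10     EIF-3      10         10         10     10  10.000         10
11     Act-1      11         11         11     11  11.000         11
```

The three planted stable references (`GR`, `aaRS`, `PMP-3`) land in the
top four; the drifting pseudo-reference `Act-1` is last. Validation of
the pulse target `NEP-1` (planted 10-fold induction at 8 h):

```r
es <- expressionSummary(run@stages$expression)
es[es$target == "NEP-1", ]
```

```
  target     condition n mean_fc sem_fc letters
1  NEP-1      dry_cyst 3   1.005 0.0704       b
4  NEP-1        PRD_8h 3   8.806 0.5406       a
...
```

`mean_fc` is the mean 2^−ΔΔCt fold change relative to dry cysts,
`sem_fc` its standard error over the three replicates, and conditions
sharing no letter differ significantly (Tukey HSD, α = 0.05): the 8 h
induction is recovered (8.8-fold, letter `a` alone).

`inst/extdata/` ships published per-method stability rank orders for an
11-gene potato cyst nematode candidate panel (*G. rostochiensis*
RNA-Seq and qRT-PCR, *G. pallida* qRT-PCR); feed them straight into the
aggregator:

```r
rt <- readRankTable(system.file("extdata",
        "grostochiensis_rnaseq_method_ranks.tsv", package = "refstab"))
recommendedGenes(comprehensiveRanking(rt))
#> [1] "GR"    "ArgRS" "PMP-3"
```

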