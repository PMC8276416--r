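---
title: "Methods: immuno-genomic classification of paired organoid/tissue cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immuno-genomic classification of paired organoid/tissue cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccotim)
```

## The analysis model

A patient-derived colorectal cancer organoid (CCO) is pure cancer
epithelium; its matched bulk tumor tissue is, to a first approximation, the
same epithelial signal mixed with an immune/stromal admixture — the tumor
immune microenvironment (TIM). `ccotim` treats the paired design as the
central modelling assumption:

* cancer-cell-*intrinsic* quantities (mutations, biallelic status, HLA-II
  expression, pathway activity, intrinsic subgroups, Ca-IIP) are measured on
  the **organoid** compartment;
* *microenvironmental* quantities (TIM class, immune-cell scores,
  exhaustion score) are measured on the **tissue** compartment;
* cross-compartment questions (is a binary organoid genotype enriched in
  tissues with low immune infiltration? does an organoid-defined group
  predict survival?) are answered with the sample-level KS enrichment
  statistic and standard survival models.

All expression inputs are assumed to be log2-scale, upper-quartile-type
normalized gene-by-sample matrices; signature means are taken on that scale
directly, without re-normalization.

## Fixed decision rules

These rules are deliberately simple and exactly reproduced, with strict
inequalities at every printed boundary:

| Rule | Default | Boundary behaviour |
|---|---|---|
| biallelic variant | VAF > 0.9 | VAF = 0.9 is *not* biallelic |
| TP53 GOF | 31-entry lookup | exact match after stripping `p.` and upper-casing |
| MSI | ≥ 2 / 1 / 0 unstable of 5 loci | MSI-H / MSI-L / MSS |
| CNV fraction | \|log2\| > 0.4 | ratio of altered to total *segmented* length |
| fusion FFPM | > 0.15 | ties fail |
| fusion support | split 0 → spanning ≥ 20; 1 → ≥ 10; ≥ 2 → ≥ 5 | see below |

Two readings of the fusion support rule are possible for exactly two split
reads, because the escalation is described as "one split read" then "more
than two split reads". We require spanning ≥ 5 at split ≥ 2: the
escalating-evidence pattern (more split reads, fewer spanning reads needed)
and monotonicity — more evidence must never turn a pass into a fail — both
point at "two or more". The exact-2 minimum is an argument
(`support_min["split2"]`) for users who prefer the literal reading.

The recurrence flag for fusions (`flag_recurrent_fusions()`, default
fraction 0.2) is a stand-in for manual curation of mis-mapping artifacts;
no quantitative rule exists for that curation, so flagged candidates are
marked for review, never auto-removed, and the pipeline manifest records
the stand-in status.

The CNV-fraction denominator is the total length of the segments supplied
(the covered exome); unsegmented genome is ignored. Coordinates are 0-based
half-open, so the metric is invariant to subdividing a segment — a property
the test suite checks.

## The sample-level KS enrichment statistic

With `N` samples ordered by increasing score (direction `enrich_low`; ties
broken by sample id so results are deterministic) and `G` members of a
binary annotation, the running sum gains `sqrt((N-G)/G)` at members and
loses `sqrt(G/(N-G))` at non-members; the statistic is the maximum prefix
sum. The full sum telescopes to zero, so the score is non-negative, and it
attains `sqrt(G(N-G))` exactly when members occupy the first `G` ranks.

*Numerical choice.* Internally the prefix maximum is computed on the
rescaled integer increments `+(N-G)` / `-G` and divided by `sqrt(G(N-G))`
at the end. This is algebraically identical but exact: non-negativity, the
telescoping zero, and every permutation comparison hold without float
roundoff, so a membership that can do no better than any permutation yields
p = 1 exactly.

The permutation p-value is the plain fraction
`p = B⁻¹ Σ_b 1(ES_obs ≤ ES_b)` over `B` label permutations preserving `G`
(default `B = 10000`). The observed score is *not* added to numerator or
denominator — the formula is implemented literally, which means `p = 0` is
possible; an `add_one` argument provides the `(r+1)/(B+1)` estimator for
users who want a strictly positive, conservative p, but it is off by
default. `exact_enumeration_pvalue()` enumerates all `choose(N, G)`
placements (bounded at 10⁶) and serves as the oracle in the test suite.

The direction default `enrich_low` reflects the motivating use: testing
whether mutation carriers concentrate among tumors with *low* cytotoxic
lymphocyte infiltration.

## Signature scoring

* `signature_mean()`: per-sample arithmetic mean of log2 expression over the
  signature genes present (absent genes are dropped with a warning).
* `select_top_hla2()`: the HLA class II signature is the `k = 5` candidate
  genes with highest cohort mean in the organoids, ties broken
  lexicographically; the fixed published selection (HLA-DRB1, -DQB1, -DRA,
  -DRB5, -DPA1) is available without recomputation.
* `quantile_stratify()`: rank-based bins, ties share the minimum rank and
  fall to the lower bin, so a constant vector is all bin 1 (degenerate
  inputs cannot scatter across bins).
* `zscore_pathway_score()`: a documented single-sample stand-in for
  gene-set variation scoring — per-gene cohort z-scores averaged over the
  set, zero-variance genes contributing 0. It is monotone in the same
  direction as GSVA-type scores, which is all the downstream pipeline
  requires; outputs carry a `provenance` tag (`zscore_mean`) so reports can
  distinguish it from plain mean expression.
* `marker_immune_scores()`: marker-mean scores per immune/stromal
  population (a deconvolution-free stand-in for CIBERSORT/MCPcounter-type
  profiling); the total immune score is the sum over populations.

The shipped gene lists deserve a caveat: only the HLA-II list is fixed from
published text. The functional categories, immune-cell markers, pathway
sets and TIM templates are editable placeholders (GMT files via
`read_gmt()`/`write_gmt()`); real-data analyses should substitute
domain-curated lists, in particular the immune and stroma templates, whose
published membership is not reproducible from text.

## Unsupervised classification

**k-means conventions** (used by `intrinsic_subgroups()` and
`caiip_classify()`): genes/signatures are z-scored across samples first, a
seed is required, and 50 restarts (`nstart = 50`) are run, making results
deterministic and scale-invariant. Cluster *ids* are arbitrary and
seed-dependent, so semantic labels are always attached by **score ranks**:

* intrinsic subgroups: the cluster with the highest mean E2F+MYC-target
  score is k1 (high proliferation); the cluster with the highest mean EMT
  score is k4 (mesenchymal); remaining clusters are the grey zone. If one
  cluster maximizes both anchors the labelling is not identifiable and the
  function errors rather than guessing.
* Ca-IIP: k-means with k = 3 on standardized HLA-II gene expression;
  clusters ranked by mean HLA-II signature are labelled k2 (highest), k1
  (middle), k3 (lowest); k1+k2 form the Higher HLA-II (Ca-IIP) group, k3
  the Lower group. The binary partition is invariant to cluster-id
  permutation and to joint monotone affine rescaling of the HLA-II genes.

**TIM classification** replaces the external Nearest Template Prediction
module with Spearman rank-correlation of each tissue profile against binary
class-template centroids over the union of the two templates' genes,
keeping the published composite decision tree exactly: immunogenic + normal
stroma = Active, immunogenic + activated stroma = Exhausted,
non-immunogenic = Desert. Because the two stage-1 centroids are
complementary over the gene union, a tie occurs exactly at zero
correlation; ties are broken toward non-immunogenic (stage 2: toward normal
stroma) with a logged warning, the conservative choice since the Desert
call triggers no further subdivision. The NTP FDR/resampling step is
omitted — the assignment, not its significance, feeds the downstream
pipeline.

## Survival

Kaplan-Meier, log-rank and Cox models are delegated to the `survival`
package. Tied event times use the discrete hypergeometric variance in the
log-rank statistic and **Efron** handling in Cox fits. Confidence intervals
are Wald intervals on the log-hazard scale at level 0.95. Rows with missing
covariates are dropped listwise; zero-variance covariates and
non-convergence raise errors instead of silently producing output. Both
overall and recurrence-free endpoints flow through the same functions via
the metadata columns `time_os`/`event_os`, `time_rfs`/`event_rfs`.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the latent structure the analysis
assumes, so that every downstream stage has a recoverable ground truth:

* three latent HLA-II groups with block means `(0, 4, 8)` log2 units and
  noise SD 0.5 — separations at which 3-group k-means recovery is expected
  to be nearly perfect, and which the recovery tests (≥ 95% agreement at
  n = 90) exercise;
* three TIM classes (Active 0.3, Exhausted 0.3, Desert 0.4) with **one
  shared admixture profile per class**; tissue = (1−a)·organoid +
  a·profile + noise, with the admixture fraction a drawn from
  `[0.3, 0.7]`. One profile per class is a deliberate simplification that
  makes template-based classification well-posed on synthetic data;
* four latent intrinsic subgroups shifting the proliferation and EMT gene
  blocks (a generator extension beyond the minimal spec of the cohort — it
  is needed so subgroup labelling has a ground truth);
* driver mutation rates APC 0.79, TP53 0.79, KRAS 0.55, FBXW7 0.24 (the
  published cohort frequencies), with log-odds couplings APC/KRAS→Desert
  and FBXW7→Exhausted of +1.5, and MSI-H samples placed in the Exhausted
  class with a hypermutator boost to passenger genes;
* VAFs from a two-component Beta mixture — subclonal `Beta(6, 14)` (mode
  ≈ 0.3) and biallelic `Beta(38, 2)` (mode ≈ 0.95), mixed at
  `biallelic_prob = 0.25` — reproducing a wide subclonal spread with a
  cleanly separable biallelic mode;
* exponential survival with independent uniform censoring; the low-HLA-II
  group's hazard is multiplied by `survival_hr_caiip = 3` (overall
  survival median 80 months at baseline; recurrence-free survival
  additionally penalizes the k1 subgroup). Exponential + uniform censoring
  is the simplest model sufficient for log-rank power checks.

Proportions of the latent groups, the admixture interval and the coupling
strengths are not published quantities; they were chosen once for
testability — clear separations, all classes well populated — and are not
tuned thereafter.

**What the generator does not emulate**, and hence what passing tests do
*not* show about real data: gene-gene correlation structure beyond block
means, compositional admixture at the read level, copy-number breakpoint
realism (segments are independent draws, MSI-H samples merely get quieter
profiles), germline variation, sequencing depth effects on VAF, and
realistic template gene sets. Recovery rates on synthetic data are upper
bounds on real-data performance.

## Determinism and problem sizes

Every stochastic step takes an explicit seed (`with_seed` scoping restores
the caller's RNG), k-means uses fixed seeds with 50 restarts, score ties
are broken by sample id, and output tables are written with full-precision
numerics — two runs of `run_pipeline()` with the same configuration produce
byte-identical files. The test suite exercises the enrichment statistic
exhaustively for N ≤ 8, calibrates the permutation null over 500 simulated
datasets of n = 60 (B = 2000), checks log-rank power over 100 generated
cohorts of n = 200 at hazard ratio 3, Cox recovery over 50 replicates of
n = 500 at hazard ratio 2, and label recovery on cohorts of n = 90 — sizes
chosen to give stable Monte-Carlo estimates while keeping a full run of the
suite in the minutes range.

## Known limitations

* The GOF table covers only the 31 listed TP53 protein changes; GOF status
  for unlisted variants is "no evidence", not "evidence of absence".
* MSI status for samples lacking panel PCR must be supplied precomputed;
  the sequence-based MSI algorithm lives in its own literature and is not
  reproduced here.
* The z-score pathway score is not GSVA; absolute score values are not
  comparable across cohorts, only ranks within a cohort.
* Template classification quality is bounded by template quality; the
  shipped templates are placeholders.
* The enrichment p-value without `add_one` can be exactly 0 at finite `B`;
  report `B` alongside `p` (the pipeline does).
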