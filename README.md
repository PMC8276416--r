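# ccotim

Immuno-genomic classification of colorectal cancer organoid (CCO) cohorts.

Patient-derived colorectal cancer organoids are pure cancer-epithelium
cultures: they carry the tumor's mutations, copy-number changes and
expression programs but none of its immune or stromal microenvironment.
Pairing each organoid with its bulk primary-tumor tissue therefore separates
two signals that are confounded in ordinary bulk RNA-seq — the
cancer-cell-intrinsic immuno-genomic state (read from the organoid) and the
tumor immune microenvironment, TIM (read from the tissue). `ccotim`
implements the analysis pipeline for such paired cohorts, for researchers
working with organoid biobanks or any cohort where a per-sample binary
genomic event needs to be tested for enrichment along a continuous immune
score.

## What it computes

**Variant and structural rules** (exact published thresholds):

* biallelic calling — a variant with allele fraction VAF > 0.9 in a pure
  organoid is biallelic (mutation of both alleles or copy-neutral LOH);
* a 31-entry TP53 gain-of-function (GOF) lookup; all other TP53 variants are
  NE-GOF;
* five-locus MSI panel (BAT-25, BAT-26, D5S346, D2S123, D17S250): ≥ 2
  unstable loci → MSI-H, 1 → MSI-L, 0 → MSS;
* CNV fraction — the share of segmented exome length with |log2 copy ratio|
  > 0.4;
* fusion filtering — FFPM > 0.15, then escalating read support (0 split
  reads need ≥ 20 spanning, 1 needs ≥ 10, ≥ 2 need ≥ 5), plus flagging of
  cohort-recurrent mis-mapping artifacts.

**Classification**:

* intrinsic molecular subgroups by k-means over pathway scores, labelled by
  score ranks: k1 = high proliferation (E2F/MYC), k4 = mesenchymal (EMT),
  k2/k3 grey zone;
* Ca-IIP — k-means (k = 3) on organoid HLA class II expression; the two
  higher-expression clusters form the "cancer cells with intrinsic
  immunogenic properties" group, the lowest cluster the Lower HLA-II group;
* TIM classes — two-stage nearest-template assignment of tissue profiles:
  immunogenic vs non-immunogenic, then normal vs activated stroma, composed
  into Active / Exhausted / Desert.

**The sample-level KS enrichment statistic.** For `N` samples ordered by a
continuous score (e.g. a cytotoxic-lymphocyte score) of which `G` carry a
binary annotation (e.g. KRAS biallelic alteration), the running sum gains
`sqrt((N-G)/G)` at each carrier and loses `sqrt(G/(N-G))` otherwise; the
enrichment score is the maximum prefix sum,

    ES = max_n [ Σ_{j≤n, j∈S} sqrt((N-G)/G) − Σ_{j≤n, j∉S} sqrt(G/(N-G)) ],

with ceiling `sqrt(G(N-G))` when carriers occupy the top `G` ranks. Its
p-value is the plain permutation fraction
`p = B⁻¹ Σ_b 1(ES_obs ≤ ES_b)` over `B = 10000` label permutations, with an
exact-enumeration oracle for small `N`.

**Survival**: Kaplan-Meier, log-rank, and multivariate Cox proportional
hazards (via the `survival` package), as used to show the Ca-IIP survival
benefit is independent of age, sex, stage, k1 subgroup and TIM status.

A synthetic paired-cohort generator (`cohort_spec()` / `generate_cohort()`)
emulates the latent structure the analysis assumes, so the entire pipeline
is exercised end-to-end without patient data.

## Worked example

```r
library(ccotim)

spec   <- cohort_spec(n_samples = 90, seed = 7)   # synthetic paired cohort
cfg    <- pipeline_config(spec = spec, enrichment_B = 10000)
res    <- run_pipeline(cfg)
print(res)
```

```
<pipeline_result> 90 samples
TIM classes: Active 33, Desert 31, Exhausted 26
Ca-IIP: 60 Higher / 30 Lower
                      test statistic     p_value
 enrichment_KRAS_biallelic 10.285913 0.081400000
       enrichment_TP53_GOF  3.500200 0.711200000
          logrank_caiip_os 10.119459 0.001467121
            logrank_k1_rfs  2.702186 0.100210765
```

The annotation table carries one row per sample (MSI status, CNV fraction,
intrinsic subgroup, HLA-II cluster and Ca-IIP group, HLA-II quantile, TIM
class, exhaustion and total-immune scores). The enrichment rows test whether
KRAS-biallelic / TP53-GOF carriers concentrate among tissues with low
cytotoxic-lymphocyte scores; the log-rank rows test the planted survival
structure — here the Lower HLA-II group's worse overall survival is
recovered (p = 0.0015), and the multivariate Cox fit attributes it to the
HLA-II grouping rather than the clinical covariates:

```r
res$survival$cox_os
#                  term        hr     lower    upper   p_value
# 1                 age 0.9943367 0.9675226 1.021894 0.6838695
# ...
# 6      lower_hla2TRUE 2.2450036 1.3035645 3.866354 0.0035479
```

Single operations are available directly, e.g.
`classify_biallelic(0.95)`, `classify_msi(...)`, `cnv_fraction(seg)`,
`enrichment_score(scores, membership)`,
`permutation_pvalue(scores, membership, B = 10000, seed = 1)`.

A thin command-line wrapper with `simulate`, `run` and `enrich` subcommands
is installed at `inst/cli/ccotim.R`.

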