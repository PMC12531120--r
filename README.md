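# fieldcanceR

Whole-organ analysis of mucosal field cancerization in R.

Bladder cancer (and other epithelial cancers) arises from *field
effects*: molecular alterations spread across mucosa that still looks
normal. When an entire organ is cut into a grid of mucosal fields and
every field is profiled — exome sequencing, RNA-seq, proteomics,
metabolomics — the evolution of the tumor becomes readable in space.
fieldcanceR is the analysis toolkit for such maps, aimed at cancer
genomicists working with multi-region / whole-organ designs.

## What it computes

Let `v_if` be the variant allele frequency (VAF) of mutation *i* in
field *f*, with presence defined as `v_if ≥ 0.01`.

* **Spatial mutation classes** — spread bins (private, regional 2–10 and
  11–20, widespread 21–30 and >30 fields) and the three-way α/β/γ split:
  α if present in < 3 fields; else β if median present VAF < 0.20; else
  γ. VAF-distribution shape diagnostics (right-skewed neutral `M(f) ∝
  1/f`; binomial/clonal; uniform).
* **Mutational signatures** — 96-trinucleotide-context spectra refit by
  non-negative least squares against a reference catalog
  (`C·w ≈ s, w ≥ 0, Σw = 1`), with case-resampling bootstrap
  significance per signature (p = fraction of replicates whose weight
  vanishes; p < 0.005 significant).
* **Organ phylogeny** — maximum-parsimony tree over fields from binary
  presence profiles (Hamming-distance NJ start, NNI hill-climbing on an
  exact two-state Sankoff kernel in C++), branch clustering, canonical
  heatmap leaf order.
* **Evolutionary timing** — a neutral-mutation clock on the tree (edge
  time ∝ α-mutation count, every root-to-leaf path rescaled to the
  T = 30-year history), sweep-aware dating of clonal-expansion edges
  into the progressive window, selection coefficients by
  exponential-growth inversion `ŝ = max(0, ln(m)/(r₀·â) − 1)`, and a
  two-rate Poisson change-point that splits carcinogenesis into dormant
  and progressive phases.
* **Monotonic multi-omics** — per-analyte stage effects vs controls
  (exact rank tests + BH), monotone-dysregulation calls with onset waves,
  stage scores (energy/OXPHOS, basal–luminal, EMT, immune, T-exhaustion),
  single-sample rank-weighted enrichment scores, and one-sided Fisher
  pathway enrichment.
* **A synthetic whole-organ generator** with known ground truth
  (histology grid, private neutral α mutations with `f(v) ∝ 1/v²` VAFs,
  contiguous β clones, one widespread γ clone, class-specific context
  spectra, monotone omics effects) that makes every stage testable
  without any external download.

## Worked example

```r
library(fieldcanceR)

org <- generateOrgan(seed = 1)     # synthetic whole organ, study scale
org$fieldMap
#> FieldMap with 40 fields ( NU=5, LGIN=5, HGIN=18, UC=12 )
org$mutations
#> MutationTable: 12809 mutations x 40 fields ( 12064 SNV, 451 INS, 294 DEL )

asg <- classifyMutations(org$mutations)
table(asg$greek_class, asg$spread_class)
#>         private regional_11_20 regional_2_10 widespread_21_30
#>   alpha   12431              0             0                0
#>   beta        0             36            18                0
#>   gamma       0              0             0              324

tl <- buildCloneTimeline(org$mutations, assignment = asg,
                         restarts = 3, seed = 1)
round(unlist(tl$partition[c("changepoint", "dormantRate",
                            "progressiveRate", "p")]), 3)
#>     changepoint     dormantRate progressiveRate               p
#>          25.015         414.152         491.271           0.005
round(tapply(tl$timeline$age, asg$greek_class, median), 2)
#> alpha  beta gamma
#> 15.00  4.64  2.14
round(tapply(tl$timeline$selection, asg$greek_class, mean), 2)
#> alpha  beta gamma
#>  0.77  2.20  8.65
```

Reading the output: the classifier recovers the planted structure —
12,431 private α mutations, 54 regionally spread β mutations and a
324-mutation widespread γ clone. The change-point model places the
dormant-to-progressive transition at year 25.0 of the 30-year history
(mutation accrual jumps from 414 to 491 events/year; Monte-Carlo
p = 0.005). Median ages fall from 15 years (α, spread across the whole
history) through 4.6 (β) to 2.1 years (γ), and mean selection
coefficients rise α → β → γ (0.8 → 2.2 → 8.7): the recent widespread
clone is the strongly selected one.

The full pipeline (classification, signatures, tree, timeline, omics,
plus TSV outputs and a checksummed JSON run manifest) is one call:

```r
res <- runOrganPipeline("out/", seed = 1)
```

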