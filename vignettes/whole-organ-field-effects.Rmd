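---
title: "Modeling whole-organ field cancerization with fieldcanceR"
author: "fieldcanceR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling whole-organ field cancerization with fieldcanceR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldcanceR)
```

# The problem

Bladder cancer develops from *field effects*: molecular alterations in
mucosa that still looks normal under the microscope. Whole-organ mapping
— cutting an entire cystectomy into a grid of mucosal fields and profiling
every field with exome sequencing, RNA-seq, proteomics and metabolomics —
makes it possible to watch carcinogenesis unfold in space. fieldcanceR
implements the analysis layer for such maps:

1. **Spatial mutation classes.** Mutations are binned by spread (private /
   regional / widespread) and split into three classes by spread and
   variant allele frequency (VAF): **α** (private, low VAF — neutral
   passengers in single uroprogenitor territories), **β** (regionally
   spread, persistently low VAF — early expanding clones), and **γ**
   (widespread, high VAF — the selected clone that drives invasion).
2. **Clonality diagnostics.** The VAF distribution of a mutation set is
   labeled right-skewed (the neutral expectation), binomial/clonal
   (a selected subclone), uniform, or indeterminate.
3. **Mutational signatures.** 96-trinucleotide-context spectra are refit
   against a reference catalog by non-negative least squares, with
   bootstrap significance per signature.
4. **Organ phylogeny.** A maximum-parsimony tree over the mucosal fields
   is built from binary mutation presence profiles, then cut into major
   branches.
5. **Evolutionary timing.** A clock calibrated on the neutral (α)
   mutations assigns every mutation an age; exponential-growth inversion
   turns VAF mass into a selection coefficient; a two-rate Poisson
   change-point splits the history into a *dormant* and a *progressive*
   phase.
6. **Monotonic multi-omics.** Analytes (genes, proteins, metabolites)
   whose dysregulation keeps its sign and grows along the NU/LGIN → HGIN
   → UC histologic sequence are called monotone, assigned onset waves,
   and summarized with stage scores and enrichment statistics.

Because a whole-organ map is a single-patient design, every stage is
validated against a synthetic whole-organ generator with known ground
truth rather than against held-out samples.

# The synthetic organ

`generateOrgan()` emulates the structure of a mapped cystectomy. Its
defaults are the study conditions of a whole-organ bladder map:

* **Histology grid** (`plantHistology`): a 5 × 8 grid (40 fields, the
  mapped organs of this design have ~37–42 samples per platform) with a
  3 × 4 carcinoma (UC) block, an HGIN ring of width 1 (18 fields), one
  LGIN rim and NU elsewhere. A rectangular grid cannot hold exactly 37
  fields; 40 is the closest realizable layout.
* **α mutations**: 12,431 (11,698 SNV / 448 INS / 285 DEL), each private
  to one field, VAF drawn from the neutral density f(v) ∝ 1/v² on
  [0.01, 0.25] — the standard neutral-growth expectation, whose
  cumulative count M(f) is linear in 1/f. The lower cutoff 0.01 is the
  detection floor used throughout.
* **β clones**: 3 contiguous clones (grown by 4-neighborhood
  breadth-first expansion — mucosal clones spread to adjacent fields)
  spanning 3–20 fields, carrying 54 mutations with per-field VAF ~
  U(0.02, 0.18).
* **γ clone**: one clone carrying 324 mutations covering every HGIN/UC
  field (≥ 21 fields) at VAF ~ Normal(0.35, 0.05²) truncated to
  [0.2, 0.5].
* **Ages** (years before observation): α ~ U(0, 30); β ~ U(2, 5); γ ~
  U(0, 2) — a 30-year history whose last 5 years form the progressive
  window, with the γ clone arising in the final 2 years.
* **True selection**: for clonal mutations the generator closes the loop
  with the timing model's growth law, s = ln(m)/(r₀·a) − 1, where m is
  the realized mutant cell mass (2·VAF·10⁶ cells per field, summed);
  α mutations are neutral (s = 0).
* **Contexts**: SNV contexts are drawn from per-class mixtures over the
  synthetic five-signature catalog (`defaultSignatureCatalog()`); β and
  γ are enriched for the clock-like CpG C>T signature S1, matching the
  prominence of that process in urothelial carcinogenesis.
* **Omics layers**: RNA (2,000 analytes), protein (2,000, 10% missing,
  500 analytes shared with RNA) and metabolite (91) matrices over the 40
  fields plus 3 control samples at baseline. 30% of analytes are planted
  monotone with log2 effects ±(1, 2, 3) over NU/LGIN → HGIN → UC and
  noise σ = 0.5 log2 units. The high monotone fraction mirrors the
  pervasive transcriptome dysregulation of such maps and, with only 3
  controls and exact rank tests, is what makes small-group significance
  achievable under Benjamini–Hochberg ranking. Named marker genes
  (basal keratins up, uroplakins/luminal factors down, OXPHOS and citric
  acid cycle down, glycolysis up, immune/T-exhaustion up) are planted
  first so the score functions can be validated end to end.

The RNA/protein layers default to 2,000 analytes — a deliberately reduced
problem size that keeps simulation studies quick; the statistical
structure (group sizes, effect sizes, noise, monotone fraction) is
unchanged by this choice. The study-scale bookkeeping tables (12,431 α /
54 β / 324 γ mutations over 12,764 loci — 45 loci carry two variant
records —, 8,475 proteins, 91 metabolites) are produced by
`syntheticSupplementaryTables()`, whose outputs are labelled
`synthetic_*` because they are generated stand-ins, not measurements.

What the generator deliberately does **not** emulate: sequencing-depth
sampling noise on VAFs, copy-number distortion of VAFs, cell-resolution
spatial structure within a field, batch effects in the omics layers, and
mutation-rate heterogeneity along the genome. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
model, not robustness to every artifact of real data.

# Classification rules

Presence means VAF ≥ 0.01 (parameter `threshold`). Spread bins follow
the field-count definition (1 / 2–10 / 11–20 / 21–30 / >30). The greek
split is deterministic: α if present in fewer than `minClusterFields`
(3) fields; otherwise β when the **median** present VAF is below
`clonalVaf` (0.20), else γ. The median (not the mean) is used for
robustness to a clone's low-purity edge fields. These thresholds
translate the heatmap-clustering operational definition of the classes
into a reproducible rule; on the generator's study conditions the rule
recovers the planted classes for 100% of mutations over 20 seeds.

`vafShape()` fires its rules in order: right-skewed when the cumulative
count is linear in 1/f (R² ≥ 0.9) **and** sample skewness exceeds 0.5 —
a zero-skew gate would label symmetric samples right-skewed half the
time by sampling noise alone; binomial/clonal when a single density mode
lies in [0.15, 0.5] and the dispersion is within twice the binomial
standard error at 300× depth; uniform by a Kolmogorov–Smirnov test;
otherwise indeterminate, as is any sample of fewer than 8 values.

# Signatures

`fitSignatureWeights()` solves min‖C·w − s‖ with w ≥ 0 (non-negative
least squares) for a normalized spectrum s against the catalog C, then
renormalizes w to sum 1; the fit is scale-invariant. Refitting against a
fixed catalog (not de novo extraction) matches how known signatures are
quantified in single-case studies. `bootstrapSignatures()` defines the
per-signature p as the fraction of B ≥ 100 case-resampled replicates in
which the signature's weight effectively vanishes (≤ `wMin` = 0.01);
p < 0.005 is called significant. The shipped catalog is a synthetic
stand-in with five well-separated signatures (CpG C>T; non-CpG C>T;
T>C; C>A; T>A/T>G; each with a 2% flat floor); any 96-context catalog
with unit column sums can be supplied instead.

# Phylogeny

The character matrix is binary presence over all silent and nonsilent
mutations. `searchTree()` starts from the neighbor-joining tree on
Hamming distances and hill-climbs with nearest-neighbor interchanges on
the parsimony score (an exact two-state Sankoff kernel in C++), with
random restarts and bounded sideways moves to escape score plateaus;
only parsimony-informative characters are rescored during the search.
On 100 random matrices with up to 8 leaves the search equals the
exhaustive optimum over all (2n−5)!! topologies in ≥ 95 cases. At organ
scale (40 leaves) the pipeline uses pure descent (`plateau = 0`): the
clades are strongly determined there and plateau walking only costs
time. `branchClusters()` greedily removes k−1 edges maximizing the
minimum inter-cluster Hamming separation, reproducing the three-branch
(δ/ε/ζ-style) partition; `treeOrder()` gives the deterministic,
orientation-invariant leaf order used for distance heatmaps.

# Timing model

The timing module is a deliberately parsimonious surrogate for a full
time-continuous branching process with immigration, built so that its
acceptance surface is parameter recovery on data generated from the
matching forward model.

* **Rooting**: the tree is rooted next to the field with the fewest
  mutations — the cheapest attachment point for a hypothetical
  mutation-free ancestor ("node 0").
* **Edge assignment**: each mutation sits on the edge above the smallest
  clade containing its presence set; non-clade presence sets are flagged
  homoplastic but still placed (excluding them is a switch).
* **Neutral clock**: raw edge lengths are α-mutation counts plus a 0.5
  pseudocount; node times are rescaled so every root-to-leaf path spans
  the calibration input T = 30 years (T is an input, not an estimate).
* **Private mutations** are dated over the full (0, T) span of their
  field's lineage — a private lineage exists from organ origin to
  observation, so restricting it to the terminal edge segment would
  carve an artificial event-free window near the origin. Within a span,
  mutations are placed at uniform quantiles ordered by VAF (higher
  frequency dates older, the neutral-growth ordering); the midpoint
  placement of classic edge-dating is available as an option and is the
  mean of the quantile rule.
* **Sweep-aware clone dating** (default on): internal edges carrying at
  least `cloneMinMut` = 5 shared mutations are clonal expansions. A
  sweeping clone's topological position is *above* the fields it covers,
  yet its expansion postdates their divergence — a clock that reads
  internal-edge positions as times would date every widespread sweep to
  the organ's origin. Clone edges are therefore re-dated into the
  progressive window W (a calibration input like T, default 5 years),
  ordered by median present VAF (successive clones show increasing
  VAFs), with the window partitioned in proportion to clone mutation
  counts. Under the generator's forward model this recovers γ ages with
  a mean absolute error of ~1.5 years and places the change-point within
  0.05 years of the planted transition; these are recovery results under
  the matching forward model, not guarantees for arbitrary clonal
  architectures.
* **Selection**: ŝ = max(0, ln(m)/(r₀·â) − 1) inverts exponential
  growth at baseline rate r₀ = 1/year; m = Σ 2·VAF·10⁶ cells. Ages are
  clamped at `ageFloor` = 1 year inside the inversion only — the
  inversion diverges as â → 0, and without the floor a handful of very
  young neutral mutations dominate the class means.
* **Change-point**: mutation origination times are modeled as a Poisson
  process with one rate change; the cut maximizes the two-rate
  log-likelihood over candidate cuts at observed times, constrained to
  leave at least 5% of events on each side (boundary cuts are scan
  artifacts). Significance is Monte-Carlo calibrated against simulated
  constant-rate histories: the scan statistic maximized over cuts is
  stochastically much larger than a χ²₁ draw, so a fixed χ² cut would be
  strongly anti-conservative; with the calibrated threshold the null
  false-positive rate is at the nominal 5%.

Identifiability is limited and stated plainly: per-mutation α ages are
not identifiable from a single time point (the generator draws VAF and
age independently), so only the ensemble distribution of α ages is
recovered; clone ages are identifiable only through the model's
window-and-ordering assumptions.

# Monotonic omics

Stage effects are group means minus the control mean (missing values
excluded pairwise) with two-sided exact Wilcoxon rank-sum tests against
the controls and BH adjustment within each group across analytes.
"Monotone" has no standard numeric definition; this package's rule is:
ordered effects e(NU/LGIN) ≤ e(HGIN) + τ ≤ e(UC) + 2τ (mirrored for
down), a non-zero UC effect, and q(UC) < 0.05, with τ = 0 by default.
Wave 1 = already significant in NU/LGIN; wave 2 = first significant in
HGIN. Analytes quantified in too few samples simply return NA effects
and are never called.

`signatureScore()` is a mean-z difference against the control
distribution (up-set minus down-set). Sign conventions: the energy score
is oxidative (OXPHOS + citric acid cycle vs glycolysis), so it falls
with progression; the basal-luminal (BLT) score is luminal minus basal,
so negative means basal-shifted; the EMT score is epithelial minus
mesenchymal, so negative means EMT-activated.

`ssgseaEs()` ranks analytes by expression and compares rank^α-weighted
(α = 0.75) in-set and out-set cumulative distributions. The reported
score is the signed **area** between the two curves (bounded in
[−1, 1]); the maximum-deviation convention is available as an option but
its null is biased for weighted curves (the weighted extreme is not
symmetric around zero), whereas the area statistic is centered within
Monte-Carlo error for random sets. The statistic is rank-based and hence
invariant under any strictly monotone transform of the expression
vector. Pathway enrichment is the one-sided Fisher (hypergeometric
upper-tail) test with BH adjustment across sets.

# Numerical and reproducibility choices

* Every stochastic entry point takes an integer seed and restores the
  caller's RNG state; rerunning the pipeline with the same config and
  seed reproduces byte-identical outputs (md5 checksums in the run
  manifest).
* All tables are UTF-8 TSVs with 6-significant-digit numeric formatting
  (10 digits for signature catalogs, whose unit column sums must survive
  the round trip); a write-read-write cycle is byte-stable.
* VAF tables with values above 1 are auto-detected as percent scale and
  divided by 100; the choice is recorded on the object and in the run
  manifest.
* Exact 2×3 Fisher tests switch to seeded Monte Carlo above a table
  total of 500.
* Degenerate inputs resolve conservatively: all-tied rank tests give
  p = 1; VAF collections below 8 values are shape-indeterminate;
  all-zero NNLS fits fall back to uniform weights.

# Problem sizes

The shipped validation uses: the full study-scale mutation landscape
(12,809 mutations × 40 fields) for classification and timing recovery
over 20 seeds; 100 random ≤ 8-leaf matrices against exhaustive topology
enumeration; n = 2,000 context draws × 100 replicates for mixture
recovery and B = 1,000 bootstrap replicates; 1,000-analyte omics layers
for the monotonic caller. These sizes make the full validation run in a
few minutes on one CPU while keeping every statistical check at the
study's own scale where it matters (the mutation landscape).

# Known limitations

* The greek split is a thresholded surrogate for a clustering-based
  operational definition; fidelity is established against the planted
  truth and class totals, not against any particular clustering.
* The timing surrogate inherits the identifiability limits above; its
  selection coefficients are unitless and comparable only within a run.
* The branch clustering optimizes single-linkage separation; other
  linkage choices can give different three-way partitions on flat trees.
* The synthetic signature catalog is a stand-in; real analyses should
  supply an external reference catalog.
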