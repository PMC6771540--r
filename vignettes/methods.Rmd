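---
title: "Methods: comparative drought-response analysis with aridr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative drought-response analysis with aridr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aridr)
library(dplyr)
```

`aridr` implements a comparative analysis of drought responses across
closely related plant species — the reference design is three Brassicaceae
(*Arabidopsis thaliana* "Ath", *A. lyrata* "Aly", *Eutrema salsugineum*
"Esa") profiled by RNA-seq under well-watered (WW) and water-deficit (WD)
conditions at four timepoints (T0, T5, T11, T14 days after watering stop)
with three biological replicates, alongside daily rosette phenotyping.
This vignette explains the models and procedures, the parameters that
matter, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the design was genuinely open.

## Expression handling

Transcript-level TPM tables are the entry point; gene abundance is the sum
of its transcripts' TPM per sample (TPM is linear within a sample, so
column totals are conserved). The working scale is `log2(TPM + 1)`. The
pseudocount of 1 is a deliberate choice: it makes the conventional
expression cutoff "log2TPM ≥ 1" equivalent to "TPM ≥ 1", so the filter
threshold and the log scale tell the same story. `expression_filter()`
keeps a gene if *any single sample* reaches the threshold — the most
permissive replicate rule — and the comparison is inclusive, so a gene
sitting exactly at the threshold is retained. Filtering is applied per
species *before* orthology, because expressed-gene sets are a per-species
property; the EMO construction then consumes them.

Duplicated feature identifiers are an error rather than being silently
summed: a duplicated row almost always signals an upstream join mistake,
and summing would mask it.

## Orthology: reciprocal best hits and EMO triples

One-to-one orthologs are called by reciprocal best hit (RBH) over pairwise
protein similarity searches (standard 12-column tabular input, E-value
cutoff 1e-3, inclusive). "Best" is defined by a deterministic tie-break
chain — maximum bitscore, then minimum E-value, then maximum percent
identity, then lexicographically smallest subject — so results are fully
reproducible regardless of input order. RBH is the simplest defensible
one-to-one rule; synteny-aware or tree-based orthology is out of scope.

Expressed mutual ortholog (EMO) triples require all three pairwise RBH
edges to close a consistent triangle (the default `closure = "strict"`),
which guarantees one-to-one-to-one triples; triangles whose third edge
points elsewhere are dropped and counted. A `"two_edge"` relaxation keeps
triples whose third edge is merely absent. Every member must pass its
species' expression filter.

## Fold changes, regulation calls and response timing

The per-gene drought response at each timepoint is
`log2((mean TPM_WD + 1) / (mean TPM_WW + 1))` over replicate means. The
pseudocount guards the 0/0 case and damps ratios of barely expressed
genes; means (not medians) match the three-replicate design. Regulation
calls are threshold-based and inclusive: `log2FC ≥ 1` is "up",
`≤ −1` is "down". No dispersion-based test is attempted — with three
replicates and a cross-species design, the threshold rule is the
transparent choice, and statistical DE testing is an explicit non-goal.

"Drought-specific" genes are those switched on only by the treatment:
expressed (log2TPM ≥ 1) in at least one post-onset WD sample, but below
threshold in *every* WW sample and every T0 sample, operationalising
"not already expressed before stress onset".

Per-EMO response timing is summarised per species by whether the gene is
induced (any post-onset `log2FC ≥ 1`), its first peak (earliest induced
timepoint) and its highest peak (argmax of fold change over induced
timepoints, earliest on ties). The cross-species *segment* label combines
which species are induced with first-peak agreement:
`"common-synchronous"`, `"common-shifted"`, pair codes
(`"Ath+Aly-shifted"`), species-specific codes (`"Esa-specific"`) or
`"none"`. This canonical taxonomy is deliberately coarse — membership
rules of finer published segmentations are not reconstructible — and is
invariant to adding sub-threshold timepoints.

## Permutation test for multi-species overlap

The significance of the number of EMOs regulated in *all* species is
assessed against a resampling null: each species' regulated set is redrawn
uniformly without replacement from the common-ortholog background
(independently per species — the minimal null given only set sizes), the
full intersection is counted, and the p-value is the fraction of
`n = 1000` permutations with a null overlap **greater than or equal to**
the observed one. When no permutation reaches it the result is reported as
"p < 1/n" rather than zero. The generator is seeded and the seed is stored
in the result. The test generalises to any number of species and can be
run per timepoint/direction stratum; both joint and separate stratum
testing are available simply by choosing the input sets.

Calibration: when the observed statistic is itself drawn from the null,
the p-values are uniform up to the discreteness of the overlap statistic;
the test suite checks coverage at several levels with a tolerance that
adds the largest null point mass to the binomial noise.

## Co-expression modules

The network chain is implemented from first principles and follows the
weighted co-expression playbook:

1. **Correlation.** Pearson correlation between all gene pairs across all
   samples of all species jointly (the EMO matrix concatenates the three
   species' samples). Zero-variance genes get correlation 0 with a
   warning.
2. **Soft thresholding.** `a = |r|^β` with β = 16 (unsigned network).
   Unsigned is the historical default of the method; a signed variant
   (`((1+r)/2)^β`) is available by flag. β is fixed, not fitted:
   scale-free-fit selection is a non-goal.
3. **Topological overlap.**
   `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
   `TOM_ii = 1`; clustering uses the dissimilarity `1 − TOM`.
4. **Average-linkage clustering** of the TOM dissimilarity.
5. **Tree cut.** The dendrogram is cut at `0.99 × max merge height` and
   branches with ≥ 30 genes become modules; smaller branches are pooled
   as `"unassigned"`. This fractional-height rule was chosen after
   examining the merge-height structure of TOM dendrograms: dissimilarity
   between unrelated genes crowds into a plateau just below the maximum,
   so a quantile over merge heights lands *inside* the plateau and fails
   to separate anything, whereas a cut just under the plateau isolates
   exactly the tight branches. The minimum size of 30 is a convention of
   the field, not a fitted value.
6. **Eigengenes and merging.** Each module's eigengene is the first
   principal component of its gene-standardised expression, unit-norm,
   sign-oriented to correlate positively with the module's mean
   standardised profile (first-gene rule when that mean is exactly flat).
   Modules whose eigengene dissimilarity `1 − r` falls below 0.1
   (correlation > 0.9) are merged closest-first, recomputing eigengenes
   after each merge until no pair qualifies; the procedure is
   deterministic and idempotent.

Module–trait association is a Pearson correlation of each eigengene with
numeric traits (one-hot species, WD indicator, timepoint rank), a
two-sided p from the t distribution on n − 2 df, and Benjamini–Hochberg
adjustment across the whole module × trait family. Two significance
conventions circulate for such heatmaps (FDR < 0.05 and < 0.1); the
threshold is an argument (`fdr_level`, default 0.05) and never hard-coded.

## Enrichment

Classic one-sided term enrichment: hypergeometric upper tail
`P(X ≥ k)` per term (identical to the one-sided Fisher exact test), BH
adjustment across tested terms. Terms with no annotated universe gene are
skipped, not padded with p = 1, to keep the adjustment family honest.
Decorrelation schemes that walk the ontology graph (elim/weight style) are
deliberately out of scope; a true-path closure (`propagate_annotations()`)
is provided so parent terms inherit member genes. The universe is the
caller's choice — all expressed genes of a species, or the EMO set for
EMO-restricted analyses.

Note that BH is *not* idempotent in general (re-applying the step-up rule
re-multiplies by m/rank); the package asserts the true properties —
`q ≥ p`, monotonicity, boundedness — instead.

## Phenotyping metrics

All formulas operate on tabular measurements (image segmentation is
upstream):

* RGR `= (ln A_t − ln A_{t−Δt}) / Δt` per consecutive day pair;
* stockiness `= 4π·area / perimeter²` (1 for a circle);
* compactness `= area / convex hull area` (1 for a convex rosette);
* stomatal index `= guard cells / epidermal cells`, exactly as printed in
  the source protocol — the more common convention
  `stomata / (stomata + epidermal)` is available behind
  `conventional = TRUE`;
* cells per leaf `= leaf area × cell density`; aperture ratio
  `= ostiole width / length`; anthocyanin index
  `= (A530 − A657) / g fresh weight` (negative values are reported with a
  warning, not suppressed).

Survival is a per-replicate percentage summarised as mean ± SD across
replicates. The first day of significant growth reduction uses a
**one-sided Welch** t-test per day (WD < WW, α = 0.05): one-sided because
the hypothesis is directional, Welch because equal variances cannot be
assumed between stressed and unstressed groups. Under the null this
per-day test fires at the nominal rate, so the earliest-significant-day
rule carries the usual α-level risk of firing before a true divergence;
the tests therefore assess onset recovery across repeated simulated
studies rather than on a single draw.

## The synthetic-data generators

The generators are first-class, tested code and define the study
conditions:

* **Design.** 3 species × 2 conditions × 4 timepoints × 3 replicates of
  transcript-level TPM; baseline gene abundances log-normal (meanlog 1.5,
  sdlog 1.2 — a realistic TPM spread), shared across species for the
  ortholog fraction (default 80% one-to-one).
* **Modules.** Planted on ortholog genes so signals are shared across
  species: each member gene's log2 profile adds
  `s·(√ρ·z + √(1−ρ)·e)` with a per-module latent `z` over the joint
  samples, signal scale `s = 2` log2 units and latent share ρ (the
  configured within-module correlation, default 0.8). Trait association
  is produced by mixing a scaled trait vector into `z`. Replicate noise
  (log-normal, σ = 0.2 log2 units by default) slightly attenuates the
  realised correlation; values clipped at the zero-TPM floor can distort
  it further for weakly expressed genes, which is why the
  perfect-correlation property is exercised at high baselines.
* **Responders.** Planted per species with a first and a highest peak
  among the post-onset timepoints; the effect (default 1.5–4 log2 units)
  is applied on the `log2(TPM+1)` scale in the WD arm from the first peak
  onward (90% of the effect at non-peak induced timepoints). Planting on
  the pseudocounted scale makes the measured replicate-mean fold change
  equal the planted value *exactly* when noise is zero — a deliberate
  construction so exactness is testable to 1e-9.
* **Orthology searches.** True pairs receive mutual top hits with
  bitscores in 500–1500 and E-values decreasing consistently with
  bitscore; paralog decoys (probability 0.2 per direction) score strictly
  lower (40–80% of the true bitscore); a missing rate drops pairs from a
  search entirely. Realism is limited to the columns the parser reads.
* **Growth.** Logistic area trajectories with per-plant parameter jitter
  and multiplicative process noise; each plant's biology is drawn once
  and shared by the WW and WD arms (counterfactual twins), so a
  noise-free, divergence-free run yields identical arms. WD growth is
  scaled by 0.25 from the species' divergence day (defaults Aly day 3,
  Ath day 5, Esa day 6). Starting areas default to 211/100/94 mm² for
  Aly/Ath/Esa and WD survival probabilities to 0.96/0.76/0.98,
  reflecting typical values for developmentally matched plants of these
  species. Perimeter and hull area derive from area via per-plant shape
  factors, keeping stockiness and compactness in (0, 1].
* **Timing profiles.** A separate generator plants segment classes
  directly at the fold-change level (class first, then a profile that
  realises it, then Gaussian noise), which is the right granularity for
  testing the classifier.

What the generators do **not** emulate: count-level sampling noise
(negative binomial mean–variance coupling) — the pipeline consumes TPM,
so noise is log-normal by design; library-size or batch artefacts;
paralog families with genuinely ambiguous orthology; dropout or
zero-inflation; non-logistic growth phases. Passing tests therefore
demonstrate correctness of the algorithms under a clean generative model,
not robustness to every artefact of real sequencing data.

## The pipeline runner

`run_pipeline()` executes the stages in dependency order from a single
validated config (`pipeline_config()` / `validate_config()`, which lists
*all* violations at once), writes every intermediate as TSV plus a JSON
report when an output directory is given, and is bit-reproducible under a
fixed seed (the report carries the seed and a hash of the analysis
settings; the output location is excluded from the hash). Stage toggles
mark skipped sections explicitly; stages whose dependencies are off are
skipped too. The default synthetic scenario uses 600 genes per species —
small enough to iterate on freely, large enough that every stage produces
non-trivial output; all structural properties being exercised (recovery,
calibration, determinism) are size-independent.

## Known limitations

* The one-to-one orthology rule is RBH; gene families with recent
  duplications will lose members by construction.
* The tree cut is a single static fractional-height rule, not an adaptive
  branch-shape analysis; very nested module structures may be split or
  pooled differently than by adaptive cutters.
* The segment taxonomy intentionally collapses peak *magnitude*
  information; two species induced at the same timepoint with very
  different amplitudes are still "synchronous".
* The enrichment test treats terms independently; parent–child
  correlation inflates related terms unless the study design accounts
  for it.
* With three replicates the threshold-based regulation calls have no
  error control; they are descriptive, as intended.

```{r example, eval = FALSE}
# a complete run on the default synthetic scenario
report <- run_pipeline(pipeline_config(seed = 1, out_dir = "run1"))
report
```
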