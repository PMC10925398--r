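---
title: "Methods: heparin-enriched plasma proteomics with brain network projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heparin-enriched plasma proteomics with brain network projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Heparin-binding proteins (HBPs) — extracellular-matrix proteins such as
SMOC1, SPON1, MDK and APOE that co-accumulate with amyloid-beta in the
Alzheimer's disease (AD) brain — are hard to measure in plasma by mass
spectrometry because albumin and a handful of other proteins dominate the
signal. Heparin-affinity enrichment followed by multi-batch tandem-mass-tag
(TMT) quantification makes them measurable, at the price of a technical
pipeline with many statistical steps: channel-loading normalization,
batch correction anchored on pooled internal standards, two-group
differential abundance, meta-analysis across independent sample sets,
correlation against fluid biomarkers, and projection onto a reference
brain co-expression network.

`hepnet` implements that pipeline as composable, individually tested
functions, together with synthetic-data generators that reproduce the
statistical structure the pipeline assumes. Because every generator plants
a known truth (effect sizes, batch offsets, module membership, latent
disease severity), every downstream stage has a parameter-recovery test.

# Data model

* **Abundance matrix** — proteins x samples, rownames
  `"UniProtID|GeneSymbol"`, `NA` the only missing marker (a stored zero in
  label-free exports means "not detected" and is converted to `NA` on
  request, never treated as an intensity). A `scale` attribute tracks
  `raw`, `normalized`, `log2` or `z`; raw/normalized values must be
  positive, log2/z values finite.
* **Sample sheet** — per-sample set, batch, channel, GIS flag, diagnosis
  (`Control` / `AD` / `AsymAD`, with the sentinel `GIS` for pooled
  standard channels), and covariates (age, sex, ...).
* **Trait table** — MoCA cognition score (0-30 points), CSF amyloid-beta
  1-42, CSF total tau, CSF pTau181, their tTau/Abeta ratio, and plasma
  pTau181 (immunoassay concentrations, pg/mL-scale).
* **Network reference** — a module membership map plus a module x sample
  eigenprotein matrix (rows standardized). Matrix joins use the UniProt
  part of the protein id; network, marker and gene-set matching use the
  upper-cased gene symbol, because reference networks and marker lists are
  published as symbols.

# Normalization and batch correction

**Channel-sum normalization** divides each observed intensity by its
sample's total and rescales by the maximum total, so complete columns end
with equal sums — the TMT convention for equalizing channel loading.

**Missingness filter**: proteins missing in more than 50% of samples are
removed (a protein missing in exactly half is kept; the rule is
"strictly greater than"). No imputation is performed in the TMT branch;
the downshifted Gaussian imputation (`impute_downshifted`, mean shifted
down 1.8 column SDs, width 0.3 SDs) exists for the label-free fraction
workflow only, where left-censored missingness is expected.

**Median-polish batch correction** (`tampor`) anchors every batch on its
denominator samples — by default the pooled global internal standard (GIS)
channels, the "tunable" choice being GIS vs all batch samples. Log2 ratios
to the per-(protein, batch) denominator median are polished by alternating
row- and column-median sweeps until the largest absolute adjustment falls
below `tol` (default 1e-8, capped at 250 iterations; non-convergence is a
warning, not an error). The polished residual is returned on the original
abundance scale by adding back each protein's log2 median. Two numerical
properties follow from this construction and are asserted in the tests:
noiseless GIS columns are *exactly* identical after correction (their
ratio rows start identical and every sweep preserves that), and the
procedure is idempotent on complete data to roughly the convergence
tolerance. With per-batch missing patterns the GIS anchor differs on
re-application, so exact idempotence holds only for complete matrices.
Medians over an even number of values are the mean of the two central
values throughout.

**Bootstrap covariate regression** removes nuisance covariates (batch,
age, sex, PMI) while protecting the diagnosis term: per protein, OLS
coefficients are averaged over bootstrap resamples of samples and only the
covariate terms' centered contributions are subtracted. Design choices
that the data sources leave open, fixed here: 100 resamples, resampling at
the sample level *stratified by batch* (so no resample loses a batch and
the design stays full rank; rank-deficient draws are redrawn up to 10
times, then skipped), and diagnosis protected. Proteins with fewer
complete cases than design columns are left uncorrected with a warning.
All downstream statistics operate in log2 space; a log2 fold-change is a
difference of group means there.

# Differential abundance and meta-analysis

The two-group test is the classical pooled-variance Student t (the Welch
form is available behind a flag), vectorized over proteins; proteins with
fewer than 2 observed values in either group are excluded from testing
and from the Benjamini-Hochberg family. BH adjustment is the standard
step-up with capping; `NA` p-values pass through without inflating the
family size. Threshold rules use strict inequalities (`p < 0.05`,
fold `> 2`), with fold thresholds interpreted on the linear scale
(fold 2 means |log2FC| > 1).

Two independent sample sets are combined by Fisher's method:
`X = -2 * sum(log p_i)` referred to chi-square with `2k` df. A protein
measured in only one set keeps that set's p-value and fold change
(`n_sets = 1`) rather than being dropped — important for proteins like
SMOC1 detectable in a single set. Exact zeros are rejected rather than
clamped, keeping the combination honest.

Before the meta-analysis, samples are filtered on biomarker and cognition
cutoffs: AD cases need a CSF tTau/Abeta ratio above 0.226 *and* MoCA
below 24; controls need ratio at or below 0.226 *and* MoCA above 26. The
source description reads as "or" over failure reasons; retention here uses
the conjunctive form (both criteria must support the label), with both
thresholds exposed in the configuration. Overlapping samples can be
exempted explicitly.

Protein-trait association Z-transforms each protein over all retained
samples of both sets pooled (mean 0, SD 1, n-1 denominator, missing
preserved) and computes pairwise-complete Pearson correlations with
Student p-values (df = n-2) against the six traits. The protein x trait
grid is reported unadjusted by default — the trait panel is small and
fixed, and the headline multi-trait selection ("significant in at least 3
of 6 traits at alpha 0.05") already demands joint support; a BH option is
available through `bh_adjust` on any column.

# Network projection

The biweight midcorrelation (`bicor`) uses Tukey biweights with the tuning
constant at 9 raw median absolute deviations; observations at or beyond 9
MADs get zero weight. A vector with zero MAD (majority ties) falls back to
Pearson centering/scaling. A module eigenprotein is the first principal
component across samples of the standardized member rows (missing member
values mean-imputed first), re-standardized and signed so it correlates
positively with the mean standardized member profile.

Module assignment computes kME (bicor of a protein against every module
eigenprotein) and assigns the best positive module when kME >= 0.30 —
the threshold is *inclusive* — otherwise `grey`; ties break to the lowest
module index. When the query proteome's samples differ from the
reference's (plasma vs brain), `mode = "recompute"` rebuilds eigenproteins
from the reference membership on the query matrix; the reference mode
mirrors re-assignment within the reference tissue itself. No special
handling exists for bottleneck-node proteins that correlate with one
module but are assigned to another; that behavior is documented upstream
of this package and out of scope here.

Overrepresentation uses the one-tailed hypergeometric ("Fisher exact")
tail `P(X >= k)` plus the standardized hypergeometric deviate
`z = (k - nK/N) / sigma`. The Z is the exact moment-based deviate, not a
probit transform of the p-value. Gene-set pruning keeps sets with
`z > 1.96`, BH q < 0.05 and at least 5 genes; the minimum-gene rule is
applied to the *overlap* by default (a hit must be supported by at least
5 foreground genes) with the set-size interpretation available, since the
pruning aims at supported hits rather than at set bookkeeping. Backgrounds
are always explicit arguments — typically all quantified proteins of the
current matrix — never implicit.

# The synthetic studies

`simulate_tmt_plasma` generates
`raw = 2^(base_i + delta_i * I(AD) + gamma_{batch,i} + lambda_j + eps)`:

| parameter | default | meaning |
|---|---|---|
| sets / batches / channels | 2 sets; 3x16 and 5x18 | discovery + replication design, one GIS channel reserved per batch |
| `n_proteins` | 2000 | quantified proteins per study |
| `n_effect_proteins` | 200 (10%) | planted AD effects, half up / half down |
| `delta_log2` | 1 | planted |log2FC|; two-sided so inter-set concordance is informative |
| `sigma_batch` | 0.5 | SD of per-(batch, protein) log2 offsets, zero-centered per protein |
| `sigma_channel` | 0.1 | SD of per-sample log2 loadings |
| `sigma_noise` | 0.25 | residual log2 noise, the replicate-SD scale of plasma TMT |
| `missing_steepness`, `missing_rate` | 4, 0.15 | logistic-on-abundance-rank missingness; steepness 0 is MCAR |

GIS channels are the noiseless per-batch realization of a fixed virtual
pool: batch and channel effects apply, but no diagnosis effect and no
measurement noise. This makes the internal-standard anchoring *exactly*
testable. Traits derive from a latent severity (standard normal, +1 SD in
AD): MoCA decreases (clamped to 0-30), CSF Abeta42 decreases, the tau
measures increase, and baselines are set so typical controls fall below
the 0.226 ratio cutoff and typical AD cases above it.

`simulate_reference_brain` plants modules as
`kme_target * e_m + sqrt(1 - kme_target^2) * noise` around latent
standard-normal eigenproteins (default 44 modules x 25 members + 200 grey
proteins over 100 samples at kME target 0.6), with CERAD-, Braak- and
MMSE-like traits driven by one designated matrisome-like module.
`simulate_lfq_fractions` emulates the enrichment experiment: triplicate
input / flow-through / enriched columns with planted enrichment and
depletion folds and fraction-unique detections.

What the generators deliberately do **not** model: peptide/PSM-level
quantification, isotope-impurity ratio compression, co-isolation
interference, non-Gaussian heavy-tailed noise, and correlated missingness
across proteins. The missingness mechanism of the real studies is not
characterized publicly; the logistic-on-rank model is an assumption, so
passing recovery tests demonstrate correctness of the *algorithms* under
the stated model, not robustness to every property of real plasma data.

# Problem sizes and numerical choices

The test suite runs the full chain at the default study size (2000
proteins, 138 channels) for the determinism and concordance checks, and
smaller sizes (60-1000 proteins) for unit-level properties; the brain
recovery check uses the 40 x 25 + 200-grey design at 100 samples. These
sizes were chosen so the entire suite exercises every stage end-to-end on
one CPU in a few minutes while keeping group sizes (about 20 per arm)
representative of the emulated study. Other numerical conventions: medians
of even counts average the central pair; TAMPOR convergence `tol = 1e-8`,
`max_iter = 250`; imputation and bootstrap draws consume seeds derived
from the single master seed through fixed stage offsets, so a run is fully
reproducible from one integer.

# Known limitations

* The pipeline starts from protein-level abundance tables; no raw-file or
  search-engine processing.
* No de-novo network construction or module-preservation statistics —
  only projection onto a provided reference.
* The bootstrap regression assumes an additive covariate model in log2
  space; surrogate-variable or mixed-model correction is out of scope.
* Fisher's method is the only meta-analysis combiner implemented;
  weighted (Stouffer) combination is not provided.
* Trait correlations are not adjusted for age or sex.
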