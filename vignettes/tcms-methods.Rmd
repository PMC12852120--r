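---
title: "Clinico-molecular subtyping with TCMS: models, parameters, and design choices"
author: "tcms package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinico-molecular subtyping with TCMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Lung adenocarcinoma (LUAD) spans a wide clinical spectrum, from indolent
ground-glass-opacity (GGO) lesions with lepidic growth to aggressive
solid/micropapillary tumors with early metastasis. The tumor
microenvironment (TME) — the immune, stromal, and vascular context of the
tumor cells — carries independent prognostic and therapeutic information.
`tcms` implements a subtyping system that integrates both axes: a 20-feature
signature panel (the Tumor Characteristics and Microenvironment Score,
TCMS), single-sample enrichment scoring, resampled consensus clustering into
four subtypes (LPI, IMD, IME, HPI), and the downstream genomic and survival
machinery used to characterize them. A synthetic-cohort generator with
planted structure makes every stage testable without patient data.

This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open, so that results produced with the
package can be interpreted — and challenged — precisely.

## The 20-feature signature panel

The registry (`default_registry()`, `build_default_registry()`) has a fixed
layout of 20 named features:

* **3 clinico-pathological signatures**, each derived from a two-group
  differential-expression comparison on log2 expression
  (`differential_expression()` + `derive_de_signature()`):
  * *GGO_lepidic* — genes overexpressed in indolent GGO/lepidic tumors;
    selection at log2FC ≥ 1 and raw p < 0.05.
  * *solid_micropapillary* — genes overexpressed in solid/micropapillary
    tumors; selection at log2FC ≥ 1 and BH-adjusted p < 0.05, followed by a
    curated exclusion list (e.g. histone genes not linked to progression).
    Both the raw/adjusted switch and the exclusion list are explicit
    arguments, because the two clinical signatures deliberately use
    different p-value types.
  * *metastasis* — genes overexpressed in early- or site-specific-metastasis
    cases; raw p < 0.05, log2FC ≥ 1. Disjointness from the
    solid/micropapillary list is checked after the exclusion step.
* **17 TME signatures** filled by consensus voting over marker sources
  (`vote_markers()`): nine cell types (CD8 T, CD4 T, B, Treg, NK,
  macrophage, CAF, endothelial, neutrophil) require presence in **at least
  4 of 9 sources** (seven deconvolution-method marker lists plus two
  single-cell datasets); three scarce cell types (T helper, M1 macrophage,
  dendritic cell) require **at least two publications**; four features
  (myeloid cells, tumor proliferation rate, matrix remodeling, angiogenesis)
  come from a **single source**; and EMT requires presence in **at least 1/5
  of the EMT literature**. All thresholds are boundary-inclusive; the
  fractional rule is evaluated as `count / n_sources >= 1/5` exactly, so
  with 84 publications the line falls at 17. Voting is monotone: adding a
  source can only add genes.

The default test of the DE step is Welch's t on log2 values; the
limma-moderated fit is available via `method = "moderated"`. At the effect
sizes the generator plants, the thresholds — not the test family — determine
signature content. Ties in the final log2FC ordering are broken by gene
symbol for reproducibility.

The registry's gene lists shipped by `default_registry()` are synthetic
placeholders with the correct structure (the published marker supplements
are not redistributed); any GMT file with the 20 canonical feature names can
replace them via `read_gmt()`.

### Single-cell QC

`qc_filter_cells()` applies, in a fixed order: genes expressed in ≥ 3
cells; cells expressing ≥ 200 genes; cells with mitochondrial count
fraction ≤ 5%; cells with detected-gene count strictly below 2500. The
order (gene → cell → mito → upper) is fixed for reproducibility; order
changes results only marginally. The upper filter retains cells *strictly
below* 2500 detected genes, the standard doublet guard; a cell at exactly
2500 is removed. Cluster-level marker discovery (Leiden/UMAP) is out of
scope; the synthetic single-cell generator supplies labeled cells instead.

## Single-sample enrichment (ssGSEA)

`ssgsea_sample()` ranks a sample's genes (average ranks for ties — FPKM
ties at zero are common) and walks them in descending order, summing the
difference between the weighted in-set ECDF and the unweighted out-set
ECDF. In-set weights are $|z|^\alpha$ with $\alpha = 0.25$ and $z = r -
(n+1)/2$ the *centered* rank statistic. Centering makes the weight profile
symmetric, which gives the statistic a clean antisymmetry (swapping in-set
and out-set on a rank-symmetric profile flips the score's sign) and keeps
it a pure function of the ranks: any strictly monotone transform of the
expression column leaves scores unchanged. Raising an in-set gene's
expression can never lower its sample's score.

Degenerate cases are defined, not accidental: a set with no overlap with
the matrix rows scores `NA` with a warning; if every in-set gene sits at
the exact median rank (total weight zero), uniform in-set weights are used.
Missing expression values are rejected outright rather than imputed.

`score_matrix()` applies this per sample and set; optional global range
normalization (divide by max − min over the whole matrix) is available, but
the clustering default is per-feature z-scoring (`zscale_features()`), which
puts all 20 features on the same scale and is the transformation the
subtype labeling rule assumes. Whether the original analysis
range-normalized or z-scored before clustering is not documented; both are
provided and the choice is recorded in the score matrix's `normalization`
attribute.

## Consensus clustering and k selection

`consensus_cluster()` resamples 80% of samples (`pItem = 0.8`, `pFeature =
1`) for `reps` iterations, clusters each subsample with PAM (k-medoids,
Euclidean distance on the z-scored features) for each k in 2–10, and
records, per sample pair, the fraction of co-draws in which they
co-clustered. Euclidean-on-z-scores is chosen over correlation distance
because with only 20 features rank-correlation distances are coarse;
the distance is switchable in principle but fixed here for coherence with
the labeling rule. PAM uses the deterministic BUILD initialization of
`cluster::pam` (so a run is a pure function of data and seed); the
consensus resampling supplies all the randomization that matters. Final
per-k labels come from PAM on `1 - consensus` as a dissimilarity, using the
classic SWAP search — the accelerated FasterPAM shortcuts can cycle on the
heavily tied dissimilarities a crisp consensus matrix produces.

`select_k()` reports three statistics of the off-diagonal consensus
entries per k: the area under their empirical CDF, the relative area
increase delta(k) (the classical elbow diagnostic), and PAC, the
proportion of ambiguous clustering (consensus entries strictly between 0.1
and 0.9). The chosen k **minimizes PAC**, with the delta-area threshold
(default 0.1) used only to break exact PAC ties toward the largest tied k.
The delta-area elbow alone was found to over-split crisply separated data:
splitting a tight cluster still inflates the CDF area (delta stays above
0.1), while PAC correctly reads the split's instability as ambiguity. A
final k is, in practice, also weighed against biological and clinical
interpretability, so `override` is a first-class argument, not a hack.

Simulation work in the test suite uses `reps = 200` rather than the
production default of 1000; consensus entries then carry sampling error of
about $1/\sqrt{200 \cdot 0.64} \approx 0.09$, which the recovery tolerances
accommodate.

## Subtype labeling and external classification

With k = 4, `label_subtypes()` anchors the cluster-to-subtype map in
biology rather than cluster indices, using per-cluster mean z-scores:

* **aggression** = mean(solid_micropapillary, metastasis,
  Tumor_proliferation, Matrix_remodeling) → the maximizing cluster is
  **HPI** (high proliferation & invasion);
* **indolence** = GGO_lepidic → the maximizer among the rest is **LPI**
  (low proliferation & invasion);
* **immunity** = mean(CD8_T_cells, NK_cells, B_cells) → of the remaining
  two, the higher is **IME** (immune-enriched), the lower **IMD**
  (immune-desert).

An exact tie in any argmax stops with an error demanding a manual map;
silent tie-breaking could invert a subtype's identity.

For external cohorts, the original stratification mechanism is not
described; the package's decision is nearest-centroid classification
(`fit_centroids()` / `classify_external()`): per-subtype mean z-profiles,
assignment by highest Spearman correlation (Euclidean optional), with the
best-minus-second-best margin reported per sample so low-confidence calls
are visible. Affinity ties fall back to the canonical subtype order with a
warning.

## Genomic layer

**Hotspot rules** (`nccn_hotspot_rules()`, NCCN v5.2022): EGFR exon 18
G719 (any substitution), exon 19 in-frame deletions, exon 20 insertions,
S768I, L858R, L861Q; KRAS G12C (G12D is *not* a hotspot under this rule
set); BRAF V600E; ERBB2 exon 20 insertions; fusions of ALK, ROS1, MET,
RET (either partner). MET exon-14 skipping is deliberately absent — the
rule list is reproduced as defined, not extended to broader practice.
Protein changes are parsed only as `p.`-prefixed single-letter missense
forms; anything else is skipped with a warning, never silently matched, and
ERBB2 exon-20 non-insertion events are surfaced via message.

**Association testing** (`pairwise_association()`,
`compare_event_frequencies()`): exact two-sided Fisher p by hypergeometric
tail summation; the odds ratio is the plain sample odds ratio with 0 and
Inf reported exactly (no Haldane correction) — direction (co-occurrent /
exclusive) is read off the odds ratio, significance off the p-value.
Raw and BH-adjusted p are both always reported, since the appropriate
correction scope for somatic-interaction scans is analysis-dependent.
Exact tests on discrete tables are conservative: null p-values are
super-uniform, so calibration is "level never exceeds nominal", not
uniformity.

**CNV events** (`cnv_gene_events()`): GISTIC-style gene-level integers in
−2..2 are consumed, not computed; amplification means exactly +2, deep
deletion exactly −2, and shallow ±1 calls never count as events.

**SV taxonomy** (`classify_sv()`, `build_sv_catalog()`): deletions, tandem
duplications, and inversions are binned by size into five half-open ranges
(1–10 Kb, 10–100 Kb, 100 Kb–1 Mb, 1–10 Mb, > 10 Mb; sub-1 Kb events fold
into the smallest bin so catalogs conserve counts), translocations carry no
size, and every event is clustered or non-clustered — 32 categories in
canonical order (non-clustered block first). The clustered/non-clustered
distance rule is not specified upstream; the package's rule is adaptive per
sample: with gaps between consecutive same-chromosome breakpoints pooled
across chromosomes, the threshold is tau = mean(gap) / `cluster_factor`
(default 10), and a record is clustered iff any of its breakpoints lies
within tau of another record's breakpoint on the same chromosome. The
generator and the classifier share this one rule, which is what makes
round-trip testing meaningful.

**SV signatures** (`extract_signatures_nmf()`): NMF by multiplicative
updates on the KL objective (the natural choice for count catalogs), with
the objective checked to be non-increasing at every iteration. Per
candidate rank, several random restarts are clustered (PAM at cosine
distance on the pooled signature columns) and the mean silhouette is the
rank's *stability*; the best restart's reconstruction gives the *mean
per-sample cosine distance*. The selected rank is the largest one that is
both stable (≥ 0.8) and still improves reconstruction by at least 0.01
mean cosine distance over the previous rank. Stability alone was found
insufficient: a surplus rank's signatures remain moderately reproducible
(silhouette ≈ 0.85 in planted-rank experiments), but its reconstruction
gain collapses to ≈ 0.002, so the elbow condition is what stops the rank
search. Refitting known catalogs uses NNLS (`refit_exposures()`), with the
KKT condition (residual orthogonal to active columns) verified in tests.

## Survival machinery

`km_estimate()`, `logrank_test()`, and `cox_fit()` wrap the standard
product-limit, O−E/V log-rank, and Cox partial-likelihood machinery of the
`survival` package. Ties use **Breslow** handling by default (switchable to
Efron; Breslow is the simpler convention and the difference is negligible
at the tie densities involved). Subjects censored at an event time remain
in the at-risk set.
Zero-variance covariates are rejected; non-convergence and monotone
likelihood (complete separation) are flagged, never silently returned.
`median_split()` defines "high" as strictly above the cohort median, ties
going to "low". `hotspot_cohort_filter()` implements the cohort exclusion
used for hotspot survival comparisons: AIS/MIA patients are dropped, as are
stage-I patients who are relapse-free and received no adjuvant therapy;
everyone else is retained. Endpoint time units are whatever the input uses
(months in all documentation examples); no conversion is attempted.

## The synthetic cohort generator

The generator (`generate_bulk_cohort()` and friends) emulates exactly the
statistical structure the pipeline assumes, no more:

* **Expression** is Gaussian directly on the log2 scale: signature-member
  genes for feature f have mean `baseline + effect_size *
  profile$feature_means[f]`, background genes sit at baseline, all with SD
  `noise_sd`. No count layer, library-size variation, batch structure, or
  gene-gene correlation beyond the planted blocks — so passing recovery
  tests demonstrates correctness of the scoring/clustering machinery, not
  robustness to those real-data features.
* **Default study conditions**: n = 400 samples, equal subtype proportions
  (0.25 each), effect size 1.5 SD, noise SD 1, 20 signatures × 15 genes in
  2000. The effect size is chosen so that consensus clustering recovers
  k = 4 reliably at n = 400 — it encodes "clearly distinct subtypes", the
  regime the subtyping method is designed for.
* **Survival** is exponential with rate `base_rate × hazard multiplier`,
  independent censoring (each subject censored with probability
  `censor_rate`, observed at a uniform fraction of its latent time).
  Default hazard multipliers (OS: LPI 0.3, IME 0.8, IMD 1.2, HPI 2.5)
  encode the qualitative prognosis ordering — LPI best, HPI worst, the
  immune-desert subtype worse than the immune-enriched one; no
  cohort-independent numeric values exist to copy. Weibull shape would be a
  config extension; the exponential matches every assumption the KM /
  log-rank / Cox layer makes.
* **Alterations**: baseline per-event Bernoulli rates (defaults 10–40%,
  configurable — published baselines for non-hotspot events are not
  available, so these are stated as arbitrary); each co-occurrence pair's
  joint 2×2 law is inflated to the stated odds ratio with marginals
  preserved (closed-form solution of the odds-ratio quadratic), so planted
  marginal frequencies remain interpretable. Hotspot-positive samples
  (probability `hotspot_rate`, default 0.6) receive one variant drawn
  uniformly from the rule list with well-formed fields.
* **SVs**: per-sample category counts are Poisson with mean `signatures ×
  exposures`. Placement respects the classifier's own tau rule by
  construction: non-clustered breakpoints are laid out with stratified
  spacing (inter-record gaps at least half the mean spacing, hence well
  above tau), clustered events are grouped into clumps of ~4 whose anchor
  breakpoints share a window of chromosome-length/1000, two clumps per
  chromosome (so within-clump distances sit well below tau while the
  between-clump span keeps the sample's mean gap large). Sizes are drawn
  log-uniformly within each category's bin.
* **Single cells**: negative-binomial counts, markers overexpressed in
  their own type, with controllable fractions of low-quality cells
  (globally depressed expression) and high-mitochondrial cells (~20% mito
  fraction) for QC round-trip tests.
* **Seeds**: one master seed; each table draws from a substream at a fixed
  offset, so adding a table never perturbs the others. All generators are
  pure functions of (config, seed).

## Problem sizes used in the test suite

The packaged simulations use: subtype recovery at n = 400, k = 2–10,
`reps = 200`, 20 seeds; NMF rank recovery at 50 samples, ranks 1–6, 8
restarts, 20 seeds; Cox/log-rank calibration at n = 1000 and 1000 null
replicates; exact-test oracles enumerate all 2×2 tables with n ≤ 40 and
all ssGSEA cases with n ≤ 12 genes and sets up to size 4. These sizes are
the package's choice of a thorough-but-routine regression suite; the
production-scale parameters (reps = 1000, rank search to 30) remain the
function defaults or documented arguments.

## Known limitations

* The shipped registry gene lists are structural placeholders; scientific
  use requires supplying real marker supplements via GMT.
* The subtype labeling rule assumes the four planted phenotypes are
  present; on cohorts where two clusters share an aggression profile it
  will (by design) stop rather than guess.
* The SV clustered/non-clustered rule is a stated, shareable substitute for
  the (unpublished) upstream heuristic, not a reconstruction of it.
* Exact Fisher tests are conservative on small tables; co-occurrence scans
  on rare events lose power accordingly, and the reported BH adjustment
  inherits that conservativeness.
* The generator does not simulate tumor purity, clonality, copy-number
  segments, or read-level data; claims supported by the test suite are
  about the analysis machinery, not about robustness to upstream noise.
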