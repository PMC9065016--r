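---
title: "Methods: the inflammation EWAS pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the inflammation EWAS pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`inflamethyl` implements the statistical machinery of a large multi-cohort
epigenome-wide association study (EWAS) of chronic low-grade inflammation,
measured as natural-log serum C-reactive protein (lnCRP, ln mg/L). The
pipeline covers: per-cohort association of lnCRP with CpG methylation under
sample and probe filters; fixed-effect meta-analysis with double genomic
control; meta-analysis of inter-CpG correlations with distance profiling,
5 kb locus pruning and density clustering; bidirectional two-sample
Mendelian randomization (MR) with triangulation; Baron–Kenny mediation with
the Aroian–Sobel test; permutation enrichment against genomic feature
tracks with standard-error-matched null sets; and a beta-weighted
methylation risk score with an odds-ratio to relative-risk transformation.
A synthetic multi-cohort generator with a known causal graph makes every
stage testable end to end without access to cohort data.

# The synthetic study and its causal graph

`sim_config()` / `simulate_study()` generate cohorts from the graph

* BMI → lnCRP (default 0.08 ln mg/L per kg/m²) and smoking → lnCRP
  (0.15 per never/former/current category), plus a polygenic score → lnCRP
  arm (0.25 per SD of the true score) and a neutrophil-fraction term, with
  residual lnCRP noise of SD 0.8 — together giving an lnCRP SD near 1;
* lnCRP → CpG for a `frac_crp_responsive` minority of CpGs (the dominant
  direction), with slope γ drawn from `gamma_range` (default
  0.01–0.05 methylation units per ln mg/L, either sign) and multiplied by a
  per-cohort `ancestry_scaling` factor;
* SNP → CpG → lnCRP for a smaller `frac_cpg_causal` arm: each causal CpG
  has one cis-SNP within ±400 kb whose dosage shifts logit methylation, and
  its methylation feeds back into lnCRP with slope drawn from
  `delta_range` (2–6 ln mg/L per methylation unit, matching the magnitude
  of the raw discovery effects the pipeline estimates).

Methylation is generated on the logit scale and mapped through the inverse
logit, which keeps beta values inside (0,1) without clipping artifacts. The
responsive-CpG shift is `γ / (μ(1-μ)) · (lnCRP − mean)` on the logit scale,
so the slope of the *beta-value* on lnCRP at the CpG's baseline mean μ
equals γ exactly in the small-noise limit — this is the linearized truth
used in parameter-recovery tests. Confounding comes from six Dirichlet
leukocyte fractions (neutrophil-dominant concentrations 9, 2, 3, 4, 30, 1)
with per-CpG loadings, batch shifts (SD 0.1 logit units), one continuous
technical covariate, and "block" structure: about 20% of CpGs sit in tight
2–3-probe blocks within <5 kb sharing a latent factor, which produces the
local correlation the pruning and distance-profiling stages exist for.
Because a null CpG can share a block factor with a causal CpG, it can
inherit a genuine lnCRP association — correlated-neighbor hitchhiking, the
phenomenon 5 kb pruning addresses.

Defaults describe the emulated study conditions: 30 cohorts with sizes
drawn in 150–2,700; tests and the acceptance script state smaller explicit
sizes (for example 3 cohorts × 500 samples × 2,000 CpGs for null
calibration, n = 3,000 for mediation power, n = 4,000–5,000 for the MR
arms), chosen so each check retains the power the property needs. The RNG
contract is a single integer seed with per-cohort substreams derived as
`seed + cohort_index`; identical `(config, cohort_index)` reproduce
byte-identical data.

What the generator does **not** emulate: realistic linkage disequilibrium
(each SNP is an independent binomial draw), array intensity artifacts,
family or kinship structure, and cohort-specific normalization pipelines.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated graph, not robustness to those real-data
complications.

# Cohort-level association model

The per-cohort regression is `lnCRP ~ CpG + age + sex + cell fractions +
batch + technical covariates`, one OLS fit per CpG
(`fit_cpg_associations()`). Internally the scan uses the
Frisch–Waugh–Lovell decomposition: outcome and every CpG column are
residualized once against the shared covariate design, and the per-CpG
simple regression on residuals reproduces the full-model coefficient, SE
and t-based two-sided p-value exactly (verified against `lm()` per CpG).
P-values use the t distribution on the residual degrees of freedom rather
than the normal — indistinguishable at n ≫ p but exact at small n. Aliased
nuisance columns (the six cell fractions sum to one) are dropped by QR
pivoting as `lm()` does; a CpG collinear with the covariates yields NA with
a warning rather than an error.

Sample filtering keeps lnCRP within median ± 4 SD, computed on the
pre-exclusion values with the plain sample SD (the robust-SD alternative is
not used; the rule's source does not specify one) and inclusive bounds. BMI
filtering for mediation is the mean-centred analogue. Probe filtering keeps
autosomal probes without a SNP in the last 10 bp of the probe sequence and
not flagged cross-reactive.

`quantile_normalize()` is the classical across-sample form — each sample's
sorted values are replaced by the mean order statistic, ties averaged
(delegated to limma's implementation). A within-probe inverse-normal
transform would be an alternative reading of "quantile normalized"; the
across-sample form was chosen as the classical array convention and is
flagged here. `residualize_methylation()` then removes age, sex, the six
cell fractions and batch by OLS; the residuals feed mediation, MR,
correlation and risk-score association stages.

# Meta-analysis and double genomic control

`ivw_meta()` is METAL-style fixed-effect inverse-variance weighting:
weights `1/SE²`, combined SE `(Σw)^{-1/2}`, two-sided normal p, per-cohort
direction string with `?` for missing cohorts, and Cochran's Q
heterogeneity. `meta_ewas()` wraps it with the double genomic-control
procedure: the inflation factor λ is the median of squared Z statistics
divided by 0.4549364 (the χ²₁ median); "GC in" inflates each cohort's SEs
by √λ of that cohort (per-cohort λ, since a shared-λ variant is equally
consistent with the procedure's name but less adaptive), and "GC out"
deflates the meta-analysis χ² by the meta-level λ. Following GWAS
convention, λ ≤ 1 is reported but never used to amplify statistics. Two
consequences are documented and tested: correction is idempotent up to
median noise, and the corrected false-positive rate on a null study is
mildly conservative (the one-sided rule only ever deflates), which is why
null-calibration checks the raw meta p-values against the binomial band
and only bounds the corrected rate from above.

Discovery significance is fixed at P < 1e-7 (the printed threshold, not
0.05 divided by the number of tested probes). Standardized coefficients are
`effect × SD_CpG / SD_lnCRP` with pooled SDs computed as the square root of
the sample-size-weighted mean of cohort variances. Ancestry replication
requires P < 0.05 and a concordant direction. The model-comparison
sensitivity report correlates Z-scores between a base and an adjusted
model, lists sign flips, and computes a per-CpG two-estimate Cochran Q that
deliberately ignores the covariance between the two models' estimates
(they share samples); this approximation is labelled in the output since
its bias direction is unknown.

# Correlation structure, pruning, clustering

Per-cohort Pearson correlations between residualized CpGs are pooled on the
Fisher-z scale with `n − 3` weights (fixed-effect; the named sample-size
weighting), back-transformed by `tanh`; `|r| = 1` is clamped at
`1 − 1e-12` with a warning. Distances between same-chromosome pairs fall
into the fixed 13-bin layout (1–5 kb in 1 kb steps, then 10, 20, 50, 100,
150, 300, 450, >450 kb) with right-closed edges — a pair exactly 5,000 bp
apart is in the 5 kb bin — and cross-chromosome pairs go to a separate
"trans" bucket.

`prune_5kb()` reduces hits to independent loci greedily: repeatedly retain
the globally lowest-P unclaimed probe, drop unclaimed probes on the same
chromosome within ≤ 5,000 bp (inclusive), ties broken lexicographically by
probe id. Greedy-by-P was chosen over a sliding window because it is
deterministic and idempotent; tests verify it against exhaustive
enumeration of admissible retain-subsets on instances up to 12 probes.

`cluster_correlations()` embeds the rows of the pooled correlation matrix
in two dimensions and applies shared-nearest-neighbor (SNN) density
clustering with the study parameters k = 35, minPts = 35, eps = 7: two
points are SNN-reachable when each is in the other's k-neighborhood and
they share at least eps of their k nearest neighbors; core points have at
least minPts reachable points; clusters grow from cores and everything else
is noise. The embedding is pluggable (`embed_fun`); the default is
classical metric MDS (`cmdscale`), which is deterministic and
dependency-free — a UMAP wrapper can be supplied where that embedding is
preferred. Neighborhoods include distance ties so coincident embedded
points behave symmetrically (the degenerate all-identical-rows case is one
cluster, not noise).

# Mendelian randomization and triangulation

Hypothesis "CpG causes CRP": for each candidate CpG, SNPs within ±500 kb
are recoded to a dominant carrier indicator and the residualized
methylation regressed on each; a valid instrument needs P < 5e-8, and among
several the lowest-P SNP is chosen (single-instrument Wald ratio — the
source procedure names the ratio method without an instrument count).
Instruments with a direct outcome path — conditional SNP association with
lnCRP given the CpG at P < 0.05/1511 — are excluded. The Wald estimate is
`β_outcome/β_exposure` with first-order delta SE `SE_outcome/|β_exposure|`.
The printed formula for this arm in the source inverts the ratio (exposure
path over outcome path); the standard orientation is implemented and both
orientations are emitted with explicit labels rather than silently
"fixing" either.

Hypothesis "CRP causes CpG": a 52-SNP beta-weighted polygenic score for CRP
(additive coding — the dominant model is used only for the cis scans) is
regressed against every sentinel CpG; score SNPs with a direct CpG effect
at P < 0.05/(52×1511) are removed from the score. Triangulation compares
observed instrument→outcome effects with the product of the two path
estimates: Pearson ρ with a two-sided p and an exact two-sided binomial
sign test at null probability ½. Direction discrimination is a tested
invariant: in a world with only CpG→CRP loci the Wald ratios are
Bonferroni-significant while the reverse triangulation is null, and vice
versa.

Mixed-model kinship adjustment from the original cohort analyses is out of
scope (synthetic samples are unrelated); the summary-statistic interfaces
accept externally computed estimates so mixed-model outputs can be
supplied.

# Mediation

`baron_kenny_paths()` fits the four OLS path models — a: mediator ~
exposure; b and c′: outcome ~ exposure + mediator (mediator and exposure
terms); c: outcome ~ exposure — sharing one covariate set across all paths
(the most conservative reading of an unstated covariate convention). For
linear models on one dataset `a·b = c − c′` holds to numerical precision
and is asserted at 1e-8; across IVW-pooled cohorts the identity need not
hold and both quantities are reported.

The Aroian–Sobel statistic is `Z = ab/√(b²SE_a² + a²SE_b² + SE_a²SE_b²)`.
The printed variant of this formula places the SE product outside the root
and unsquared, which is dimensionally inconsistent; the standard Aroian
form is the default and the printed variant is available as
`variant = "as_printed"` for comparison only.

The eligibility gate requires a nominally significant a-path and c-path and
an attenuating indirect effect, operationalized as `|c′| < |c|`: under full
mediation the direct effect hovers around zero and may cross it, which
still counts as attenuation, while suppression (`|c′| > |c|`) is labelled
`positive_indirect` and excluded. A same-sign requirement on c and c′ was
considered and rejected because it misclassifies roughly half of genuine
full mediations. The Sobel test is computed only for eligible records, and
is conservative under the no-mediation null (rejection ≤ 6% at α = 0.05 in
10,000-simulation checks). Six candidate causal orderings can be screened
with `select_model()`; note that in a linear-Gaussian world the
Baron–Kenny preconditions cannot by themselves refute reversed orderings —
the gates report violations, they do not prove direction.

# Enrichment with SE-matched permutation nulls

Overlaps between a CpG set and a BED feature track use centralized
coordinate conversion: the manifest is 1-based, BED is 0-based half-open,
and a CpG counts at most once per track (union semantics). The permutation
null matches the target's standard-error composition: universe SEs are
binned into fixed 0.005-wide intervals `[k·0.005, (k+1)·0.005)` and each of
the 10,000 permuted sets draws exactly the target's per-bin counts without
replacement. Matching is on the meta-analysis SE (the source text uses
"standard errors" and "SD" interchangeably); target CpGs stay in the
sampling pool by default (`exclude_target` switches this). Empirical
p-values use the add-one rule in both directions so no p is zero, and a
Fisher exact p is computed from the 2×2 table of the observed overlap
against the rounded null mean — one defensible reading of a "Fisher p from
the null mean", labelled as such. Because overlap counts are small
integers, calibration checks use randomized p-values (exactly uniform under
exchangeability); the deterministic add-one p is separately asserted to be
valid, never anti-conservative.

# Risk score and relative risk

The methylation risk score is the plain weighted sum of beta values with
discovery coefficients as weights, no rescaling for missing CpGs (a
`rescale_missing` sensitivity option exists). Binary phenotype associations
use logistic regression; continuous use OLS; per-cohort estimates pool by
IVW. Odds ratios convert to adjusted relative risks via
`RR = OR/(1 − LR + LR·OR)` with the literature lifetime risks COPD 0.1145,
T2D 0.399, MI 0.248, CAD 0.4015, hypertension 0.81. The "per one percent of
the score" risk is computed on the log-odds scale
(`OR_unit = exp(logOdds × 0.01)`), chosen because the full score spans the
0→1 methylation swing and log-odds are the scale on which logistic effects
add; a linear-odds alternative is exposed via `scaling = "linear_odds"`.
The published per-percent figures cannot be reverse-engineered without the
unpublished full odds ratios, so this scaling is a documented convention,
not a validated reproduction.

# Numerical choices and degenerate inputs

* λ estimator: median of Z², constant 0.4549364; fewer than 100 statistics
  triggers a warning.
* Collinear focal predictors: NA with warning; collinear nuisance columns:
  silent QR pivot drop.
* Zero or negative SEs in meta input: record rejected with a warning;
  `|r| = 1` in correlation pooling: clamped.
* Constant polygenic or risk scores: NA estimates with a warning;
  separation in logistic fits: flagged, estimate NA.
* Pruning ties: lexicographic by probe id; probes without positions are
  excluded with a warning.
* All thresholds live in `pipeline_config()` with the study defaults
  (discovery 1e-7, replication 0.05, instrument 5e-8, cis window 500 kb,
  prune window 5 kb, 10,000 permutations, SE bin 0.005, mediation α 0.05).

# Known limitations

The generator's independence assumptions (no LD, unrelated samples) make
the MR power checks optimistic relative to real cohorts. The two-model
heterogeneity statistic ignores estimate covariance. The SNN clustering
operates on an MDS embedding by default, so cluster geometry can differ
from a UMAP-based analysis even with identical graph parameters. Reported
percentages are recomputed from printed count pairs where individual-level
data would be required otherwise; one such pair (729/1136) rounds to 64.2%
while its source prints 64.1%, a truncation noted in the test suite.
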