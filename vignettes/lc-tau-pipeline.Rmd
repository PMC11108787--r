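---
title: "From locus coeruleus integrity to tau spread: models, synthetic worlds and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From locus coeruleus integrity to tau spread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lctau)
```

# The scientific problem

The locus coeruleus (LC), a small noradrenergic brainstem nucleus, is
among the earliest sites of hyperphosphorylated tau in Alzheimer's
disease. The package implements an analysis cascade around one central
question: does declining LC integrity, measured in vivo with a dedicated
neuromelanin-sensitive MRI sequence, precede and predict tau
accumulation in the medial temporal lobe (MTL), with downstream
consequences for cognition — and do the implicated regions share a
transcriptomic profile that might explain their joint vulnerability?

The cascade has five stages, each an independent, testable unit:
LC signal quantification; voxel-wise tau regression with Monte-Carlo
cluster correction; moderation/mediation models at the subject level;
ex vivo tangle staging with exact binomial inference; and an
imaging-transcriptomics similarity analysis. Because the cohort,
autopsy and atlas datasets behind such analyses are access-restricted,
a first-class synthetic-data module generates inputs with known planted
structure for every stage.

# LC signal model

The LC slab is normalized slice-wise against a pontine tegmentum
reference as a contrast ratio, $(I_v - \bar{I}_{\mathrm{ref}(s)}) /
\bar{I}_{\mathrm{ref}(s)}$. This choice (over, say, z-scoring per slice)
follows the established contrast-ratio convention for neuromelanin
imaging, makes a uniform slab map to exactly zero, and renders the
extracted statistic invariant to global scanner gain: multiplying the
raw slab by any $k > 0$ leaves the output unchanged (a tested property).

LC intensity is the best mean over 26-connected sets of five in-mask
voxels. The stated search procedure — "30 search iterations" — is
under-determined, so the package makes it deterministic: the 30 seeds
are the 30 brightest in-mask voxels (ties broken by ascending linear
index), and each restart grows candidate sets by connected neighbors.
Pure brightest-neighbor (greedy) growth turned out to be measurably
myopic: on random 30-voxel masks it matched the exhaustive
connected-quintet optimum only ~88–90% of the time. Each restart
therefore keeps a small beam (width 8) of the highest-sum partial sets;
greedy growth is the width-1 special case. With the beam the search
agreed with exhaustive enumeration on 100/100 random masks while
remaining deterministic, and it provably never exceeds the true optimum
(it only ever evaluates valid connected sets). Connectivity is
26-connected in 3D across the 3-mm slices by default; an in-plane-only
search can be emulated by masking single slices, since the original
method's within- vs across-slice behavior is unstated.

Inversion is plain negation (`intensity_r = -mean(left, right)`), not
`max - x`: negation preserves linear-model coefficients up to sign, so
every downstream regression is interpretable on the same scale.

# Voxel-wise regression and cluster inference

Each voxel is fit by OLS of the outcome map on an intercept, the
predictor and covariates; the predictor's $t$ is mapped to
$z = \Phi^{-1}(T_{df}(t))$ with the CDF clamped to
$[10^{-15}, 1-10^{-15}]$ so perfect fits stay finite. The voxel
threshold is one-tailed $z > 1.64$; cluster extent comes from a
Monte-Carlo null: white Gaussian volumes smoothed at the configured
8-mm FWHM, re-standardized within the mask, thresholded, and the
maximum cluster size recorded per iteration. The extent threshold is
one more than the $\lceil(1-\alpha) n\rceil$-th order statistic of
those maxima. Smoothness is taken from configuration rather than
estimated from residuals (no spatial autocorrelation-function
estimation); this is a stated limitation — on real data the assumed
FWHM should be chosen to match the preprocessing smoothing.

Directional comparison (does baseline LC predict follow-up tau better
than the reverse?) extracts the predictor's *partial correlation*
$r = t/\sqrt{t^2 + df}$ at every cluster voxel for both model
directions and runs a paired t-test over voxels. Partial correlations
rather than raw betas because the two directions' coefficients live on
different scales; $r$ is unitless and comparable. Pairing is over the
forward-analysis cluster voxels by default (a `labels` argument selects
other sets). Degenerate cases are defined, not errors: identical
coefficient vectors give $t = 0$; an exactly constant nonzero shift
gives $t = \pm\infty$ with a zero p-value.

# Subject-level models

**PACC5.** The cognitive composite is the mean of five z-transformed
test scores (MMSE, Logical Memory Delayed Recall, Digit Symbol, FCSRT
free+total, Category Fluency); reference means/sds default to the
supplied cohort, so the reference cohort's composite has mean zero (a
tested invariant). Any missing component propagates to a missing
composite; analyses use complete cases per model with the dropped count
recorded.

**Robust regression** is Huber M-estimation (tuning 1.345, MAD scale,
IRLS to relative change $< 10^{-8}$ or 200 iterations). Huber was
chosen over other M-estimators because it is the most common referent
for "robust linear regression" and coincides with OLS on clean data,
which keeps recovery tests interpretable.

**Johnson–Neyman.** The moderated model $y = b_0 + b_1 x + b_2 m +
b_3 xm + \text{covariates}$ yields significance boundaries as roots of
$(b_1 + b_3 m)^2 = t^2_{crit}\,\mathrm{Var}(b_1 + b_3 m)$ — a quadratic
in $m$ classified by the sign pattern of its leading coefficient and
discriminant into above/below/inside/outside/everywhere/nowhere. The
everywhere/nowhere labels are judged over the *observed* moderator
values: with a near-zero interaction and a strongly significant main
slope the quadratic always has real roots, but they lie far outside any
observed moderator, and "significant everywhere" is the informative
description of the data at hand. Boundaries are reported regardless.
Boundaries are invariant to affine rescaling of $y$ and equivariant to
affine rescaling of $m$ (tested). A dense-grid significance scan is the
independent oracle.

**Mediation** runs three OLS regressions sharing one covariate set —
mediator on x; outcome on x and mediator; outcome on x — so the
identity $ab + c' = \text{total}$ holds *exactly on every bootstrap
draw*, which the tests assert at $10^{-8}$. The same covariates must
enter all three paths for the identity to hold; that resolves the open
design question of per-path covariate sets. CIs are percentile over
subject resamples; p-values are two-tailed bootstrap tail proportions
(not Sobel). The proportion mediated is reported unclipped: values
above 1 are legitimate when direct and indirect effects have opposite
signs.

**Amyloid positivity** is the point between the two component means of
a univariate two-component Gaussian mixture (EM, k-means starts, best
log-likelihood over restarts) where the posterior responsibility equals
0.5, solved in posterior log-odds so tight well-separated modes do not
underflow. Component sds are floored at $10^{-3}$ sd(data) so
point-mass-like modes stay numerically stable. Unimodality is flagged
(warning, cutoff NA) when the components merge (means closer than 0.1
pooled sd) *or* when the fitted mixture density has no dip between the
component means — EM on genuinely unimodal data converges to two
overlapping components about one sd apart, which the distance criterion
alone never catches.

# Ex vivo staging

Thresholds are derived in two Braak-conditioned steps: the maximum
density among subjects at (or below) the conditioning stage — stage 0
for the LC, one below the stage of interest for the allocortical
region — then the mean with a 95% t-interval over cognitively
unimpaired subjects *strictly below* that maximum. The mean (not a CI
bound) is the operating classification point, with both CI bounds
exposed for sensitivity reruns; "high" means strictly greater, so ties
classify low. Group proportions get exact Clopper–Pearson intervals
via the beta-quantile form, cross-checked in tests against direct
binomial-tail inversion. All four concordance classes are always
reported even when one is empty.

Partial Spearman correlations are rank-then-residualize: rank transform
(average ranks on ties), OLS-residualize both rank vectors on the
covariates, Pearson-correlate the residuals, and test on
$n - 2 - p$ degrees of freedom. The residualize-then-rank alternative
gives a different (also defensible) estimator; rank-first was chosen
because it is the common definition and reduces exactly to classical
Spearman with no covariates.

# Imaging transcriptomics

The aggregation is three explicit steps per donor — probe-to-gene mean,
sample-to-region assignment, within-region median — followed by a
median across donors. Sample assignment is strict: inside a labeled
voxel, or nearest labeled voxel strictly closer than 3 mm (ties to the
smallest label), else unassigned. The LC similarity profile is Pearson
correlation across genes on values as provided (microarray atlas values
are already log-scale; a rank-based variant is a one-line change at the
call site). The permutation null shuffles the partner column's gene
assignment with the seed column fixed; shuffling either column is
distributionally equivalent. Top-fraction sets take the
$\lfloor 0.05\,n\rfloor$ highest-expressed genes per region with ties
broken by gene id, making every set deterministic. The risk-gene
overlap probability is plain set overlap against uniform random draws,
$(1 + \#\{ \text{draw} \ge \text{obs}\})/(n_{draws}+1)$, which the
tests verify against the closed-form hypergeometric tail. Gene-ontology
enrichment is deliberately out of scope: the module exports the ranked
union gene list for external enrichment tools.

# The synthetic world

Every generator writes a machine-readable truth record; recovery tests
consume only the generated data and touch the truth record solely for
the final comparison.

**Cohort** (`cohort_sim_spec`): 77 subjects by default (65% female,
ages uniform on 42–90, ~95% with CDR 0), a 20³ grid of 2-mm "SUVR"
voxels with baseline level 1.2, a 27-voxel MTL cluster carrying the
planted LC→follow-up-tau slope, a second cluster carrying the
LC×amyloid product, amyloid drawn from the mixture
0.8·N(1.1, 0.05²) + 0.2·N(1.6, 0.10²) (analytic posterior crossing
≈ 1.29, near the conventional 1.324 DVR cutoff), and a planted
mediation path a = 0.5, b = 0.4, c' = 0.1 (indirect 0.20). Two planted
missing amyloid values and three missing follow-up cognition values
mirror per-analysis complete-case sizes of 75 and 74. Two deliberate
modeling choices: tau volumes are generated directly in SUVR units (the
inference consumes SUVR maps; PET physics adds nothing testable here),
and planted slopes act on the *standardized* LC score — on the raw
contrast-ratio scale (sd ≈ 0.05) slopes of 0.5 would be statistically
invisible at n = 200, which would make every recovery test vacuous.
The generator does not emulate realistic MRI artifacts, spatial noise
correlation, motion, or longitudinal atrophy; a green recovery test
establishes that the estimators find planted effects under iid noise,
not that they are robust to scanner physics.

**Tangles** (`tangle_sim_spec`): 160 subjects in four concordance
classes with planted proportions 0.20 / 0.05 / 0.75 (remainder
low/low). Low and high densities live on disjoint supports
(LC: ≤0.05 vs ≥0.30; hippocampus: ≤1.0 vs ≥5.0), Braak stages follow
the class structure (region-low subjects at 0–I, a Braak-II "spacer"
subgroup of unimpaired both-class subjects with hippocampal densities
between 5 and 7.91, the rest at III–VI), and the both-class carries a
+2 percent-area amyloid shift. Two generator decisions matter for
interpretation. First, class counts and per-class unimpaired counts
are allocated exactly (stratified) rather than drawn iid: the derived
mean threshold is a ratio of group contributions, and under iid
allocation its sampling noise (±0.02 around ≈0.27) crosses into the
lc-only support on a nontrivial fraction of seeds, turning the
staging-recovery test into a coin flip. With stratification the derived
thresholds land deterministically inside the planted gaps and
classification recovers every planted class. Second, the spacer
fraction (14.5% of the both class) is chosen so the derived hippocampal
cutoff sits near the middle of its gap. Real tangle densities are of
course continuous, not gap-structured; the generator states a world in
which threshold *recovery* is well-posed, which is what the machinery
tests need.

**Expression** (`expression_sim_spec`): 2,000 genes × 20 regions × 3
donors × 2 samples/region (1–3 probes per gene, probe and sample noise
sd 0.05 against unit-variance gene profiles) — a deliberate ~10× scale
reduction of a six-donor, 20,737-gene atlas. Five regions carry planted
LC correlations (0.31, 0.24, 0.22, 0.34, 0.28, the reported similarity
profile); the rest are independent. The risk list of 75 genes contains
exactly 3 members guaranteed inside the LC/partner top-set union and 72
fillers drawn from genes below the 80th percentile of every relevant
column — a margin that sample noise cannot bridge to the top 5%, so the
planted overlap is exact. An earlier design that forced fillers to a
constant low value in all regions silently inflated every
inter-regional correlation (shared structure is correlation); profiles
are now never modified for the default spec, and the optional
top-gene-planting mechanism (which does modify profiles) is documented
as incompatible with asserting the correlation targets.

# Numerical and interface choices

- Voxel indexing is 0-based at interfaces (NIfTI convention); world
  coordinates are mm through the affine. Inter-volume operations demand
  matching shape and affine — resampling/registration is out of scope.
- NIfTI-1 I/O is implemented in-package (no NIfTI reader exists in the
  declared dependency environment): 3D volumes, the five common
  datatypes, sform affines, gzip; volumes are written as float64 so
  round-trips are bit-exact. Read/write were cross-validated
  element-for-element against an independent Python implementation.
- All randomness flows from one master seed; stages derive sub-seeds
  deterministically from a stage label, so any stage can be re-run
  alone and reproduce its output bit-exactly.
- Monte-Carlo defaults follow the analysis constants (10,000 cluster
  iterations, 5,000 bootstrap draws, 10,000 permutations); tests scale
  these down (e.g. 500–1,000) and say so, relying on the checked
  property that the estimators are unbiased in the iteration count.

# Known limitations

- Cluster-null smoothness is assumed, not estimated; FWER control is
  demonstrated only for matched simulation smoothness.
- The centiloid conversion for amyloid values is a configurable linear
  map with no defaults, since the published coefficients are not
  reproduced here; Johnson–Neyman boundaries are reported in the
  moderator's native units.
- The greedy/beam LC search is exact only empirically (100/100 against
  enumeration); adversarial masks can in principle defeat any fixed
  beam width. The enumeration oracle in the test suite is the ground
  truth for such cases.
- The transcriptomic stage correlates raw regional profiles; per-gene
  standardization or rank correlation would change the profile and is
  exposed only as a user-side transformation of the input matrix.
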