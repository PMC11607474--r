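---
title: "Quantifying PET tumor burden and dissemination for lymphoma prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PET tumor burden and dissemination for lymphoma prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petburden)
```

## The problem

Advanced mantle cell lymphoma presents with multiple FDG-avid lesions spread
through nodal and extranodal sites. Two families of PET-derived features are
candidate prognostic markers: *metabolic burden* — the maximum standardized
uptake value (SUV), the metabolic tumor volume (MTV, the summed volume of all
segmented lesions), and total lesion glycolysis (TLG, the sum over lesions of
volume x SUVmean) — and *dissemination*, summarized by Dmax, the largest
Euclidean distance between any two lesions, optionally divided by body
surface area (Dmax-bsa) to remove the trivial dependence on patient size.
After first-line therapy the end-of-treatment scan is graded on the Deauville
five-point scale and collapsed to the Lugano binary response (complete =
Deauville 1-3, no new lesions). The prognostic chain then dichotomizes each
continuous feature at a ROC-derived cutoff and relates features and response
to progression-free (PFS) and overall survival (OS) through Kaplan-Meier
curves, log-rank tests and Cox proportional-hazards regression.

`petburden` implements that chain end to end, together with two generators —
voxel-level phantoms and patient-level cohorts — so every stage can be tested
against known ground truth without access to clinical data.

## Lesion segmentation

Hypermetabolic foci are detected as 3-D connected components above a fixed
SUV seed threshold (default 2.5, 26-connectivity, minimum component size 2
voxels). Each component is then segmented at the EANM-style relative
isocontour: 41% of the component's SUVmax, restricted to the connected piece
containing the hottest voxel. The seed stage replaces the manual region
placement of clinical workstations with a reproducible rule; the 41% stage
is the feature-defining operation. Two consequences worth knowing:

* Because the final threshold is *relative*, rescaling the whole volume
  (e.g. a dose or calibration change) leaves the segmented voxel sets
  unchanged; only the seed threshold is absolute.
* When 41% of SUVmax falls below the seed threshold the isocontour is
  allowed to grow beyond the seed component inside a dilated bounding box
  (5 voxels by default), so faint lesion rims are not clipped at 2.5.

Lesion volume is voxel count x voxel volume; centroids are intensity
weighted in physical mm (voxel centers at `(i - 0.5) * spacing`). On the
noise-free phantoms the segmentation recovers exactly the rasterized lesion
mask, so the only MTV error left is rasterization itself, below 5% for radii
of 5 mm and up at 1 mm voxels.

## SUV normalizations

SUV = tissue concentration / (injected activity / normalizer), with the
normalizer body weight (SUVbw), James lean body mass (SUVlbm) or Du Bois
body surface area (SUVbsa). The package uses the James 1976 equations for
LBM — the prevailing convention in the clinical era the pipeline targets —
and `BSA = 0.007184 x height^0.725 x weight^0.425`. For SUVbsa the display
convention expresses BSA in cm², which puts SUVbsa at roughly a quarter of
SUVbw for typical adults (an SUVbw of 10 pairs with an SUVbsa near 2.5, the
magnitude relation seen in published series); the raw m²-normalized value is
available via `bsa_scale = 1`. Decay correction is assumed already applied
to the injected activity, as scanner consoles report it.

## Dissemination

Dmax is the brute-force maximum over all unordered lesion pairs of the
Euclidean distance between lesion reference points, reported in cm. The
reference point is the intensity-weighted centroid by default (hottest-voxel
position as an alternative); the literature does not settle the choice, and
on the phantoms the two differ by less than a lesion radius. Dmax-bsa is the
plain quotient Dmax/BSA — the convention consistent with published mean
pairs (a mean Dmax of 54.6 cm and mean Dmax-bsa of 29.5 imply a typical
adult BSA of 1.85 m²). With fewer than two lesions Dmax degenerates to 0 and
is flagged rather than raising.

## Deauville and Lugano

The five-point rules: 1 = no residual uptake, 2 = residual at or below the
mediastinal blood pool, 3 = above mediastinum but at or below liver,
4 = moderately above liver, 5 = markedly above liver or new lesions. Two
genuinely open points were fixed as follows:

* *The 4/5 boundary.* "Moderately" vs "markedly" is qualitative; guidance
  ranges put the split at 2-3x liver uptake. The default multiplier is 2
  (the conservative end) and is configurable (`k_marked`).
* *Equality at the liver.* Some wordings assign "lower than liver" to score
  3, leaving equality ambiguous; standard Deauville semantics place uptake
  equal to the liver in score 3, and that is what the package does.

New lesions force score 5 and hence non-complete response even at low
residual intensity, the Lugano convention. Complete metabolic response is
Deauville 1-3 without new lesions.

## The survival chain

`km_estimate` is the product-limit estimator with the median defined as the
earliest event time where the curve reaches 0.5 (flagged "not reached"
otherwise — such groups are excluded from median tables). `logrank_test` is
the standard unweighted two-group statistic with hypergeometric variance.
`cox_fit` maximizes the partial likelihood by Newton-Raphson with
step-halving; Efron tie handling is the default and Breslow is available
(matching SPSS-era software defaults), Wald confidence intervals are
`exp(beta +- 1.96 se)`, and monotone likelihood (perfect separation) is
flagged instead of silently reporting an enormous coefficient. All three are
cross-checked in the test suite against the `survival` package to 1e-5 and
better on randomized datasets with ties.

ROC dichotomization evaluates every midpoint between consecutive sorted
unique feature values, classifies "positive" as strictly above the
threshold, and picks the threshold maximizing Youden's J (lowest threshold
on ties); the AUC is the trapezoidal area and agrees with `pROC` to machine
precision. The outcome used is the endpoint's *event indicator*, ignoring
censoring time — the simplest reading of ROC-based cutoff selection in
retrospective series; a caveat follows below. The univariate screen fits one
Cox model per covariate; covariates with univariate p < 0.05 enter the
multivariate model with no stepwise refinement. Significance is two-sided
0.05 throughout, without multiplicity correction, matching common practice
in the clinical literature this pipeline mirrors.

One methodological note: optimizing a cutoff on the same data that is then
tested inflates the type-I error of the *dichotomized* feature's test. The
package's null-calibration checks therefore split on fixed, pre-specified
cutoffs; users of `univariate_screen` on ROC-derived cutoffs inherit the
optimism that the original clinical workflow carries.

## The phantom generator

Phantoms are uniform backgrounds with non-overlapping ellipsoidal lesions of
uniform interior SUV, rasterized by the voxel-center rule, plus optional
additive Gaussian noise truncated at zero. Uniform ellipsoids were chosen
deliberately: the ground-truth volume is the analytic `4/3 pi r1 r2 r3` and
the centroid is the specified center, stored as such (never re-rasterized),
so segmentation accuracy is measured against exact values. Overlapping
lesions are rejected to keep the ground truth unambiguous. What the phantoms
do *not* emulate: scanner physics (scatter, partial volume, reconstruction
artifacts), physiologic uptake (brain, bladder, myocardium), or textured
lesions. Passing the phantom suite shows the geometry and bookkeeping are
right; it does not validate performance on clinical images, where seed
thresholds meet physiologic structures the package expects to be masked out.

## The cohort generator

The patient-level simulator draws, per patient: sex (75% male), age
(normal, mean 65.6, SD 10, truncated 30-89), sex-specific height and weight,
a lesion count `2 + Poisson(4)` (every patient has at least two lesions),
SUVbw max (log-normal, median 9, truncated 3.5-14.5), MTV (log-normal with
median 358 cm³ and sdlog 0.795, chosen so the mean is about 491 cm³,
truncated 2-4000), TLG as MTV x a SUVmean around 60% of SUVmax, and lesion
positions uniform in a 30 x 20 cm axial box whose cranio-caudal extent is
43% of height — with about six lesions this yields a mean Dmax near 55 cm
with a wide range, and Dmax-bsa near 29. Clinical covariates (stage, MIPI,
Ki-67, bulky disease, B symptoms, LDH, beta-2-microglobulin, splenomegaly,
blastoid morphology) are drawn at their published marginal frequencies.
These choices pin the *marginals* to published descriptive tables; the
joint law (e.g. MTV independent of Dmax given lesion count) is a modeling
choice the literature does not constrain, and is stated here once rather
than tuned.

Incomplete metabolic response occurs with probability
`plogis(-1.25 + 0.45 (age - 65.6)/10 + 1.0 ki67_high)` — about 30% overall,
increasing with age and Ki-67, the pattern seen in response-group
comparisons. Deauville scores are then drawn within the response class at
published frequencies.

Survival uses a Weibull proportional-hazards model: PFS hazard is raised by
high MTV (HR 2.7) and incomplete response (HR 3.5); OS hazard by high
Dmax-bsa (HR 1.75) — the effect pattern of multivariate prognostic tables
in advanced MCL. Baselines are shape 1.2 with PFS scale 80 months (median
about 59 months in the best group) and OS scale 130 months; censoring is
uniform between 12 months (an inclusion-criterion floor) and 150 months,
mimicking staggered accrual. Under the defaults a 120-patient cohort lands
near a median PFS of 27 months with roughly 30% incomplete response.

Two design points deserve emphasis:

* *PFS <= OS coupling.* The two endpoints share a single comonotone uniform
  draw, and the OS scale is constrained to
  `scale_os >= scale_pfs * exp(max(0, beta_os)/shape)`, which makes the OS
  quantile curve dominate the PFS curve for every covariate pattern. Both
  marginals remain *exact* proportional-hazards laws, so Cox regression
  recovers the generating hazard ratios with nominal confidence-interval
  coverage — an additive "progression then death" construction was rejected
  because it destroys the PH marginal for OS and biases any recovery check
  built on it. The price is perfect rank correlation between the latent
  endpoint times, which is stronger than biology; it matters only for
  analyses of the joint law, which the pipeline does not perform.
* *Four-group ordering.* With hazard ratios 2.7 (MTV) and 3.5 (response),
  proportional hazards implies the median-PFS ordering
  low-MTV/complete > high-MTV/complete > low-MTV/incomplete >
  high-MTV/incomplete. Clinical series have reported the two middle groups
  in the opposite order, which is not achievable under a no-interaction PH
  model with response the stronger effect; the package's ordering checks
  follow the hazard model it actually simulates.

## Numerical choices and degenerate inputs

Cox fitting centers covariates, guards the exponential against divergent
intermediate steps, halves steps when the partial likelihood decreases, and
stops on a relative log-likelihood change below 1e-10 (at most 50
iterations). Tied event times are grouped exactly, not jittered. Constant
covariates, empty groups, all-censored samples, single-class ROC outcomes,
single-voxel lesions and sub-two-lesion Dmax all have defined behavior
(error or flagged degenerate value) covered by tests. Problem sizes in the
test and acceptance runs — 200 null replicates at n = 200 and 100 recovery
replicates at n = 500 — were chosen as the smallest sizes at which
Monte-Carlo error is comfortably inside the calibration bands being
checked.

## Known limitations

* No physiologic-uptake modeling: on real scans the fixed seed threshold
  requires organ masks the package does not compute.
* ROC cutoffs use the event flag, not time-dependent ROC; with heavy or
  informative censoring the cutoff target drifts.
* The SUVbsa and LBM conventions are documented choices among several in
  field use; absolute SUVlbm/SUVbsa values are comparable only under the
  same conventions.
* The simulator's joint feature law is a stated invention; only its
  marginals and its hazard structure are anchored to published values.
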