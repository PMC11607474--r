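# petburden

Quantification of pretreatment FDG-PET tumor burden and dissemination in
lymphoma, and the prognostic analysis built on it — aimed at nuclear-medicine
and biostatistics researchers who want the full chain from voxels to hazard
ratios as tested, reproducible code rather than a manual workstation
workflow.

## What it computes

**Burden.** Hypermetabolic lesions are detected as 3-D connected components
above an SUV seed threshold and segmented at the EANM-style 41%-of-SUVmax
isocontour. Per patient:

- SUVmax under three normalizations: body weight (SUVbw), James lean body
  mass (SUVlbm), Du Bois body surface area (SUVbsa),
  with BSA = 0.007184 · height^0.725 · weight^0.425;
- MTV = Σ lesion volumes (cm³); TLG = Σ lesion volume × SUVmean.

**Dissemination.** Dmax = max over lesion pairs of the Euclidean distance
between intensity-weighted centroids (cm); Dmax-bsa = Dmax / BSA.

**Response.** Deauville five-point scoring of end-of-treatment scans against
mediastinal and liver references, collapsed to the Lugano binary response
(complete = Deauville 1–3, no new lesions).

**Prognosis.** ROC/Youden dichotomization of continuous features,
Kaplan–Meier product-limit curves with medians and horizon rates, two-group
log-rank tests, univariate and multivariate Cox proportional-hazards
regression (Newton–Raphson partial likelihood, Efron/Breslow ties, Wald
CIs), and the combined baseline-MTV × metabolic-response four-group
stratification of PFS.

**Generators.** Voxel-level PET phantoms (non-overlapping ellipsoids with
exact analytic ground truth) and patient-level synthetic cohorts under a
Weibull proportional-hazards model with coupled PFS ≤ OS endpoints, so every
stage is testable offline. See `vignettes/petburden-methods.Rmd` for the
models, conventions and their rationale.

## Worked example

```r
library(petburden)

sp <- phantom_spec(
  grid_shape = c(120, 120, 110), voxel_spacing_mm = c(1, 1, 1),
  background_suv = 0.5,
  lesions = list(
    list(center_mm = c(30, 30, 30), radii_mm = c(10, 10, 10), peak_suv = 9),
    list(center_mm = c(85, 40, 55), radii_mm = c(7, 7, 7),    peak_suv = 7),
    list(center_mm = c(45, 90, 85), radii_mm = c(12, 12, 12), peak_suv = 6)))
ph  <- generate_phantom(sp)
seg <- segment_lesions(ph$volume, min_voxels = 1)
seg
#> <lesion_set> 3 lesion(s), MTV 12.90 cm^3, TLG 91.57
d <- dmax(seg)
dmax_bsa(d$dmax_cm, du_bois_bsa(74, 175))
#> [1] 4.4  # Dmax 8.3 cm over a 1.89 m^2 adult
```

The three analytic lesion volumes sum to 12.86 cm³, so the segmented MTV of
12.90 cm³ is within 0.4%; the segmented Dmax matches the ground-truth
centroid geometry (8.3 cm) to a hundredth of a cm.

A simulated cohort through the full prognostic analysis:

```r
co  <- generate_cohort(cohort_sim_config(n_patients = 120, seed = 42))
res <- run_survival(co)
res$pfs$km
#> <km_curve> PFS: n=120, events=95, median 25.0 months
res$pfs$multivariate
#> <cox_fit> n=120, events=95, ties=efron, converged
#>             term                  hr            p
#>        mipi_high 2.014 (1.295-3.132) 1.896010e-03
#>  response_noncmr 2.625 (1.634-4.217) 6.587632e-05
#>     mtv_cm3_high 1.692 (1.092-2.622) 1.857299e-02
#>    dmax_bsa_high 1.574 (0.635-3.904) 3.278062e-01
round(res$combined$medians, 1)
#>     lowMTV_CMR  lowMTV_nonCMR    highMTV_CMR highMTV_nonCMR
#>           52.0           13.4           28.5           12.6
```

Incomplete metabolic response and high baseline MTV carry independent PFS
hazards (the cohort was generated with HRs 3.5 and 2.7), and the four
MTV × response groups separate median PFS from 52 down to 13 months. A thin
command-line front end with `simulate` / `quantify` / `survival` subcommands
lives at `inst/cli/petburden.R`.

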