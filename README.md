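# adipoquant

Automated quantification of abdominal adipose tissue on axial CT slices,
and phenome-wide association testing of the resulting measures against
electronic-health-record (EHR) outcomes.

Body composition — in particular the split between **visceral adipose
tissue (VAT)**, the fat around the organs, and **subcutaneous adipose
tissue (SAT)**, the fat under the skin — predicts metabolic and
cardiovascular risk better than BMI. Abdominal CT already acquired during
routine care contains this information; `adipoquant` extracts it
automatically and couples it to diagnosis codes and clinical labs for
association testing. It is aimed at imaging-informatics and genetic/clinical
epidemiology groups who want to phenotype adiposity from existing scans at
scale.

## The method

Segmentation is an unsupervised contour-minimization pipeline in four
stages:

1. **Preprocessing** — threshold the slice at −500 HU, remove thin
   material artifacts (scanner table, trays) by morphological opening,
   keep the largest connected component, and fill interior holes.
2. **Outer body contour** — trace the mask boundary with Moore-neighbor
   tracing (Jacob's stopping criterion), then refine it with a discrete
   *greedy snake*: each contour point moves, within a 3×3 window, to the
   position minimizing
   `E = α·Ê_cont + β·Ê_curv + γ·e_img + δ·Ê_pres`,
   where `E_cont = (d̄ − |v − v_prev|)²` (continuity),
   `E_curv = |v_prev − 2v + v_next|²` (curvature), `e_img` is a
   globally-normalized smoothed-gradient edge energy, and `E_pres` is an
   inward-pressure (balloon) term, disabled (δ = 0) for this stage.
3. **Abdominal cavity contour** — re-run the snake from the body contour
   inward with δ > 0, with the skin edge suppressed in the energy, so the
   contraction crosses the subcutaneous fat ring and stalls on the
   gradient ridge of the abdominal muscle wall.
4. **Adipose quantification** — classify every pixel in the Hounsfield
   window [−190, −30] as adipose; TAT is the fat inside the body contour,
   VAT the fat inside the cavity contour, SAT their difference, with the
   ratios VSR = VAT/SAT and VTR = VAT/TAT and the waist circumference
   (physical perimeter of the body contour).

Because no imaging or EHR data are distributable, the package ships two
seeded generators with exact ground truth: a **CT phantom** (elliptical
body, skin shell, subcutaneous fat ring, muscle wall, organ interior with
visceral fat blobs, optional table artifact, Gaussian HU noise) and a
**synthetic EHR cohort** (correlated lognormal VAT/SAT, diagnoses from
logistic models with chosen odds ratios, ICD-9-style visit counts, labs
with chosen slopes). All accuracy and calibration claims are measured
against these generators.

The association stage mirrors standard EHR PheWAS practice: cases need ≥3
visits for a 5-digit ICD-9 code, controls have 0 visits, 1–2 visits are
excluded, and codes with <50 cases are dropped; adipose exposures are
Box-Cox-normalized and standardized; logistic (diagnoses) and linear
(labs, after 2.5-SD outlier trimming) models adjust for age and sex, with
sex-stratified repeats adjusting for age; results carry Bonferroni
(`α/(n_outcomes × n_exposures)`) and Benjamini–Hochberg FDR annotations.

## Worked example

```r
library(adipoquant)

## segment a synthetic phantom and compare with its ground truth
ph  <- generate_phantom(phantom_params(seed = 42))
seg <- segment_slice(ph$ct)
seg$measures
#> <adipose_measures> phantom-seed42 @ 0
#>   TAT 239.80 cm^2 = VAT 60.68 + SAT 179.12; VSR 0.339, VTR 0.253; WC 84.9 cm
ph$truth$tat_area_cm2; ph$truth$vat_area_cm2; ph$truth$sat_area_cm2
#> 239.80; 59.64; 180.16
```

The estimated areas differ from truth by 0.0 % (TAT), 1.7 % (VAT), and
0.6 % (SAT) on this slice: the fat pixels are classified exactly and the
only error source is where the cavity contour settles within the muscle
wall.

```r
## associate adipose measures with synthetic EHR outcomes
gen <- generate_synth_ehr(2000, synth_effect_spec(), seed = 1)
res <- run_phewas(gen$adipose, gen$visits, gen$labs, gen$covars,
                  phewas_config(exposures = c("vat", "sat")))
head(res[res$stratum == "combined" & res$converged,
         c("exposure", "outcome", "model", "beta", "or_", "p_value")])
#>  exposure outcome    model    beta  or_  p_value
#>       vat     hdl   linear -0.0870   NA 3.62e-49
#>       vat    trig   linear  0.1566   NA 4.27e-48
#>       vat     wbc   linear  0.0637   NA 2.24e-28
#>       vat  250.00 logistic  0.7335 2.08 1.82e-26
```

The generator planted an odds ratio of 2.0 for VAT on code 250.00 and
slopes −0.075/+0.153 for VAT on HDL/triglycerides; the fitted effects
(OR 2.08, β −0.087/+0.157) recover them, and all four clear the
Bonferroni threshold.

A thin command-line wrapper (`inst/cli/adipoquant.R`) exposes the same
pipeline as `phantom`, `segment`, and `phewas` subcommands; every run
writes a JSON log of its fully resolved configuration.

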