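# tspovt

Quantification of second-generation TSPO PET radioligand binding and its
association with clinical covariates, with a synthetic-cohort generator that
makes every stage verifiable by parameter recovery.

TSPO (translocator protein 18-kDa) is over-expressed by activated microglia
and astrocytes, and TSPO PET is a standard in-vivo marker of
neuroinflammation. Quantifying it requires full arterial kinetic modelling:
there is no reference region. `tspovt` implements that chain for dynamic
[18F]-FEPPA-style acquisitions and the group-level inference that typically
follows, for imaging scientists who need a tested, reproducible pipeline or
a ground-truthed simulation environment for power and calibration studies.

## What it computes

1. **Arterial input function.** From dense automated whole-blood sampling
   (first 6 min, 1 Hz) plus seven manual arterial draws (2.5, 7, 15, 30, 60,
   90, 120 min): a mono-exponential whole-blood-to-plasma ratio model
   converts the early automated samples to plasma; a Hill function
   `PF(t) = 1 − (1 − p_inf) t^h / (t^h + t50^h)` models the unmetabolized
   parent fraction; the metabolite-corrected plasma curve is fitted by a
   straight line from zero to the peak followed by the sum of three
   exponentials (continuity enforced at the peak).
2. **Kinetics.** The two-tissue-compartment (2TC) model with impulse
   response `h(t) = φ1 e^{−θ1 t} + φ2 e^{−θ2 t}` convolved semi-analytically
   with the parametric input, a fixed 5% whole-blood vascular fraction, and
   frame averaging over the 20-frame acquisition scheme (1×120, 2×60, 3×120,
   6×300, 8×600 s). Weighted multi-start Levenberg–Marquardt fits yield the
   total distribution volume `V_T = (K1/k2)(1 + k3/k4)` per ROI with a
   delta-method standard error.
3. **Partial-volume correction.** Region-based geometric-transfer-matrix
   (GTM) correction: `G[i,j]` is the mean over region `i` of the
   PSF-smoothed indicator of region `j`; solving `G x = observed` recovers
   true regional means exactly on piecewise-constant images.
4. **Association statistics.** Per-ROI generalized linear models with a
   Gamma distribution and log link (V_T is positive and right-skewed),
   always adjusting for TSPO rs6971 genotype (high- vs mixed-affinity
   binders); coefficient t statistics are converted to effect sizes
   `d = 2t/√df`, `r = t/√(t²+df)`; Benjamini–Hochberg FDR is applied within
   each predictor family across the seven ROIs (six regions + whole brain).
5. **Synthetic cohort generator.** Covariates (PTSD symptom severity with
   four symptom-cluster subscales, months of site exposure, genotype, MCI
   status, six cognitive domains) and regional V_T drawn from the same
   Gamma/log-link model the analysis fits, with microparameters back-solved
   so stored V_T is exact; blood curves and frame-binned TACs generated from
   the forward models with controllable noise.

## Worked example

```r
library(tspovt)

# Simulate one subject's blood data and fit the input-function chain.
bt    <- default_blood_truth()
blood <- simulate_blood_data(bt$input, bt$hill, bt$ratio, noise_cv = 0.02, seed = 1)
chain <- fit_input_chain(blood, seed = 42)
unlist(chain$parent_fraction[c("p_inf", "h", "t50")])
#>      p_inf          h        t50
#>  0.2078419  2.0134266 19.7487959     (truth: 0.2, 2, 20)

# Simulate a 20-subject cohort, one subject's TACs, and fit the hippocampus.
cfg   <- simulation_config(n_subjects = 20, seed = 1)
sim   <- simulate_cohort(cfg)
truth <- subject_truth_from_cohort(sim$truth, "S001")
tacs  <- simulate_tacs(truth, blood, default_frame_scheme(), noise_cv = 0.05, seed = 2)
fit_2tc(tacs$hippocampus, chain$input, chain$wb_curve, seed = 42)
#> 2TC fit: K1=0.2947 k2=0.0884 k3=0.0364 k4=0.0142 (vB=0.05 fixed)
#>   V_T = 11.855 mL/cm^3 (SE 1.195), RSS = 94.36, converged: TRUE
# Ground-truth V_T for this subject/region: 11.799 (0.5% error at 5% TAC noise)

# Genotype-adjusted Gamma/log-link association of V_T with symptom severity.
vt  <- regional_vt_table(sim$truth$vt$subject_id, sim$truth$vt$region, sim$truth$vt$VT)
res <- run_regional_analysis(vt, sim$cohort, predictors = "pcl5_total")
res[, c("region", "B", "SE", "p", "p_fdr", "d", "r")]
#>        region     B     SE        p   p_fdr     d     r
#> 1     frontal 0.137 0.0473 0.010081 0.01176 1.404 0.575
#> 2    parietal 0.084 0.0425 0.064525 0.06453 0.959 0.432
#> 3    temporal 0.165 0.0376 0.000391 0.00274 2.134 0.730
#> 4   occipital 0.159 0.0494 0.005001 0.00875 1.563 0.616
#> 5   cingulate 0.156 0.0476 0.004419 0.00875 1.591 0.623
#> 6 hippocampus 0.165 0.0493 0.003763 0.00875 1.627 0.631
#> 7 whole_brain 0.161 0.0522 0.006790 0.00951 1.494 0.598
```

`B` is the log-V_T change per SD of the predictor (use `raw_units = TRUE`
for native units); `p_fdr` is the BH-adjusted p-value across the seven
regions. The generator applied the same severity effect (0.15 per SD) to
every region here, so all regions show comparable coefficients.

The whole chain — simulation, input-function fits, per-subject kinetic fits,
optional PVC, statistics, CSV/JSON outputs and a run manifest — is driven by
`run_pipeline(pipeline_config(...), out_dir)`, or from a shell via the thin
wrapper `inst/cli/tspovt.R` (subcommands `simulate`, `inputfn`, `kinfit`,
`pvc`, `stats`, `run`).

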