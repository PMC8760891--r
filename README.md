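# perfquant

Fully automated pixel-wise quantification of myocardial blood flow (MBF)
from dual-sequence first-pass contrast-enhanced cardiac MR perfusion series,
with the downstream diagnostic metrics used to detect significant coronary
artery disease.

## Who this is for

Researchers processing stress/rest first-pass perfusion studies — a
low-resolution arterial-input-function (AIF) series plus three myocardial
short-axis slices per heartbeat for ~60 beats and two proton-density (PD)
reference frames per slice — who want quantitative flow maps in ml/g/min and
segment-level diagnostic summaries without any manual contouring, and a
synthetic phantom with known ground truth to validate every stage.

## What it computes

The pipeline runs five fully automatic stages per condition:

1. **Surface-coil intensity correction** — the receive-coil gain field is
   estimated as the heavily smoothed mean PD image (normalized to mean 1 over
   the foreground) and divided out *before* registration, because the coil
   field is static in the scanner frame while the heart moves through it.
2. **Rigid motion correction** — per-frame in-plane translation maximizing
   normalized cross-correlation on difference-of-Gaussians images against an
   iteratively refined reference (median of mid-enhancement frames, then two
   re-averaging passes), applied with sub-pixel bilinear interpolation.
3. **ROI detection** — the LV blood pool on the AIF series is the
   high-amplitude connected component with the *later* arrival (the RV
   enhances first); the myocardium is the ring of moderately, later-enhancing
   pixels around the earliest-enhancing compact cavity.
4. **Timing detection** — contrast-arrival foot (baseline mean + 3 SD,
   sustained 2 frames), peak, and first-pass end on the AIF curve.
5. **Fermi-constrained deconvolution** — per pixel, the tissue curve
   c(t) is modeled as the convolution of the AIF with a Fermi residue

       h(t) = F / (1 + exp(k (t − τd − w))),  t ≥ τd   (0 before τd)

   fitted by bounded nonlinear least squares (amplitude profiled
   analytically, delay handled per inter-sample window), and

       MBF = h(τd) = F / (1 + exp(−k·w))   [ml/g/min]

Downstream, stress/rest maps give MPR (= stress MBF / rest MBF), an
18-segment model (3 slices × 6 transmural sectors) collapses into 9 coronary
territories by averaging adjacent segment pairs (LAD: anterior +
anteroseptal; RCA: inferior + inferoseptal; CX: anterolateral +
inferolateral), relative measures rMBF/rMPR ratio each territory to the most
hyperemic ("remote") one, and per-patient / per-vessel minima feed ROC
analysis with DeLong AUC comparisons, Youden-index operating points, and
McNemar tests (`evaluate_cohort()`).

## Worked example

Simulate a stress/rest study with an ischemic mid-ventricular RCA territory
(stress MBF 0.8 vs 3.0 ml/g/min elsewhere, rest 1.0 everywhere), with coil
shading, ±3-pixel breathing motion and curve SNR 20, then quantify it:

```r
library(perfquant)

spec <- phantom_spec(image_size = 64, aif_size = c(32, 24),
                     motion_max_px = 3, noise_snr = 20,
                     ischemia = list(slice = 2, sectors = c(3, 4),
                                     stress_mbf = 0.8))
ph  <- build_phantom(spec, seed = 101)
res <- run_study_pipeline(ph$study)

res$territories[, c("territory", "stress_mbf", "rest_mbf", "mpr", "rmbf", "rmpr")]
#>    territory stress_mbf rest_mbf   mpr  rmbf  rmpr
#> 1  basal-LAD      2.950     1.06 2.787 0.933 0.985
#> 2  basal-RCA      2.898     1.02 2.851 0.916 1.007
#> 3   basal-CX      2.941     1.02 2.876 0.930 1.016
#> 4    mid-LAD      3.163     1.13 2.830 1.000 1.000
#> 5    mid-RCA      0.941     1.11 0.858 0.298 0.303
#> 6     mid-CX      3.086     1.07 2.952 0.976 1.043
#> 7 apical-LAD      2.733     1.06 2.588 0.864 0.915
#> 8 apical-RCA      2.723     1.04 2.630 0.861 0.929
#> 9  apical-CX      2.672     1.09 2.464 0.845 0.870

round(res$summary$patient, 3)
#>   mbf   mpr  rmbf  rmpr
#> 0.941 0.858 0.298 0.303
```

The normal territories recover stress ≈ 3, rest ≈ 1 ml/g/min and MPR ≈ 2.8;
the ischemic mid-RCA territory stands out with stress MBF 0.94, MPR 0.86 and
rMBF 0.30 (truth: 0.8 / 0.8 / 0.27). The per-patient minima are exactly the
quantities a cohort-level ROC analysis of disease detection consumes.

Command-line equivalents (see `exec/perfquant`):

```sh
perfquant phantom --spec spec.json --seed 101 --out study/
perfquant run --study study/ --out results/ [--condition stress|rest|both]
perfquant stats --segments summaries.csv --truth labels.csv --out accuracy/
```

Studies are read from a self-describing archive directory (NIfTI arrays +
JSON manifest, bit-exact round trip) or from DICOM directories
(`read_study(..., dialect = "dicom")`); maps are written as lossless float
NIfTI and as CSV tables.

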