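---
title: "perfquant: models, assumptions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{perfquant: models, assumptions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the quantitative
model and its assumptions, the tunable parameters with their defaults and
units, what the synthetic phantom does and does not emulate, and the design
decisions taken where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## The quantification model

First-pass perfusion imaging acquires, every heartbeat, a low-resolution
arterial-input-function (AIF) image of the blood pool and three myocardial
short-axis slices, plus two proton-density (PD) frames per slice before the
contrast bolus. Under the indicator-dilution view of tissue enhancement, the
baseline-subtracted tissue signal is the convolution of the arterial input
with a tissue residue function whose initial height is the flow:

$$ c_\mathrm{tissue}(t) = \int_0^t c_\mathrm{AIF}(s)\, h(t-s)\, ds $$

`perfquant` constrains \(h\) to the Fermi (logistic-decay) family

$$ h(t) = \frac{F}{1 + e^{k (t - \tau_d - w)}} \;\; (t \ge \tau_d), \qquad
   h(t < \tau_d) = 0, $$

with amplitude \(F\), decay rate \(k\) (1/s), plateau width \(w\) (s) and
arrival delay \(\tau_d\) (s). Myocardial blood flow is read out as the
residue height at the delay,

$$ \mathrm{MBF} = h(\tau_d) = \frac{F}{1 + e^{-k w}} \;
   [\mathrm{ml\,g^{-1}\,min^{-1}}], $$

with a 60 s/min conversion inside the convolution so that \(F\) carries
ml/g/min directly. Because signal, not absolute concentration, enters on
both sides, MBF is invariant to any common rescaling of AIF and tissue
curves; only the *relative* amplitude matters. Two assumptions follow:

* **Signal–concentration linearity.** The low-flip-angle AIF readout and the
  myocardial readout are both treated as linear in gadolinium concentration
  with the *same* proportionality. No saturation correction is applied; this
  is the main fidelity limit relative to in-vivo acquisitions.
* **Additive Gaussian noise.** First-pass signals sit well above the noise
  floor, where magnitude-image Rician noise is effectively Gaussian.

### Identifiability of the delay, and how the fit handles it

With the hard causality cutoff \(h(t<\tau_d)=0\) and curves sampled once per
heartbeat, the least-squares objective is *exactly constant* along the ridge
\((\tau_d + \delta,\, w - \delta)\) as long as \(\tau_d\) stays inside one
inter-sample interval: the discrete convolution only evaluates \(h\) at
whole-beat offsets, so a sub-sample shift of the cutoff that keeps
\(\tau_d + w\) fixed changes no sample. Sub-sample delay is therefore
mathematically unidentifiable from beat-sampled data — no estimator can
recover it. Two consequences shape `fermi_deconvolve()`:

1. The objective is smooth in \((k, w, \tau_d)\) *within* each inter-sample
   delay window but discontinuous across sample times (a naive quasi-Newton
   or simplex search stalls on the jumps). The fit therefore scans a
   \((k, w)\) grid at each candidate delay window around the AIF-to-tissue
   foot-delay estimate, refines the best two windows by bounded L-BFGS-B
   with the amplitude profiled analytically (the model is linear in \(F\)),
   and fits the lower delay bound explicitly (its window lies outside the
   parameter box and is otherwise unreachable).
2. The fitted delay is reported at the *top* of its flat interval — delays
   in whole samples. When the true delay lies on the beat grid (the
   phantom's stated world, with transit delays of whole heartbeats), MBF is
   recovered exactly at zero noise; for off-grid delays the readout may move
   by up to one beat along the ridge, a limitation inherited from the
   sampling, not the optimizer.

Defaults: bounds \(F \in [0,10]\) ml/g/min, \(k \in (0,5]\) 1/s,
\(w \in [0,30]\) s, \(\tau_d \in [0,10]\) s; a 3×3 \((k, w)\) scan grid
\(k \in \{0.2, 0.8, 2.0\}\), \(w \in \{1, 4, 10\}\). Failed fits are flagged
and carried as `NA` — never clamped — so they remain auditable in the
segment table.

### Curve preparation

The AIF curve's timing points define a common analysis window: baseline =
first 4 frames (configurable; must precede the contrast foot or the run
errors out), foot = last frame before the signal first exceeds baseline
mean + 3 SD sustained for 2 frames (the sustained requirement suppresses
single-frame noise triggers; no threshold is standard, this one is fixed
here), peak = maximum after the foot, end = first local minimum after the
peak on a lightly smoothed curve, else the 50%-of-peak crossing, else the
series end. All curves are baseline-subtracted, cropped to
[foot − 2 frames, end], and linearly resampled to a uniform grid at the
nominal RR interval. All timing logic is invariant to affine intensity
rescaling.

## Preprocessing

**Correction order.** Coil-intensity correction runs *before* motion
correction. The receive field is static in the scanner frame while the
heart moves through it; dividing already-registered frames by a static
field imprints a per-frame multiplicative error of order
\(|\text{shift}| \times \nabla B / B\) — a few percent per frame at 3-pixel
motion and realistic field gradients, which is coherent across a slice and
biases MBF substantially. The two operations commute only in the limit of a
flat field, which the test suite checks on a gentle-gradient phantom.

**Bias field.** The field is the heavily Gaussian-smoothed mean PD image
(default sigma: 1/16 of the image's smaller dimension), normalized to mean
1 over a robust foreground (intensity at or above the 5th percentile), and
clipped positive. An infinite smoothing scale yields exactly 1 — the no-op
limit. PD frames with anatomic structure bias the estimate toward that
structure; the phantom's PD is anatomically flat, so a green test
establishes recovery of the *field*, not robustness to PD anatomy.

**Motion correction.** Translation-only by design: the in-plane breathing
component dominates at this scale and a deformable stage is out of scope.
Shifts are estimated by normalized cross-correlation on
difference-of-Gaussians images (sigma 1 / 6 pixels) — raw-intensity NCC is
dominated by the smooth coil shading and by global enhancement changes and
localizes poorly. The initial reference is the temporal median of
mid-enhancement frames (middle tertile of the series-mean curve, so
pre-contrast and noisy frames do not dominate); two refinement passes
re-average the registered frames. Three conventions matter:

* **Gauge fixing.** A reference built from the data has no absolute
  position, so the trace is centered to zero median displacement; the
  phantom's motion schedule is median-centered for the same reason.
* **Deadband.** Corrections below 0.25 px are zeroed and those frames are
  passed through without resampling. The estimator's enhancement-coupled
  jitter floor sits near 0.2 px; resampling by such sub-jitter shifts costs
  more (baseline errors at strong static edges) than it corrects.
* **Interpolation.** Bilinear, edge-clamped. Its smoothing is what bounds
  the idempotence tolerance (re-running on corrected output moves frames by
  well under half a pixel) and it sets the intrinsic partial-volume floor
  of map accuracy at moving acquisitions.

Featureless (blank) frames make the metric undefined; they fall back to
zero shift and are flagged in the trace.

## Detection and the segment model

The LV blood pool on the AIF series is found from per-pixel enhancement
features (peak amplitude, upslope, arrival); among the two largest
candidate components the LV is the one with the **later** arrival, since
the right ventricle enhances first. With a single candidate the package
warns and proceeds — the documented failure mode when only one chamber is
in view. The curve is the frame-wise mean over a 1-pixel-eroded mask.

The myocardium is detected as the ring of moderately, later-enhancing
pixels around the earliest large-enhancement compact region (the cavity),
closed morphologically, required to surround the cavity with near-complete
angular coverage. All thresholds are relative (quantiles and ratios of the
data), so detection is invariant to a global intensity scale.

Sectorization divides the mask into six equal 60° bins counterclockwise
from the anterior reference angle (straight up in standard short-axis
orientation; the convention is a package choice — automatic RV-insertion
detection is out of scope, and segment naming depends on it). Sector names
anterior, anteroseptal, inferoseptal, inferior, inferolateral,
anterolateral map to coronary territories LAD (anterior + anteroseptal),
RCA (inferior + inferoseptal) and CX (anterolateral + inferolateral) at
every slice level; averaging each adjacent pair gives 9 territories per
patient. Segment statistics exclude a 1-pixel rim of the mask as a
partial-volume guard. The relative measures rMBF and rMPR ratio each
territory to the *reference* territory, chosen as the one with maximal
stress MBF (the most normal hyperemic flow — a definitional choice; a
normality criterion other than the maximum would need clinical priors the
package does not have). Patient- and vessel-level summaries take minima
over territory values, including min over territory MPR (rather than
re-ratioing minima), because disease is expected to depress the local
reserve.

## Statistics

ROC AUC is the Mann–Whitney concordance (ties at half credit) with the
DeLong structural-components standard error; paired AUCs are compared with
the DeLong test. Operating thresholds are candidates at midpoints between
adjacent sorted unique values; the Youden index \(J = \text{sens} +
\text{spec} - 1\) is maximized with ties broken toward the smaller
\(|\text{sens} - \text{spec}|\) (the balance criterion) and then toward
higher specificity. All four perfusion metrics are treated as
lower-is-positive for disease — direction is always explicit, never
inferred from data. Group comparisons use the rank-sum test (exact for
\(\min(n_1, n_2) \le 8\) without ties, normal approximation with tie and
continuity corrections otherwise); paired sensitivity/specificity
comparisons use McNemar's test (exact binomial below 25 discordant pairs,
continuity-corrected \(\chi^2\) above; \(p = 1\) by convention with no
discordant pairs). Agreement between paired quantifications uses Pearson
correlation and Bland–Altman bias with 1.96 SD limits; with zero-variance
differences the bias p-value is 1 for zero bias and 0 otherwise, by
convention.

## The phantom's stated world

The generator (`phantom_spec()` / `build_phantom()`) emulates the
dual-sequence acquisition with these defaults, chosen once:

| quantity | default | why |
|---|---|---|
| frames / RR | 60 / 1.0 s | one sample per beat over a first pass |
| myocardial matrix | 128×128 (tests: 64×64) | rendered matrix; tests follow the end-to-end budget |
| AIF matrix | 64×48 (tests: 32×24) | low-resolution blood-pool readout |
| annulus radii | epi = size/4, endo = 0.156·size | mid-ventricular wall ≈ 10 mm at ~2.8 mm/px |
| slice taper | epi radius × (1, 0.88, 0.75), constant wall thickness | the ventricle tapers; the wall does not thin proportionally |
| normal MBF | stress 3.0 / rest 1.0 ml/g/min | healthy hyperemic and resting flow |
| painted residue | k = 0.8 /s, w = 3 s, τd = 1 s | plateau of a few seconds, delay of one beat |
| AIF bolus | gamma-variate, α = 2.5, β = 1.5 s (stress), t0 = 8 s; recirculation 15% at +12 s | arterial first pass with a second pass |
| signal levels | background 70, myocardium 100, blood 110, gain 400, PD 300 | static anatomic contrast exists pre-contrast (without it, registration would be physically impossible) |
| shading | quadratic polynomial, range ≈ ±25%, mean 1 | smooth surface-coil falloff |
| motion | median-centered sinusoidal drift + jitter, clipped to ±max | breathing around a neutral position |
| noise | per-condition SD = that condition's normal tissue peak / SNR (default SNR 20) | "curve SNR" means the curve being fitted |

Ground truth (per-pixel MBF maps, sector labels, shading field, per-frame
translations, noise-free AIF) is returned alongside the study, and all
randomness flows through the single seed.

**What the phantom does not emulate** — and hence what a green test does
*not* establish: SSFP saturation nonlinearity and dark-rim artifacts,
through-plane and deformable motion, Rician noise statistics, arrhythmic
beat-to-beat timing jitter, PD frames with anatomic structure, and any
difference in signal-to-concentration gain between the AIF and myocardial
readouts. Passing tests establish correctness of the algorithms under the
model's assumptions, not clinical accuracy.

## Numerical choices and degenerate inputs

* Convolution: FFT-based discrete causal convolution, rectangle rule, on
  the acquisition grid.
* Fermi fit convergence: L-BFGS-B, maxit 60 per start; profiled amplitude
  clipped to its bounds; residual RMS reported per fit.
* Zero tissue signal fits to MBF 0 (the profiled amplitude floors at 0);
  all-zero PD frames, flat signal curves, single-class ROC labels,
  empty groups and empty sectors raise structured errors or flagged `NaN`s
  (empty sector: `NaN` + warning), never silent numbers.
* NCC ties (featureless or noise-free regions) break toward zero shift via
  an infinitesimal centered prior; sub-deadband corrections skip resampling
  entirely, so a motionless series round-trips bit-exactly.
* Maps are written as float64 NIfTI so that write/read round trips are
  bit-identical; the DICOM dialect quantizes to 16-bit with per-series
  slope/intercept and is lossless exactly for integer-valued studies.

## Known limitations

* Sub-sample arrival delays are unidentifiable at beat sampling (see
  above); MBF from off-grid delays can shift by up to the per-beat logistic
  factor along the delay ridge.
* At 64×64 with several-pixel motion, bilinear resampling sets a
  partial-volume floor of a few percent on thin-wall sector statistics even
  with perfect registration.
* The remote-territory reference (argmax stress MBF) makes rMBF/rMPR
  undefined in globally ischemic (balanced three-vessel) phantoms — the
  reference itself is then diseased.
* Thresholds chosen by the Youden index on a cohort are optimistic for that
  same cohort; the package computes them but does not cross-validate.
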