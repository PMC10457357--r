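---
title: "Quantifying in vivo glucose uptake from dynamic FDG-PET: methods and design"
author: "PatlakPET authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in vivo glucose uptake from dynamic FDG-PET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PatlakPET)
```

# The measurement problem

[18F]-fluorodeoxyglucose (FDG) is a glucose analog that is transported
into tissue and phosphorylated like glucose, but the phosphorylated
form is not metabolised further and accumulates. Over the duration of a
scan the tracer is therefore effectively *irreversibly* trapped, and
the rate of trapping reports the tissue's glucose uptake. A dynamic
scan — many short frames early, longer frames late — records the
tissue concentration $C_t(t)$ in every voxel, and a vascular region
supplies the blood concentration $C_p(t)$ (the image-derived input
function, IDIF) without arterial sampling.

This package quantifies small-animal skeletal-muscle and myocardial
glucose uptake from such scans, together with the fasting-state
metabolic indices (HOMA-IR, HOMA-$\beta$, longitudinal AUCs) and
plate-respirometry parameters that accompany this kind of metabolic
study. A synthetic-data module generates every input with known ground
truth, so each stage is validated by parameter recovery rather than by
eyeballing.

# The kinetic model and Patlak analysis

The irreversible two-tissue compartment model has a free (exchangeable)
pool $C_1$ and a trapped pool $C_2$:

$$
C_1' = K_1 C_p - (k_2 + k_3)\, C_1, \qquad
C_2' = k_3\, C_1,
$$

with total voxel signal
$C_t = (1 - V_b)(C_1 + C_2) + V_b C_p$, where $V_b$ is the fractional
blood volume. $K_1$ (mL plasma per mL tissue per min) is transport in,
$k_2$ (1/min) transport out, $k_3$ (1/min) phosphorylation; $k_4 = 0$
expresses trapping.

The Patlak transformation plots

$$
y(t) = \frac{C_t(t)}{C_p(t)} \quad\text{against}\quad
x(t) = \frac{\int_0^t C_p\,d\tau}{C_p(t)},
$$

which for an irreversible tracer becomes linear once the exchangeable
pool has equilibrated, with slope equal to the net influx rate

$$
K_i = \frac{K_1 k_3}{k_2 + k_3}.
$$

`patlakTransform()` evaluates the coordinates at frame mid-times;
`fitPatlak()` runs unweighted ordinary least squares on the points
whose mid-times fall in the closed window 16–40 min (7 of the 24
frames of the default schedule). Both conventions — mid-times, and
unweighted OLS — are deliberate simple defaults; neither is forced by
the mathematics, and both are stated here because alternatives
(frame-end times, inverse-variance weights) exist in the field.

**Blood-volume effect.** The $V_b C_p$ term divided by $C_p$ is a
constant: it moves the Patlak *intercept*, not the slope — except that
the tissue terms are scaled by $(1 - V_b)$. The slope recovered from a
voxel is therefore exactly $(1 - V_b) K_i$. `phantomGroundTruth()`
reports both $K_i$ and this recoverable slope (`true_slope`), and all
recovery claims are stated against `true_slope`. No blood-volume
correction is applied to measured data, mirroring common practice at
this scan length.

**Validity window.** The Patlak plot is only asymptotically linear; the
transient decays as $e^{-(k_2+k_3)t}$. Numerical experiment with this
package's own simulator shows that with the fit window starting at
16 min, parameter sets with $k_2 + k_3 < 0.15\ \mathrm{min^{-1}}$
carry a transient slope bias of several percent to >10% that no
implementation can remove — the method, not the code, is out of its
regime. The package's recovery grid therefore spans
$K_1 \in [0.05, 0.3]$, $k_2 \in [0.1, 0.5]$,
$k_3 \in [0.02, 0.15]$ but requires
$k_2 + k_3 \ge 0.15\ \mathrm{min^{-1}}$ (equivalently
$(k_2+k_3)\,t_{start} \gtrsim 2.4$); inside that regime the worst-case
recovery error is below 1%.

# From Ki to a metabolic rate

Trapping competes with a saturable transport/phosphorylation system,
so the *saturation-corrected maximal* metabolic rate of glucose is

$$
MR_{glu}^{max} = K_i\,(K_m + C_{glu}),
$$

with Michaelis–Menten constant $K_m = 130$ mg/dL by default and
$C_{glu}$ the arithmetic mean of the blood glucose samples taken
during the scan (the protocol samples at 10, 20 and 40 min;
1 mmol/L = 18.016 mg/dL). With $K_i$ in mL/mL/min and concentrations
in mg/dL the rate is in mg per 100 mL tissue per min. The formula is
implemented exactly as stated: no lumped constant is applied and no
parameter for one is exposed, so `mrglu(x)/ki(x) - cglu` recovers
$K_m$ identically. All internal glucose concentrations are mg/dL
($K_m$'s unit); glucometer values in mmol/L are converted at the I/O
boundary.

# Region construction

Three ROI rules are implemented, matching the anatomy of this kind of
study:

* **Muscle**: digital cylinders, 10 voxels in diameter and 10 slices
  long (`cylinderROI()`). A voxel belongs to the disc when its center
  is *strictly* inside the radius — deterministic and checkable by
  brute-force enumeration. Voxel indices are 1-based, following R.
* **Myocardium**: within a search volume, voxels whose last-frame
  activity is at least 40% of the search maximum
  (`thresholdROILastFrame()`). The comparison is inclusive ("at
  40%"). Late in the scan trapped myocardium is hot and blood has
  cleared, so the rule isolates the wall.
* **Vena cava** (input function): within a search volume, voxels
  strictly above 60% of the maximum in the *first frame with uptake*
  (`venaCavaROI()`; "above 60%" is read as strict). "First frame
  with uptake" is not defined by the protocol wording; here it is the
  first frame whose within-search maximum exceeds 5% of the global
  within-search maximum, a configurable choice that is robust to
  pre-arrival noise. Whether the rule should search the whole field
  of view is equally unstated; this implementation requires an
  explicit search volume and documents that as an interpretation. An
  interactive "manually delineated search volume" is replaced by an
  explicit mask or box argument (`boxMask()`) — a library has no
  interactive step.

Region curves are unweighted voxel means (`extractTAC()`) — the
simplest defensible reading. The IDIF is used directly as the plasma
input, with no whole-blood/plasma or metabolite correction, a known
simplification at this scan length.

# Numerical choices

* **Kinetic simulation** (`simulateTissue()`): the system is linear,
  so instead of a generic ODE solver the impulse response is convolved
  analytically with a piecewise-linear interpolant of $C_p$ on a
  0.5 s grid (recursive exact update per step). Against an adaptive
  ODE solver the curves agree to ~$10^{-5}$ relative.
* **Cumulative input integral** (`cumulativeInputIntegral()`):
  duration-weighted frame sums — every completed frame contributes
  `activity × duration`, the current frame half of its own. Because
  frame values are time-averages, the completed-frame part is exact
  for frame-averaged curves, and a constant input integrates to
  exactly $c\,t$. Near the bolus peak no frame-grid rule can resolve
  the curvature (the peak sits inside the first 30 s frame) and
  early-frame relative errors reach tens of percent; this affects the
  Patlak intercept, not the windowed slope — within the 16–40 min
  window the per-frame increments agree with the closed form to
  <0.5% and the full-schedule integral to <0.5%.
* **Degenerate inputs**: frames with input activity below
  $10^{-3} \times \max C_p$ are excluded with a reason code rather
  than producing unstable ratios; voxels with no activity in the fit
  window get an `NA` sentinel and a quality code in parametric maps.
  Negative slopes are reported as-is with a flag — filtering is the
  caller's decision, and no $r^2$ threshold is applied by default.
* **Flat ordinates** give slope 0, flag `"flat"`, and undefined
  $r^2$.

# The synthetic-data module

The generators exist so that every pipeline stage has a ground truth.

* **Plasma model**: a sum of rise-and-decay exponential pairs
  $\sum_j A_j (e^{-\lambda_j t} - e^{-\mu t})$ — zero at injection,
  single bolus peak, monotone decay, and a closed-form running
  integral that serves as an exact oracle. Defaults
  ($A = 350, 80$ kBq/mL, $\lambda = 0.9, 0.008$ /min, $\mu = 5$ /min)
  give a mouse-like bolus: a sharp peak of a few hundred kBq/mL near
  0.4 min and a slow tail of tens of kBq/mL at 40 min. Real
  acquisitions derive the input from the image, so this parametric
  form is a simulator choice, not a claim about measured blood curves.
* **Phantom** (`phantomSpec()`, `buildPhantom()`): 64 × 64 × 32
  voxels at 0.4 mm isotropic (a typical preclinical reconstruction voxel size)
  containing two muscle cylinders
  ($K_1{=}0.1, k_2{=}0.25, k_3{=}0.05, V_b{=}0.03$, $K_i = 0.0167$),
  a myocardial shell around a blood-pool interior
  ($K_1{=}0.3, k_2{=}0.6, k_3{=}0.15, V_b{=}0.10$, $K_i = 0.06$) —
  muscle-to-heart contrast in the physiological direction — and a
  vena-cava tube; blood classes carry the frame-averaged plasma
  curve, the background is zero.
* **Noise law** (`addNoise()`): additive zero-mean Gaussian with
  $\mathrm{sd} = s\sqrt{\max(a, a_{floor})/\Delta}$ per frame
  (activity $a$, duration $\Delta$ in min) — the first-order
  count-statistics approximation: shorter frames are noisier. The
  default scale $s = 1$ yields ~5–8% relative noise on late 5-min
  muscle frames, typical of small preclinical ROIs. Results are
  clipped at zero.
* **Cohort** (`simulateCohort()`): three arms over weeks 0–9 with
  piecewise-linear means — control flat (7 mmol/L glucose,
  15 µU/mL insulin), untreated diabetic rising to 28 mmol/L as
  insulin falls to 4 µU/mL, treated re-normalising to 9 mmol/L —
  and mean-one multiplicative lognormal noise (CV 8%).
* **Mito-stress plates** (`simulateMitoPlate()`): four phases in
  fixed order (3 baseline measurements, then oligomycin, FCCP,
  rotenone + antimycin), plateau means per phase, Gaussian noise,
  5 wells per condition. The `"uncoupled"` preset raises the
  post-oligomycin plateau (70 vs 40 pmol O2/min over a background of
  10) — the proton-leak signature of a chemical uncoupler — and a
  higher basal OCR/ECAR ratio.

What the generators do *not* emulate: scatter, attenuation,
reconstruction physics, partial-volume blur beyond voxelisation,
motion, plasma metabolites, or inter-animal kinetic variability.
Passing recovery tests therefore demonstrates correctness of the
quantification chain, not robustness to every artefact of real data.

# Respirometry parameters

From per-well phase summaries (vendor conventions: last baseline,
minimum under oligomycin, maximum under FCCP, minimum under
rotenone + antimycin — each rule configurable, since instrument
software does not publish its exact statistic):
non-mitochondrial respiration = rot/AA summary; basal = baseline −
non-mito; proton leak = oligomycin − non-mito; ATP-linked = basal −
leak; maximal = FCCP − non-mito; spare capacity = maximal − basal;
coupling efficiency = ATP-linked / basal. The conservation identities
(basal = ATP-linked + leak; spare = maximal − basal) hold by
construction. The oxidative-preference ratio is OCR/ECAR at the last
baseline measurement. Wells are computed first, then condition means
± SEM; no protein/cell-count normalisation is applied.

# HOMA indices and AUC

$\mathrm{HOMA\text{-}IR} = \frac{G \cdot I}{22.5}$ and
$\mathrm{HOMA\text{-}\beta} = \frac{20\,I}{G - 3.5}$ with $G$ in
mmol/L and $I$ in µU/mL. At $G \le 3.5$ the β-index denominator
leaves the model's range; the package returns a typed `NA` rather
than an infinity or an error. Insulin measured by ELISA in ng/mL is
converted at a configurable 25 µU/mL per ng/mL — published factors
vary and no single value is canonical. Longitudinal summaries use the
plain composite trapezoid rule over observed times with no baseline
subtraction.

# Problem sizes and reproducibility

The validation suites use: a 24-parameter-set noise-free recovery
grid; 200 noisy replicates for the stochastic suite; the full
64 × 64 × 32 phantom for voxel maps; 1000 randomized traces for the
respirometry identities. All generators take explicit seeds and are
bit-reproducible; seeded calls restore the session RNG state.
`runPipeline()` records derived thresholds, a config hash and stage
timings in its manifest.

# Known limitations

* No motion/registration handling, no partial-volume or spill-over
  correction for the IDIF (a recognised simplification of vena-cava
  input functions), no metabolite correction.
* Patlak only: no full nonlinear compartment fitting, no
  reversible-tracer ($k_4 > 0$) extension.
* Group statistics (ANOVA and post hoc families) are out of scope;
  the package stops at per-subject/per-region quantities.
* The Michaelis–Menten form of $MR_{glu}^{max}$ is used exactly as
  stated, without a lumped constant; absolute rates are therefore
  comparable within this convention only.

# A worked example

```{r example, eval = FALSE}
bundle <- runPipeline(loadConfig(), phantom = phantomSpec(),
                      glucose = c(10, 11, 12))
bundle$fits$muscle
bundle$mrglu$muscle
phantomGroundTruth(phantomSpec())
```
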