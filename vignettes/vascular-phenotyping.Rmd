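---
title: "Quantitative vascular phenotyping of tumor xenografts: methods and design"
author: "xenovasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative vascular phenotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenovasc)
```

# Scope

Anti-angiogenic treatment response in tumor xenografts is read out across
four complementary modalities: in vivo dynamic contrast-enhanced MRI
(perfusion), ex vivo micro-CT angiography of contrast-perfused specimens
(vascular morphology), double-stained histological sections (endothelial
proliferation and pericyte coverage), and HR MAS MR spectroscopy of intact
tumor tissue (choline metabolism). `xenovasc` implements the complete
quantitative chain for all four, a nonparametric group-comparison layer, and
synthetic phantom generators that produce data with exact ground truth for
every stage. Raw animal imaging data of the kind this chain targets are
rarely deposited; the generators are therefore first-class citizens — every
claim the test suite makes about the analysis code is backed by a phantom
whose true answer is known by construction.

# Perfusion metrics (DCE-MRI)

A dynamic series is a 4D signal array with a frame interval (default 4.8 s)
and a count of pre-injection baseline frames (default 10). Per voxel:

* `S0` — mean over all baseline frames. Averaging all baseline frames rather
  than using the last one suppresses noise in the denominator of every
  derived quantity. Voxels with non-positive `S0` are flagged invalid and
  leave the ROI.
* `RSI(t) = S(t)/S0` — relative signal intensity. `RSI_1min` is read at the
  acquired frame nearest 60 s post-injection, with no interpolation. At a
  4.8 s interval, 60 s is exactly between post-injection frames 12 (57.6 s)
  and 13 (62.4 s); the tie resolves to the later frame. Reading an acquired
  frame keeps the quantity an observation rather than a model value.
* `AUC_1min` — trapezoidal integral of the relative enhancement
  `(S(t) - S0)/S0` from the injection (anchored at the last baseline frame,
  enhancement ~0) to 60 s. When 60 s is not an acquired time, the final
  partial trapezoid uses the linear interpolant between the two bracketing
  frames — the trapezoid rule's own behaviour, so a step enhancement of
  amplitude 1 integrates to exactly 57.6 relative-enhancement seconds
  (`0.5*4.8 + 11*4.8 + 2.4`), the value the unit tests pin.
* Enhancing voxels: `RSI_1min >= 1.5` within the ROI. The boundary voxel at
  exactly 1.5 is enhancing; 1.4 is not. The fraction of enhancing voxels
  (FEV) is the enhancing count over the ROI count.

The tumor-wise `AUC_1min` summary is the median over *enhancing* voxels
only, so that non-perfused tumor core does not dilute the perfusion signal;
`summarizeTumor(aucOverRoi = TRUE)` switches to the all-ROI alternative for
sensitivity analyses. Longitudinal change is the plain difference of
consecutive-day summaries per tumor.

AUC is defined on relative enhancement rather than raw signal, which makes
it invariant under global scanner gain (asserted as a property test).
Pharmacokinetic modelling (Tofts parameters, AIF estimation, T1 mapping) is
deliberately out of scope.

# Micro-CT vascular morphometry

Volumes are isotropic (9 um by default); anisotropic voxels are rejected
rather than resampled.

**Vesselness.** Bright tubular structures are enhanced with a Frangi-type
three-eigenvalue tubularity measure computed from a Gaussian-derivative
Hessian (second-moment-normalized, gamma = 2) at scales {9, 18, 36, 72} um,
taking the voxel-wise maximum over scales and rescaling to [0, 1]. With
eigenvalues `|l1| <= |l2| <= |l3|`,

$$V = \left(1 - e^{-R_A^2/2\alpha^2}\right)\, e^{-R_B^2/2\beta^2}\,
      \left(1 - e^{-S^2/2c^2}\right),\qquad
R_A = \tfrac{|l_2|}{|l_3|},\;
R_B = \tfrac{|l_1|}{\sqrt{|l_2 l_3|}},\;
S = \lVert(l_1,l_2,l_3)\rVert,$$

zeroed where `l2 >= 0` or `l3 >= 0` (bright tubes need both cross-sectional
curvatures negative); `alpha = beta = 0.5` and `c` is half the maximal `S`
per scale. The second-derivative kernels are mean-subtracted so a constant
volume yields an exactly zero response.

**Segmentation.** The threshold is determined by Otsu's method on the
vesselness values inside the tumor mask, extended by hysteresis: voxels
above 0.35 x the Otsu threshold are kept when 26-connected to a voxel above
the full threshold, and components smaller than 27 voxels are removed. The
hysteresis step is a deliberate design choice: the tubularity response
tapers toward a tube's surface, so a single hard cut retains only vessel
cores (about 64% of true vessel voxels on noise-free tree phantoms) and
systematically underestimates vessel volume and caliber; the connected low
cut restores the full caliber while the connectivity requirement keeps
isolated background out. Setting `hysteresisLow = 1` recovers the plain
hard threshold. Conversely, Gaussian smoothing spreads the response about
one voxel *beyond* the tube surface, and for thin tubes that dim halo can
inflate vessel volume by tens of percent; since contrast-cast vessels are
bright by construction, the mask is finally gated on image intensity (Otsu
over tumor voxels, `intensityGate = TRUE` by default, to be disabled for
volumes where vessels are not reliably bright). With both refinements the
segmentation-chain FBV error on noise-free tree phantoms is 4-6% across
vessel volume fractions of 0.03-0.06.

**Metrics.**

* FBV — vessel voxels within the tumor mask over tumor voxels.
* Vessel caliber (VC) — per-voxel local thickness: twice the radius of the
  largest sphere fully inscribed in the vessel mask that covers the voxel
  (the standard largest-inscribed-sphere definition; volume border counts
  as background, spheres are open balls). Summaries: the 90th percentile
  (linear interpolation between order statistics, pinned so tests are
  exact) and the fraction of vessel voxels with VC *strictly* greater than
  150 um. Histograms are per-voxel distributions normalized to unit sum.
* Distance to nearest vessel (DNV) — exact Euclidean distance transform of
  the non-vessel tumor voxels to the nearest vessel voxel, scaled to um.
  Summaries (median, 90th percentile, fraction beyond 200 um — the upper
  bound of the oxygen diffusion distance) are taken over non-vessel tumor
  voxels only, since vessel voxels carry distance 0 by definition.

The distance transform (Felzenszwalb–Huttenlocher, exact), local thickness
(sphere-painting over the distance-to-background map) and connected-component
labelling are implemented in C++ and are pinned against brute-force R
oracles — exhaustive nearest-neighbour search and explicit sphere fitting —
with exact equality on random masks up to 32^3. One subtlety the oracle
tests surfaced: sphere containment must be evaluated in exact squared-integer
arithmetic, because squaring a floating-point radius re-admits voxels lying
exactly on the open-ball boundary.

# Histology quantification

Fields are 8-bit RGB with a known pixel size. Stains are segmented in HSV
space by fixed hue/saturation(/value) bands — one band set for an entire
study run, recorded in the result object. Defaults: lectin (blue)
hue 0.52–0.75, Ki67 (brown) hue 0.03–0.14, alpha-SMA (brick red)
hue 0.86–0.995, each with saturation above ~0.3 so the white background
never classifies.

Touching proliferating nuclei are separated by watershed on the interior
Euclidean distance map, with markers the regional maxima detected within a
neighbourhood of a quarter of the expected nucleus diameter (default 8 um)
and a merge tolerance of 0.5 px of distance-map depth. That tolerance
separates disk pairs down to centre separations of 0.6 diameters without
splitting single round nuclei.

A proliferating endothelial cell (PEC) is a nucleus whose centroid falls
within a vessel. "Within a vessel" uses the lectin mask with interior holes
filled: a nucleus enclosed by a vessel profile displaces the lectin stain
at its own pixels, so the unfilled mask would never contain a nucleus
centroid. A >= 50% pixel-overlap alternative is available
(`criterion = "overlap"`). PEC density is reported per mm^2 of (unfilled)
lectin-positive area; counts and areas pool across fields *before*
dividing, making the per-tumor density invariant to how fields were
partitioned.

Vessel maturity applies a component-level distance rule: a lectin component
whose minimum distance to any alpha-SMA pixel is at least 5 um (inclusive)
counts as immature, and the immature fraction is the summed immature area
over total lectin area. The rule is applied per vessel component because
maturity is a property of a vessel, not of a pixel; a per-pixel variant is
available behind `perPixel = TRUE`.

# Chemometrics (HR MAS MRS)

Preprocessing: exponential line broadening of 0.3 Hz applied as convolution
with a unit-area Lorentzian of that FWHM (the frequency-domain equivalent of
FID apodization, so Lorentzian widths add — pinned by a closed-form test:
1.0 Hz broadened by 0.3 Hz gives 1.3 Hz within 2%), optional polynomial
baseline subtraction fit to the signal-free envelope by iterative clipping,
and mean normalization (every spectrum divided by its mean, removing
sample-mass scaling).

PLS-DA is NIPALS PLS1 regression of the mean-centred spectral matrix on a
-1/+1 class response, two latent variables by default (the number plotted in
treatment-response studies of this kind), deflating X and y between
components. Cross-validation is leave-one-out with a full refit (including
re-centring) per held-out sample; sensitivity and specificity take the
treated class as positive. Variable importance on projection is

$$\mathrm{VIP}_j = \sqrt{p \sum_a w_{ja}^2\, \mathrm{SSY}_a \Big/ \sum_a \mathrm{SSY}_a},$$

with `p` variables, unit-norm weight vectors `w_a` and `SSY_a` the response
sum of squares captured by component `a`; the mean squared VIP is exactly 1,
asserted to 1e-9. The default analysis window is 3.0–3.5 ppm — the
choline/creatine region containing the discriminating resonances at 3.23 ppm
(phosphocholine) and 3.24 ppm (glycerophosphocholine) — configurable to the
full spectrum.

Model significance uses a label-permutation test (default 1000 permutations)
with leave-one-out accuracy as the statistic and the add-one convention
`p = (#{permuted >= observed} + 1)/(n + 1)`, which can never return 0.
Because LOO accuracy on twelve samples takes only thirteen values, the
permutation p is *super*-uniform under the null (measured: mean p ≈ 0.59,
empirical CDF never above the uniform CDF): the test is valid but
conservative, and the calibration check in the test suite is accordingly
one-sided. A continuous statistic would remove the conservatism at the cost
of departing from the sensitivity/specificity framing in which such models
are reported.

# Group comparison and assay layer

Two-tailed Mann-Whitney U tests compare arms metric by metric, with
median +/- MAD summaries; MAD is the plain median absolute deviation with no
1.4826 consistency factor, matching how such studies print dispersion. For
tie-free samples with `nA + nB <= 12` — the group sizes that actually occur
(6–11 per arm) — the p value is exact by full enumeration of all rank
assignments, `p = 2 min(P(U <= u), P(U >= u))` capped at 1; larger or tied
samples use the normal approximation with tie correction and a 0.5
continuity correction. The exact path is pinned against an independent
enumeration oracle (pair counting over explicit value assignments) on 1000
random inputs, and the approximation's type-I error at alpha = 0.05 is
verified to land in [0.03, 0.07] over 10,000 null simulations at n = 8 vs 9.

Tumor volume from calipers is `V = L W^2 / 2` (width/length swapped with a
warning if transposed), normalized per animal to the baseline day.
Immunoassay calibration fits the four-parameter logistic
`y = d + (a-d)/(1 + (x/c)^b)` to standards by least squares with `c` kept
positive via a log parameterization, inverts it in closed form, excludes
readings outside the fitted asymptotes (optionally also outside a 20–80%
transmittance window), and normalizes the analyte amount to the sample's
RNA content.

# Synthetic data: what the phantoms emulate

Each generator is a pure function of its arguments including the seed
(identical seed, identical output, asserted bit-for-bit), and every painted
or rasterized structure doubles as exact ground truth.

* **Vascular phantoms** — random-walk branching tube trees (segment length
  110 um, branching probability 0.3, radii 18–90 um), rasterized exactly
  (voxel centre within radius), bright on a dark background with additive
  Gaussian noise. `targetFbv` grows the tree until the rasterized vessel
  fraction reaches a target, budgeting late segments to a fraction of the
  remaining volume so the realized fraction lands within ~25% granularity
  of whole tubes would otherwise allow. The defaults emulate a 9 um
  isotropic acquisition at desk scale (64^3 default volume; the acceptance
  studies use 40^3–48^3 with scales {9, 18, 36} um, sizes chosen as the
  package's standard desk-scale conditions and stated here once).
* **DCE phantoms** — 200 frames at 4.8 s with injection after the tenth;
  a designed voxel subset follows the saturating exponential
  `RSI(tau) = 1 + (peak-1)(1 - e^{-tau/12 s})` (monotone, closed-form AUC
  for oracles), the rest stay flat. The designed enhancing fraction is
  recorded exactly.
* **Histology phantoms** — blue vessel capsules, brown nucleus disks (a
  fraction as touching pairs at 0.6–0.9 diameter separation, guaranteeing
  watershed test cases), optional brick-red pericyte rims on a subset of
  vessels chosen to approximate a target immature area fraction. Colors are
  sampled strictly inside the threshold bands and the generator re-segments
  its own output after 8-bit quantization, failing loudly if any painted
  pixel left its band. Vessel spacing enforces the 5 um maturity rule by
  construction. Pixel size is a required argument — no magnification
  implies a standard value.
* **Spectra** — sums of Lorentzian lines (PCho 3.23 ppm, GPC 3.24 ppm,
  plus choline, creatine, taurine, lactate and neighbours) on a smooth
  baseline with Gaussian noise; treated-class effects multiply designated
  peak amplitudes (defaults: PCho x 1.5, GPC x 0.6, the reported effect
  directions), and per-sample log-normal amplitude variability (CV 5%)
  stands in for biological spread.
* **Two-arm studies** — per-tumor phantoms for every modality with
  treated-arm parameters scaled by the designed effects (vessel volume
  fraction x 0.73, immature fraction x 0.71, final-day uptake x 0.7 after a
  mild day-4 increase, enhancing fraction x 0.85 on the final day), six
  tumors per arm by default, and a manifest that regenerates byte-identically
  from the same seed.

What the phantoms do *not* emulate: MR relaxation physics, CT beam physics
and reconstruction artifacts, stain chemistry, peak misalignment or phasing
errors, motion, and partial-volume blur at vessel boundaries. Passing tests
therefore demonstrate that the analysis chain computes its defined
quantities correctly and recovers designed effects under controlled
conditions — not that those quantities are unbiased on any particular real
scanner's output.

# Numerical choices and degenerate inputs

* Percentiles: linear interpolation between order statistics (quantile
  type 7), pinned for exact tests.
* Strict vs inclusive cuts: VC > 150 um strict; RSI >= 1.5 inclusive;
  maturity distance >= 5 um inclusive — each matching its defining rule.
* Empty cases: an empty vessel mask makes DNV undefined (error); an empty
  enhancing set reports FEV 0 with a missing median; an empty lectin mask
  makes the immature fraction undefined (NA); zero-mean spectra cannot be
  normalized (error). Tumors whose stage fails inside a study run are
  excluded with a logged reason rather than aborting the report.
* The exact U-test switches to the approximation at combined n > 12 or any
  tie; with zero variance (all values identical) the p value is 1.
* Permutation p values use the add-one convention and can never be 0.

# Known limitations

* The vesselness formulation is one member of the Hessian family; the
  segmentation interface (`VesselSegmentation`) isolates it so an
  alternative tubularity measure can be swapped in without touching the
  metrics.
* Histology phantoms paint ideal colors; there is no stain variability
  model, so HSV-band robustness on real slides is untested here.
* PLS-DA assumes aligned, phased spectra; no peak alignment is performed.
* Anisotropic voxels, whole-slide imaging formats and DICOM ingestion are
  out of scope.

# A minimal run

```{r example, eval = FALSE}
study <- generateTwoGroupStudy(studyDesign(), seed = 1,
                               microctShape = c(48, 48, 48),
                               dceShape = c(16, 16, 3))
report <- runStudy(study, studyConfig(vesselScalesUm = c(9, 18, 36)))
report
makeStudyFigures(report, "figures")
```
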