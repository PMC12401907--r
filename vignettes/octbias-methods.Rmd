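---
title: "Catheter-bias morphometry and dissection risk: models and methods"
author: "octbias authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catheter-bias morphometry and dissection risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octbias)
```

## The problem

Rotational atherectomy (ROTA) ablates calcified coronary plaque with a burr
advanced over a dedicated guidewire. When the wire — and with it the
imaging catheter and the burr — runs eccentrically through the vessel
("guidewire bias"), the burr can cut into relatively normal wall and cause
an iatrogenic dissection. Intravascular OCT sees this geometry directly:
each cross-sectional frame shows the lumen (intima), often the media, the
imaging catheter, calcium, and — after the procedure — dissection flaps.

`octbias` turns segmented OCT cross-sections into quantitative bias
indices, coregisters pre- and post-procedure pullbacks on a common 1-mm
grid, and asks which pre-procedure index best discriminates the frames
that go on to dissect. The package consumes *contours*, not pixels:
segmentation is upstream and out of scope.

## Per-frame measurement model

A frame carries a closed simple intima polygon (mm coordinates, normalized
counterclockwise), optional media and EEM polygons, and the catheter pose
(center + radius, default 0.45 mm for a 2.7F imaging catheter). From these:

* **Bias geometry.** The *vessel center* is the area centroid of the
  intima contour. The *bias angle* is the direction from the vessel center
  to the catheter center; the *bias quadrant* is the closed 90° sector
  about that ray (±45°), anchored at the vessel center. When the catheter
  sits within `eps_bias = 0.05` mm of the centroid the bias direction is
  declared undefined rather than numerically unstable.
* **Distance indices.** `d_cib`/`d_cio` (`d_cmb`/`d_cmo`) are measured
  from the catheter *center* along the bias ray and its opposite to the
  first crossing of the intima (media). Missing media is a first-class
  `NA`, never a sentinel — behind attenuating plaque the media is often
  unrecognizable, and that missingness is itself informative.
* **Touch angle.** Rays from the catheter center every `dtheta = 0.5°`;
  contact where the intima lies within `gap_tol = 0.02` mm (≈ two OCT
  pixels) of the catheter surface. The reported angle is the largest
  contiguous contact run (wrap-around merged), because observed contact is
  a single arc; a `sum` mode exists for fragmented contact.
* **Lumen metrics.** Area by the shoelace formula; min/max lumen diameter
  as chords through the centroid swept every `dtheta`; eccentricity
  `(max − min)/max`; EEM area and average vessel diameter
  `(min EEM diameter + max EEM diameter)/2` analogously about the EEM
  centroid.

### Numerical choices

* Chord sweeps are anchored to the direction of the contour's first
  vertex about the centroid, so the sampled direction set rotates with the
  shape and all measurements are rigid-motion invariant to numerical
  tolerance (the touch angle to within one `dtheta` step).
* Ray–polygon intersection accepts a ±1e-9 tolerance on the edge
  parameter so rays through a shared vertex are never missed; the
  duplicate hit is harmless under the minimum.
* Angles are degrees counterclockwise from +x; angular intervals are
  half-open `[start, end)` with wrap-around, so intervals sharing only an
  endpoint do not overlap.
* Where the anatomy leaves a genuinely open choice, the package defaults
  are: vessel center = lumen (not EEM) centroid, since the EEM is often
  absent behind calcium; touch angle subtended at the catheter center;
  both recorded as configuration.

## Coregistration

Pullbacks are aligned by a fiduciary side-branch landmark
(`offset = landmark_pre − landmark_post`), and frames are paired on a 1-mm
grid over the intersection of both covered spans restricted to the
pre-phase analysis span (the burr movement segment, supplied as metadata).
Each grid point takes the nearest frame of each phase within 0.5 mm (half
the grid step; the tolerance is configurable);
ties go to the earlier frame; grid points missing a frame in either phase
are dropped and counted. *Coincidence* between a post-phase dissection and
the pre-phase bias quadrant is operationalized as non-empty overlap of the
dissection arc with the quadrant (a stricter midpoint-containment mode is
available behind a flag).

## Statistical stage

* **Univariate correlation** defaults to Spearman rank correlation (the
  indices are non-normal); point-biserial Pearson by flag.
* **ROC.** Empirical curve over all distinct thresholds; the trapezoidal
  AUC equals the normalized concordant-pair count. Orientation is chosen
  automatically so the reported AUC ≥ 0.5 (`d_cmb` discriminates with
  *small* values, touch angle with *large* ones). The CI is the DeLong
  normal approximation truncated to [0, 1].
* **Youden cutoff.** Candidates at midpoints between consecutive distinct
  predictor values; maximizes `J = sens + spec − 1`; ties break toward
  higher specificity, then the lower cutoff.
* **DeLong test** compares the two best AUCs via placement-value
  covariances; a zero-variance difference (e.g. one predictor a monotone
  transform of the other) raises a classed degenerate-test error, which
  the report stage records rather than hides.
* **Agreement.** ICC(2,1) — two-way random effects, absolute agreement,
  single measures, the conventional inter-rater form — and unweighted
  Cohen's kappa for categorical reads.
* **Clustering.** Frames cluster within patients. As a sensitivity
  analysis the report resamples patients with replacement (cluster
  bootstrap, B = 2000, percentile CI) — a deliberate surrogate for a GEE
  model, and labelled as such in the output.
* No multiplicity adjustment is applied; all tests are two-sided at 0.05.

## What the synthetic generator emulates — and what it does not

No image data ship with the package; a generator produces paired studies
with the structure the analysis assumes, at the emulated study's scale:
21 patients, 12–25 analyzable 1-mm frames each (≈ 388 total), and a
dissection fraction near 56/388 ≈ 0.144.

Each frame is a noisy rotated ellipse (radius U(1.1, 1.7) mm, eccentricity
U(0, 0.3), low-order Fourier perturbation), with media and EEM as radial
offsets (intima–media U(0.22, 0.42) mm, media–EEM U(0.12, 0.22) mm),
visible with probability 0.85 / 0.7. The catheter sits on a per-patient
bias direction (±5° per-frame drift): with probability 0.17 it *presses
into* the wall (indentation U(0.02, 0.22) mm, the intima molded around the
catheter surface, as a soft wall deforms around the probe), otherwise it
floats with clearance U(0.03, 0.6) mm. Indentation simultaneously shortens
`d_cmb` and widens the touch angle, so the two predictors correlate as
they do anatomically.

Dissection is decided mechanistically from the frame's *measured* values:
in threshold mode, `dissected ⇔ d_cmb < 0.72 mm or touch > 98.2°` (the
package's reference cutoffs are the generator's ground truth, making
parameter recovery the natural acceptance check; `tau_d = 0` or
`tau_a = Inf` disables a term). A logistic mode replaces the step with a Bernoulli draw
whose intercept is calibrated on the generated cohort to hit the target
event fraction. Dissected frames get a flap arc placed *inside* the bias
quadrant (width U(20, 40)°) and a subintimal catheter flag with
probability 1; non-dissected frames get 2–8% lumen growth (ablation
effect). The contact probability 0.17 was chosen a priori so the
threshold rule's expected event fraction lands near 0.144, and was not
revisited.

Because labels derive from noiseless measured values, a green
perfect-discrimination test establishes that the measurement, pairing and
ROC stages are *internally consistent* — it does not establish that real
vessels separate perfectly. The generator has no speckle, no segmentation
error (reader noise is modelled as vertex jitter, SD 0.01 mm, matching the
ICC > 0.99 regime), no longitudinal correlation of lumen shape between
neighbouring frames, no calcium-dependent wall mechanics, and no burr
kinematics. Scale parameters beyond the stated counts are plausibility
choices, documented here as assumptions.

## Known limitations

* Frames are independent 2-D sections; no 3-D reconstruction.
* The dissection depth taxonomy is carried as labels, but only the
  intimal-dissection flag is the analysis endpoint.
* The cluster bootstrap approximates, not reproduces, a GEE analysis.
* Published agreement statistics and real-data AUCs are not reproducible
  without the study's images; the package's acceptance surface is the
  mechanistic synthetic study plus internal-consistency checks.

## Reproducing the full pipeline

```{r, eval = FALSE}
res <- reproduce_study(generator_config(seed = 1), out_dir = "run1")
res$analysis
```

The same chain is scriptable: `Rscript scripts/acceptance.R --seed 1 --out
results/acceptance.json` recomputes the headline quantities from scratch.
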