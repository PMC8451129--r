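---
title: "Phantom-based verification of microstructural and functional cardiac MR analysis"
author: "cmrphantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based verification of microstructural and functional cardiac MR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrphantom)
```

## Why a phantom

Longitudinal infarct studies report regional relaxometry (native T1, T2,
ECV), diffusion-tensor microstructure (MD, FA, helix angle) and function
(volumes, strains, torsion) at a handful of timepoints from the acute to
the chronic stage. Raw animal data behind such studies are rarely
deposited, so an analysis pipeline cannot be validated against them
directly. `cmrphantom` instead makes the *pipeline itself* verifiable: a
synthetic left ventricle carries known regional parameter values through
the same forward physics the scanner would apply, and every fitting stage
must recover those values. At zero noise each fit inverts its forward
model exactly (to 1e-9 relative); at realistic noise the region-of-interest
means must land within the dispersion reported for in-vivo cohorts.

## The phantom

The ventricle is a stack of short-axis annuli (default: 10 slices of 8 mm,
2 mm in-plane pixels on a 64 x 64 grid, endocardial radius 20 mm,
epicardial 30 mm), ordered apex to base with slice position
$z_s = s\,(\Delta z_\text{thk} + \Delta z_\text{gap})$. Angles are measured
counterclockwise from the anterior RV-insertion reference, which anchors
the 16-segment AHA ring parcellation (basal 1-6, mid 7-12, apical 13-16).
An infarct occupies an inferolateral sector (default 79.2 degrees over 5
of 10 slices, i.e. 11% of the myocardial voxels, matching the LGE-based
ischemic-region size the phantom emulates); the septal segments 8 and 9
act as the remote reference zone and are required to be disjoint from the
infarct sector.

Transmural depth is 0% at the endocardial and 100% at the epicardial
border, computed as the normalized position along the radial ray between
the two contours. The helix angle ramps linearly with depth from a
positive (right-handed) endocardial value to a negative (left-handed)
epicardial value; a symmetric ramp with endpoints $\pm 50\,|g|$ realises a
prescribed transmural HA gradient of $g$ degrees per percent depth.

Per timepoint (`baseline`, `day6`, `week5`, `week9`) each region carries
scalar ground truth. The defaults encode the acute-to-chronic infarct
timeline: acute edema raises infarct T2 to 83 ms (remote 61 ms, healthy
58 ms) and normalises chronically; infarct native T1 sits in the
1099-1128 ms range (< 3% drift) against roughly 1000 ms healthy tissue at
1.5 T; infarct MD rises by 17/33/29% and FA falls by 31/38/36% versus
baseline at day 6 / week 5 / week 9 (healthy MD 1.5e-3 mm^2/s, FA 0.45);
infarct ECV rises by 125/157/146% over a 0.25 baseline. The post-contrast
T1 ground truth is *derived* from the target ECV through the ECV relation
(`t1PostForECV()`), so the relaxometry chain closes exactly by
construction. Torsion, global strains and HA-gradient targets per cohort
and timepoint follow the corresponding functional tables of porcine
infarct cohorts (torsion 0.20-0.31 degrees/mm, GRS 37-49%, GCS -14 to
-18%, GLS -14 to -17%, HA gradient -1.02 to -1.26 degrees/%).

## Forward models

* **Diffusion.** Per voxel an axially symmetric tensor is built with the
  primary eigenvector at the prescribed helix angle in the
  circumferential-longitudinal surface and eigenvalues
  $\lambda_1 = \mathrm{MD}(1 + 2\delta)$,
  $\lambda_{2,3} = \mathrm{MD}(1 - \delta)$,
  $\delta = \mathrm{FA}/\sqrt{3 - 2\,\mathrm{FA}^2}$, the unique axially
  symmetric solution whose MD and FA equal the prescribed values. The
  signal is $S_0 e^{-b\,g^\top D g}$ under the 18-direction scheme
  (3 @ b=100, 3 @ b=200, 12 @ b=450 s/mm^2, 8 averages, no b=0 volume —
  $\ln S_0$ is an unknown of the fit).
* **MOLLI.** $|A - B e^{-TI/T_1^*}|$ with ideal inversion $B = 2A$
  (imperfect inversion available via `inversionEfficiency`), Gaussian
  noise added to the signed signal before the magnitude operation.
* **Multi-echo T2.** $S_0 e^{-TE/T_2}$ over 9 echoes spaced 8.8 ms, with
  Rician noise.
* **LGE.** Inversion-nulled remote myocardium Normal(mu, sigma) with scar
  at +15 sigma — comfortably above the 5SD threshold, as after a
  correctly chosen inversion time.
* **Motion.** Mid-mural, endo- and epicardial contours with point
  correspondence; slice rotation $\theta_s(t) = \tau\, z_s\, w(t)$ with a
  smooth 0-1-0 activation $w$ peaking at 35% of the cycle; GCS/GRS/GLS
  scale mid-wall radius, wall thickness and long-axis length by their peak
  values.
* **Noise.** Rician noise is the modulus of a complex signal with
  independent Gaussian channels. The default channel sigma is 1/30 of the
  reference signal (SNR 30). No SNR is stated for the in-vivo protocols
  the phantom emulates; SNR 30 was chosen once as representative of 1.5 T
  cardiac imaging, and it leaves the recovered ROI means well within the
  reported in-vivo standard deviations, which is the property the
  acceptance checks exercise.

## Fitting stages and numerical choices

**MOLLI T1.** The magnitude model is fitted per voxel by polarity
restoration plus separable least squares: for a candidate flip count $k$
(the first $k$ samples negated) and a candidate $T_1^*$, the then-linear
$(A, B)$ subproblem has a closed-form solution. A log-spaced $T_1^*$ grid
(48 nodes, 100-5000 ms) is evaluated for all voxels at once; each
candidate flip count is then refined per voxel by golden-section search
and the hypothesis with the lowest residual wins. Candidate flip counts
cover the neighbourhood of the two smallest-magnitude samples — noise can
displace the apparent null by a sample, and restricting candidates to the
minimum alone leaves a wrong-polarity fit with a several-percent T1 bias.
The Look-Locker correction $T_1 = T_1^*(B/A - 1)$ is applied afterwards;
voxels with non-positive $A$, $B$ or $T_1$ are flagged invalid and
excluded from ROI means.

**T2.** Weighted log-linear least squares with weights equal to the
squared signal, which down-weights the Rician-inflated tail of the decay;
non-positive signals are excluded from the log transform and voxels with
fewer than three usable echoes are invalid. A per-voxel nonlinear
refinement is available (`refine = TRUE`) but changes nothing at the
noise levels considered here. The model is a 2-parameter mono-exponential;
no constant offset is fitted by default.

**ECV.** $(1 - \mathrm{Hct})\,\Delta R_{1,\text{myo}} /
\Delta R_{1,\text{blood}}$ per voxel, with blood values taken from the
fitted blood-pool ROI so the computation is end-to-end. Out-of-range
voxels are clipped to [0, 1] and counted rather than failing — noise can
push individual voxels outside the physical range. Pre/post series of the
phantom are co-registered by construction; an integer-pixel translation
search (`registerTranslation`) is provided for perturbed inputs.

**Diffusion tensor.** Weighted linear least squares on the log signal for
$[\ln S_0, D_{xx}, D_{yy}, D_{zz}, D_{xy}, D_{xz}, D_{yz}]$, weights equal
to the squared signal; signals below a floor are clipped and flagged.
Rank deficiency of the design is a protocol-validation error, not a
per-voxel one. Eigenvalues are ordered descending; FA is clipped to
[0, 1], defined as 0 for numerically-zero tensors, and negative
eigenvalues flag the voxel.

**Helix angle.** $p = e_1 - (e_1\cdot\hat r)\hat r$,
$\mathrm{HA} = \operatorname{atan2}(p\cdot\hat l,\; p\cdot\hat c)$.
Eigenvectors have arbitrary sign, so $e_1$ is flipped to make
$p\cdot\hat c \ge 0$; on the boundary ($p\cdot\hat c \approx 0$) the
tie-break flips to $p\cdot\hat l \ge 0$, keeping the map continuous at
±90 degrees. Voxels with projection norm below 0.2 (dominantly radial
eigenvector) are masked invalid; the in-vivo literature does not state a
threshold for this exclusion, and 0.2 is documented here as the package's
choice. The transmural gradient is an ordinary least-squares slope of HA
against depth *in percent* (matching the degrees-per-percent unit of the
functional tables) over the septal segments 8 and 9 only — the wall at
the infarct is too thin for a reliable transmural fit, which is why the
operation takes explicit segment labels rather than a whole-mask flag.

**Mechanics.** Volumes by Simpson summation of cavity areas times slice
spacing; ED and ES are the max- and min-volume phases. Torsion regresses
each slice's mean contour-point rotation (about the slice centroid,
relative to phase 0) on the slice's *initial* longitudinal position;
"maximum torsion" is taken as the max over phases of the absolute slope,
reported at its signed value, since systolic peak and absolute maximum
coincide for the phantom's activation. Rotation is
counterclockwise-positive viewed from the apex, making the reported
torsion values positive. The global strains are declared geometric
simplifications of commercial feature tracking: GCS from the mid-wall
perimeter, GRS from mean endo-epi wall thickness, GLS from the long-axis
landmark length. They are exact for the phantom's similarity-type
deformation but are not a replacement for feature-tracking strain on real
images.

**Scar.** Threshold at remote mean + 5 SD, estimated volumetrically over
the whole remote ROI (per-slice estimation is a possible variant; the
volumetric choice is the package default). Mass uses 1.05 g/ml myocardial
density. A largest-connected-component refinement stands in for manual
refinement and is off by default, and its use is recorded in the result.

**Statistics.** Relative changes are per-subject
$(x_\text{infarct} - x_\text{ref})/x_\text{ref}$ with the remote zone or
the subject's baseline as reference; control-vs-remote bias enumerates all
control x infarct pairs normalized by the pair mean. Group comparisons use
the classical pooled-variance Student's t-test (paired within subjects),
with fixed conventions for degenerate inputs (identical samples: t = 0,
p = 1; zero-variance nonzero shift: p = 0, flagged). No multiple-testing
correction is applied, mirroring the study design the package emulates;
this is recorded in the output. Correlations are Pearson with the usual
t transform and OLS confidence bands. Operations take explicit row
selections rather than guessing which timepoints pool into a correlation.

## What the phantom does and does not show

The phantom shares the grid, protocols, contrasts and noise character of
in-vivo acquisitions but is deliberately idealised: no motion between
frames or series (registration is identity), no EPI/off-resonance
distortion, no partial-volume mixing at tissue borders, piecewise-constant
regional truth, circular contours, and an axially symmetric tensor field.
Passing recovery tests therefore demonstrates that the *analysis* is
correct and calibrated — not that it is robust to segmentation error,
through-plane motion or distortion on real data. Conversely, any failure
on phantom data is a genuine pipeline defect, which is what makes the
round-trip tests sharp.

```{r quick-example, eval = FALSE}
gt <- buildPhantom(defaultPhantomConfig("day6", seed = 1L))
ser <- simulateMultiEcho(truthMap(gt, "T2"), seed = 12,
                         noiseSigma = 1000 / 30)
t2 <- fitT2Map(ser, myocardium(gt))
mean(t2[roiLabels(gt) == 2L], na.rm = TRUE)  # ~83 ms
```

## Problem sizes and determinism

The full-resolution phantom (64 x 64 x 10, ~4000 myocardial voxels) is
used for the acceptance runs; unit tests run reduced stacks (48 x 48 with
2-4 slices), which keeps the complete suite around two minutes without
changing any model. The whole-study driver `runStudy()` defaults to the
5 infarct + 4 control design over four timepoints and derives one seed per
subject-timepoint from the study seed, so reruns are bit-identical. All
noise flows through R's RNG seeded per simulated series; changing only the
seed moves ROI means by no more than the expected standard error.
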