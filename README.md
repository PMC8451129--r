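# cmrphantom

Synthetic left-ventricle phantom and analysis pipeline for longitudinal
microstructural and functional cardiac MR.

Quantitative CMR studies of myocardial infarction track a region of
interest through relaxometry (native T1, T2, extracellular volume),
diffusion-tensor microstructure (mean diffusivity MD, fractional
anisotropy FA, transmural helix-angle gradient), function (volumes,
ejection fraction, torsion, global strains) and late gadolinium
enhancement, from the acute edema phase to chronic scar. Because raw
animal data behind such studies are rarely available, `cmrphantom` makes
the analysis verifiable the other way around: a digital short-axis LV
phantom with an inferolateral infarct carries known regional ground truth
through the standard forward models — MOLLI inversion recovery, 9-echo T2
decay, an 18-direction 3-shell DWI scheme (3@b=100 / 3@b=200 / 12@b=450
s/mm², 8 averages), inversion-nulled LGE, and tracked contour motion —
with Rician noise, and each analysis stage must recover the configured
values.

Core quantities, in the field's notation:

* Look-Locker corrected T1 from the magnitude fit of
  |A − B·exp(−TI/T1\*)|, T1 = T1\*(B/A − 1); mono-exponential T2;
  ECV = (1 − Hct)·ΔR1_myo / ΔR1_blood.
* Diffusion tensor by weighted log-linear least squares (ln S0 plus six
  tensor elements; no b=0 volume); MD = tr(D)/3;
  FA = √(3/2)·‖λ − MD‖/‖λ‖; helix angle from the primary eigenvector
  projected into the circumferential–longitudinal surface, and the septal
  (AHA segments 8–9) transmural HA gradient in °/% depth.
* Torsion as the slope of slice rotation versus initial longitudinal
  position (°/mm); simplified geometric GRS/GCS/GLS; 5SD LGE scar mass as
  percent of LV mass.
* Study statistics: per-subject relative changes
  (infarct vs remote, or vs baseline), all-pairs control-vs-remote bias,
  paired/unpaired pooled-variance t-tests, Pearson correlations with 95%
  confidence bands.

## Worked example

```r
library(cmrphantom)

# acute-stage phantom: infarct T2 83 ms, remote 61 ms, scar = 11% of LV
gt <- buildPhantom(defaultPhantomConfig("day6", seed = 1L))

# T2 mapping at SNR 30
ser <- simulateMultiEcho(truthMap(gt, "T2"), seed = 12, noiseSigma = 1000/30)
t2  <- fitT2Map(ser, myocardium(gt))
mean(t2[roiLabels(gt) == 2L], na.rm = TRUE)   # infarct ROI
#> [1] 83.96097
mean(t2[roiLabels(gt) == 1L], na.rm = TRUE)   # remote
#> [1] 62.2008

# scar quantification by 5SD thresholding of the LGE volume
lge    <- simulateLGE(gt, seed = 13)
remote <- (ahaSegments(gt) %in% 8:9) & myocardium(gt)
segmentScar5SD(lge, myocardium(gt), remote)
#> ScarResult: threshold 148.42; scar 14.78 g of 134.4 g (11% of LV mass)

# torsion from noiseless tracked contours (configured 0.23 deg/mm)
torsionFromContours(simulateContourMotion(gt))$peak
#> [1] 0.23
```

The infarct-ROI T2 lands within the Rician-floor bias (~1 ms) of the
configured 83 ms; the 5SD segmentation returns the geometrically true 11%
scar fraction; the torsion regression inverts the prescribed twist
exactly.

A whole simulated study (5 infarct + 4 control subjects, four
timepoints) runs with `runStudy(defaultStudyConfig())`, producing the
long region table, relative-change and bias statistics, and the
strain/HA-gradient correlation.

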