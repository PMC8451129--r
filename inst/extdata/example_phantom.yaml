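nSlices: 6
sliceThickness: 8.0
sliceGap: 0.0
pixelSpacing: 2.0
gridSize:
- 48
- 48
endoRadius: 20.0
epiRadius: 30.0
rvInsertionAngle: 0.0
infarctSector:
- 240.0
- 319.2
infarctSlices:
- 3
- 4
- 5
bloodPool: yes
hematocrit: 0.33
timepoint: day6
regional:
  region:
  - remote
  - infarct
  - blood
  T1native:
  - 1010.0
  - 1099.0
  - 1550.0
  T1post:
  - 491.818537
  - 315.7782754
  - 300.0
  T2:
  - 61.0
  - 83.0
  - 250.0
  MD:
  - 1.5
  - 1.755
  - 3.0
  FA:
  - 0.45
  - 0.3105
  - 0.05
  scar:
  - no
  - yes
  - no
haEndo: 58.0
haEpi: -58.0
torsionSlope: 0.23
peakContractionFraction: 0.35
strainTargets:
  GRS: 42.0
  GCS: -14.0
  GLS: -16.0
noiseSigma: 0.0333333
seed: 7
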