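# corrdiff

Correlated diffusion imaging (CDI) for multi-b-value diffusion-weighted
MRI, with the standard ADC baseline, a synthetic prostate phantom, and a
voxel-level ROC/LOOCV evaluation protocol.

## The problem and the method

Prostate cancer is hard to delineate with any single diffusion weighting:
the contrast between cancerous and healthy tissue depends on how the
gradient pulses (strength *G*, duration *δ*, separation *Δ*) are
configured, summarised by the b-value
*b* = γ²*G*²*δ*²(*Δ* − *δ*/3). Dense tumor tissue restricts water
diffusion, so its signal stays high at *every* weighting. CDI exploits
this by mixing all acquisitions whose b-values fall in a diffusion range
[*q_α*, *q_β*] into the local joint correlation of signal attenuation —
the expected product of the in-range signals over a spatial sub-volume
*V*(x):

    C(x) = (1/|V(x)|) · Σ_{x′ ∈ V(x)} Π_{i ∈ I} S_i(x′),
    I = { i : q_α ≤ b_i ≤ q_β }

Restricted diffusion keeps every factor large, so the product amplifies
cancer/healthy contrast multiplicatively, while the sub-volume mean pools
local statistics. The package computes CDI maps (default range
[0, 2000] s/mm², default 3×3×3 sub-volume), ADC maps (unweighted OLS on
ln S over Ω = {0, 100, 1000} s/mm²), and evaluates both with binormal ROC
analysis (A_z), a two-class Gaussian maximum-likelihood voxel classifier,
leave-one-out cross-validation, and Fisher class-separability. A phantom
generator provides prostate-like multi-b-value stacks (mono-exponential
decay per tissue, Rician magnitude noise, SNR 20 at b = 0) so the whole
pipeline runs without patient data.

Everything is S4 with validity checking: `DWIStack` (4D signal +
b-values), `ScalarMap` (derived maps with provenance), `LabelMap`,
`PhantomSpec`, `ROCResult`, `EvalMetrics`. I/O is NIfTI-1 (.nii/.nii.gz)
with FSL-style `.bval` sidecars and JSON provenance sidecars.

## Worked example

```r
library(corrdiff)

ph  <- generatePhantom(defaultProstateSpec(seed = 1))  # 64x64x16, b = 0/100/1000/2000
cdi <- computeCDI(ph$stack)      # diffusion range [0, 2000], 3x3x3 sub-volume
adc <- computeADC(ph$stack)      # omega = {0, 100, 1000}

cdi
#> ScalarMap [CDI]: 64 x 64 x 16 voxels
#>   range: [1.48019e+07, 1.22794e+11]
#>   spacing (mm): 1.56 x 1.56 x 3.50

sc <- extractScores(cdi, ph$labels)           # lesion vs healthy-gland voxels
binormalROC(sc$cancer, sc$healthy)
#> Binormal ROC: a = 2.9228, b = 0.3974, Az = 0.9967

scA <- extractScores(orientScores(mapValues(adc), "ADC"), ph$labels)
binormalROC(scA$cancer, scA$healthy)
#> Binormal ROC: a = 7.6332, b = 2.3905, Az = 0.9984

separability(sc$cancer, sc$healthy)
#> [1] 7.377211
```

The CDI map separates the restricted-diffusion lesions from healthy gland
at A_z ≈ 0.997 on this phantom; the ADC baseline reaches ≈ 0.998 here
because the phantom's mono-exponential, piecewise-constant signal is
exactly the ADC model — see the methods vignette
(`vignettes/correlated-diffusion.Rmd`) for why phantom-scale rankings do
not transfer to clinical data.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/corrdiff.R", package="corrdiff"))')" \
    phantom generate --seed 7 --out-dwi dwi.nii.gz --out-bval dwi.bval \
    --out-labels labels.nii.gz
# then: cdi compute / adc compute / evaluate roc / evaluate loocv
```

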