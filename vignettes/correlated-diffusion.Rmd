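---
title: "Correlated diffusion imaging: model, estimator and evaluation protocol"
author: "corrdiff package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated diffusion imaging: model, estimator and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrdiff)
```

## The imaging model

Pulsed-gradient spin-echo diffusion MRI acquires a magnitude signal volume
per gradient-pulse configuration $q_i = (G_i, \delta_i, \Delta_i)$ — pulse
strength (T/m), pulse duration (s) and pulse separation (s). The
configuration collapses into a single diffusion weighting, the b-value,

$$ b_i \;=\; \gamma^2 G_i^2 \delta_i^2 \left(\Delta_i - \tfrac{\delta_i}{3}\right), $$

with $\gamma$ the proton gyromagnetic ratio, fixed here at the CODATA value
$2.6752218744\times 10^{8}\,\mathrm{rad\,s^{-1}\,T^{-1}}$. Internally the
package works in SI units ($\mathrm{s/m^2}$) and converts to the
conventional $\mathrm{s/mm^2}$ only at the interface (`bValue()`); the
closed-form inverse `configFromBValues()` lets protocols and phantoms be
specified by b-value alone, since published protocols rarely print the
$(G, \delta, \Delta)$ triples. Water in dense, highly cellular tissue such
as prostate cancer is *restricted*: it attenuates little at every
weighting, which is the physical premise of everything below.

## Correlated diffusion imaging

A single weighting forces a choice: low $b$ keeps signal but little
diffusion contrast, high $b$ the reverse, and the best choice is
tissue-dependent. Correlated diffusion imaging (CDI) avoids the choice by
mixing all acquisitions within a diffusion range
$[q_\alpha, q_\beta]$ into one quantity — the local joint correlation of
signal attenuation: the expected product of the in-range signals under
their joint distribution over a spatial sub-volume $V(\underline{x})$.
`computeCDI()` realises that expectation with its plug-in estimator, the
sub-volume sample mean of the across-acquisition product:

$$ C(\underline{x}) \;=\; \frac{1}{|V(\underline{x})|}
   \sum_{\underline{x}' \in V(\underline{x})} \;
   \prod_{i \in I} S_i(\underline{x}'), \qquad
   I = \{\, i : q_\alpha \le b_i \le q_\beta \,\}. $$

The empirical distribution over $V$ is the only estimator consistent with
the printed definition that requires no distributional assumptions; it is
also what makes the map computable in one separable sliding-window pass.
Restricted-diffusion voxels keep a large signal in *every* factor, so their
product is larger than that of healthy tissue by roughly the product of the
per-acquisition contrast ratios — a multiplicative amplification no single
acquisition provides.

Numerical and boundary choices, each recorded in the map's provenance:

* **Diffusion range.** Default $[0, 2000]\ \mathrm{s/mm^2}$, the standard
  clinical prostate range; any acquisition set inside it is accepted and
  the in-range indices are recorded. An empty in-range set is an error, not
  an empty map.
* **Sub-volume.** The default is per-axis voxel half-widths $(1,1,1)$, a
  $3\times3\times3$ cube. A physical-extent mode converts a size in mm
  (cube side) or mm$^3$ (volume) to the smallest covering half-widths,
  rounding up per axis. A "7 mm$^3$" sub-volume is genuinely ambiguous
  between a 7 mm-sided cube (343 mm$^3$) and a 7 mm$^3$ volume (side
  $\approx 1.91$ mm); at the default spacing of
  $1.56\times1.56\times3.5$ mm these give half-widths $(3,3,1)$ and
  $(1,1,1)$ respectively. Both readings are supported
  (`neighborhoodSpec(size = 7, unit = "mm")` / `unit = "mm3"`) and neither
  is asserted as canonical; the voxel-radius default coincides with the
  mm$^3$ reading.
* **Boundaries.** Neighborhoods are clipped at the volume edge and averaged
  over the in-bounds count only — no padding fabricates signal outside the
  imaged volume.
* **Scale.** Raw magnitude signals enter the product, so the map scales as
  $c^{|I|}$ when the stack is scaled by $c$; an optional `normalizeB0`
  switch divides every volume by the $b=0$ volume first, for use across
  scans with different gains.
* **Arithmetic.** Products are taken directly in double precision; with
  $|I| \le 8$ and clinical signal magnitudes the dynamic range is far from
  overflow, so no log-domain accumulation is needed.

## The ADC baseline

The comparison standard is the apparent diffusion coefficient: per voxel,
an unweighted ordinary least-squares fit of $\ln S$ against $b$ over
$\Omega = \{0, 100, 1000\}\ \mathrm{s/mm^2}$, with ADC the negated slope
clamped at zero. Unweighted log-linear fitting is the standard clinical
estimator for 2–3 b-values. Nonpositive signals (possible in noisy
magnitude data after interpolation) are floored at $10^{-6}\times$ the
stack maximum before the log; floored voxels are counted in provenance.
The log-signals are centred before the slope projection so constant
signals give a slope of exactly zero rather than rounding residue.

## The synthetic phantom

No imaging data accompany the method, so the package ships a generator
(`generatePhantom()`) whose defaults (`defaultProstateSpec()`) emulate the
study conditions: a $64\times64\times16$ grid at
$1.56\times1.56\times3.5$ mm (the cohort's median in-plane resolution and
slice thickness), acquisitions at $b \in \{0, 100, 1000, 2000\}$ — spanning
the ADC set $\Omega$ and both endpoints of the CDI range — an ellipsoidal
healthy gland (semi-axes $22\times18\times14$ mm, a typical gland volume)
and two spherical lesions of radius 4 and 6 mm, clinically relevant small
foci, placed strictly inside the gland.

Signal follows mono-exponential decay per tissue,
$S = S_0 e^{-bD}$, with healthy $D = 1.5\times10^{-3}$ and cancer
$D = 0.7\times10^{-3}\ \mathrm{mm^2/s}$ — literature-typical prostate
values with the restricted-diffusion ordering — equal $S_0 = 1000$ for
gland and lesion, and a dim fluid-like background
($S_0 = 100$, $D = 3\times10^{-3}$). Observed magnitudes are Rician,
$\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$ with independent zero-mean
Gaussians of scale $\sigma = 50$, i.e. SNR 20 at $b = 0$ — magnitude-MR
statistics rather than additive Gaussian, which matters precisely where
the ADC log-fit is most stressed (high $b$, low signal). Generation is
bit-reproducible from the spec seed and leaves the caller's RNG state
untouched.

What the phantom deliberately does **not** model: zonal anatomy, coil
profiles, motion or eddy-current artifacts, partial-volume mixing *within*
a voxel (each voxel is purely one tissue), and any deviation from
mono-exponential decay — no IVIM perfusion term, no kurtosis. The last
point is important for interpreting results: piecewise-constant
mono-exponential data satisfy the ADC model exactly, so the phantom is the
most favourable possible setting for the ADC baseline (see *Limitations*).

## Evaluation protocol

Scores are analysed at voxel level within the gland, cancer being the
positive class; CDI maps are used as-is (cancer hyperintense) and ADC maps
are negated first (cancer hypointense), so higher always means more
cancer-like.

* **Binormal ROC** (`binormalROC()`): Gaussian class-conditional scores
  fitted by moment matching (sample mean/SD), giving
  $a = (\mu_1-\mu_0)/\sigma_1$, $b = \sigma_0/\sigma_1$ and
  $A_z = \Phi\!\left(a/\sqrt{1+b^2}\right)$. Moment matching (rather than
  ROC-curve maximum likelihood) is deterministic, testable against the
  closed form, and needs no binning. Orientation is not auto-flipped:
  reversed scores give $A_z < 0.5$ and are meant to.
* **Empirical ROC** (`empiricalROC()`): the Mann–Whitney AUC with ties
  counted half — a distribution-free cross-check of the binormal fit.
* **Two-class ML classifier** (`fitMLClassifier()`, `classifyVoxels()`):
  per-class Gaussians from voxel intensities pooled unweighted across
  training cases (each voxel counts once), maximum-likelihood estimates
  (biased-denominator SD), no class priors; a degenerate class gets an SD
  floor of $10^{-12}(|\mu|+1)$ so synthetic fixtures stay evaluable, and
  flooring is logged.
* **LOOCV** (`loocv()`): each case held out once; pooled metrics come from
  summed confusion counts, and sensitivity/specificity/accuracy are exact
  rationals of those counts.
* **Separability** (`separability()`): the exact statistic behind the
  published "tissue class separability" phrase is not defined anywhere we
  could follow, so the package uses the Fisher ratio
  $(\mu_1-\mu_0)^2/(\sigma_0^2+\sigma_1^2)$ as a documented stand-in, not
  as a claim about the original analysis.

Score maps built for classification (e.g. negated ADC) may be negative;
the nonnegativity invariant applies to CDI and ADC maps themselves. No
per-case shifting or rescaling is applied to scores — a per-case offset
(such as subtracting a map minimum) would misalign the pooled class
Gaussians across cases.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen as the smallest sizes at which every property is
informative: estimator-equivalence checks on random stacks up to
$12\times12\times6\times4$ against a brute-force nested-loop oracle;
distributional checks at $10^4$ samples per class; the phantom protocol on
ten seeded $64\times64\times16\times4$ phantoms; LOOCV on three phantom
cases.

## Limitations and known behaviour

* **ADC is near-optimal on this phantom by construction.** On ten seeded
  default phantoms the mean binormal $A_z$ is $\approx 0.9966$ for CDI and
  $\approx 0.9984$ for negated ADC. Two structural reasons: the phantom's
  decay is exactly the ADC model, and CDI's sub-volume averaging mixes
  tissue classes at lesion boundaries — at 3.5 mm slice thickness with
  4–6 mm lesions, nearly every lesion voxel is a boundary voxel (on pure
  interior tissue the ordering reverses: CDI $A_z = 1.0$ vs ADC
  $\approx 0.9985$). The phantom also omits a mechanism plausibly
  contributing to CDI's clinical advantage — elevated water content
  (higher $S_0$) in cancer — which would raise CDI contrast while leaving
  ADC, an $S_0$-invariant quantity, exactly unchanged. Phantom-scale
  results therefore say nothing about the relative clinical merit of the
  two maps; they validate the machinery, not the modality ranking.
* The noiseless contrast-direction guarantee (every lesion voxel above
  every healthy voxel) holds voxelwise for ADC, but for CDI only on voxels
  whose whole sub-volume lies in one tissue; class means are strictly
  ordered either way.
* At SNR 20 the per-voxel ADC dispersion in lesions is on the order of
  10–15%; the median lesion ADC (the robust per-lesion estimate) errs by
  about 1% from the generating $D$.
* Gradient-direction handling (.bvec) is out of scope: the method operates
  on pulse strength/timing, and stacks are assumed direction-averaged
  (trace-weighted) per b-value.

## Worked example

```{r example, eval = FALSE}
ph  <- generatePhantom(defaultProstateSpec(seed = 1))
cdi <- computeCDI(ph$stack)                 # [0, 2000], 3x3x3 sub-volume
adc <- computeADC(ph$stack)                 # omega = {0, 100, 1000}

sc  <- extractScores(cdi, ph$labels)
roc <- binormalROC(sc$cancer, sc$healthy)
roc
separability(sc$cancer, sc$healthy)
```

The same pipeline is scriptable from a shell via the installed wrapper
(`system.file("scripts", "corrdiff.R", package = "corrdiff")`); every
subcommand writes its parameters into a JSON provenance sidecar and is
reproducible under `--seed`.
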