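---
title: "Quantifying multispecies biofilm structure from confocal z-stacks"
author: "biofilmq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multispecies biofilm structure from confocal z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmq)
```

## The problem

Mixed-species biofilms — for instance *Stenotrophomonas maltophilia*
growing with *Pseudomonas aeruginosa*, *Staphylococcus aureus* or
*Candida albicans* — organise into striking vertical structures: distinct
bottom and top layers, three-band "sandwich" arrangements, or complete
exclusion of one species.  Confocal laser scanning microscopy of
fluorescently tagged strains records these communities as multichannel
z-stacks, one channel per fluorophore/species, with the substratum at the
bottom of the stack.  Turning those images into numbers — how much volume
each species occupies, where along z it sits, and how the community
composition shifts over time — requires a small chain of image-analysis
steps, each of which can quietly bias the result.  This package
implements that chain as tested, reusable components, together with a
synthetic scene generator that provides exact voxel-level ground truth
for validating every step.

## The method

The pipeline runs four stages, in this order:

1. **Crosstalk calibration.**  Fluorophores bleed into each other's
   detection channels.  For each ordered dye pair, a *single-label
   control* stack (only one organism present) gives the per-voxel ratio
   $I_{\mathrm{unpop}}(z,y,x)\,/\,I_{\mathrm{pop}}(z,y,x)$ between the
   unpopulated and the populated channel.  The mode of the histogram of
   these ratios is the crosstalk coefficient $k_{i\to j}$.  Coefficients
   for all ordered pairs form the mixing matrix $K$ (unit diagonal).
2. **Crosstalk correction.**  Each mixed-species stack is corrected
   subtractively, $I'_j = \max\!\big(0,\, I_j - \sum_{i\neq j} k_{i\to j}
   I_i\big)$, or by solving the full linear mixing system per voxel
   (`method = "unmix"`).  The two agree to second order in $k$; the
   subtractive default matches the pairwise way the coefficients were
   calibrated.
3. **Segmentation.**  Each corrected channel is blurred with a Gaussian
   and thresholded with Li's minimum cross-entropy method, giving a
   binary occupancy mask per channel.  One global threshold is used per
   channel per stack, since thresholding precedes the per-slice
   bookkeeping.
4. **Quantification.**  Occupied voxels are summed per z slice and in
   total, normalised to the slice and stack volume ("biovolume
   fractions"); the per-channel totals give composition shares in percent
   (the "cell ratio" of a species combination at a time point);
   replicate profiles (three imaged positions per condition in the study
   design this mirrors) are averaged with sample standard deviation; and
   total volumes of two conditions are compared with Welch's two-sample
   t-test.

## Estimating crosstalk: choices that matter

**Which voxels enter the ratio histogram.**  Dividing two noisy channels
voxel-by-voxel over the whole stack is dominated by background $0/0$
ratios.  Ratios are therefore computed only over the *calibration
foreground* — the voxels where the populated channel exceeds its own Li
threshold — where the denominator is far from zero.

**Background correction.**  With a detector offset $b$, the raw ratio of
a bleed-through voxel is $(k s + b)/(s + b) \neq k$; at typical
foreground-to-background ratios this inflates a $k$ of 0.05 to about
0.095.  Both channels are therefore background-corrected before division,
subtracting each channel's median intensity outside the calibration
foreground.  On offset-free data this leaves ratios untouched.

**Mode, not maximum.**  The coefficient is the *mode* of the ratio
histogram (centre of the highest-count bin, ties resolved to the lowest
bin).  The largest observed ratio is an unbounded noise statistic and
would grow without limit with stack size.

**Discard, don't clamp.**  Ratios are histogrammed over a configurable
range, $[0, 1.5]$ in 256 bins by default.  Out-of-range ratios are
*discarded*: with additive noise and small $k$ a sizeable fraction of
ratios is negative, and clamping them to the range edge would pile that
mass into the first bin and drag the mode to zero.  (Noise-free, this
makes no difference.)

With these choices the estimator recovers $k \in \{0.02, 0.05, 0.10,
0.20\}$ to within half a histogram bin ($\approx 0.003$) on noise-free
renders, and to within $0.02$ under Gaussian noise of 5% of the mean
foreground brightness — the bounds asserted in the test suite.

## Li thresholding: numerical details

The threshold is computed on a 256-bin histogram of the blurred channel
scaled to its own min–max range, with bin centres shifted so the smallest
sits one bin width above zero (the criterion takes logarithms of class
means; the shift also makes the result exactly shift-equivariant).
Starting from the overall mean, the Li–Tam fixed-point iteration

$$t_{n+1} = \frac{\mu_b(t_n) - \mu_a(t_n)}
                 {\ln \mu_b(t_n) - \ln \mu_a(t_n)}$$

runs until the update is below half a gray level (at most 100 iterations;
well-separated histograms converge in fewer than 20).  The test suite
checks the fixed point against an independent exhaustive scan of the
cross-entropy criterion over all 256 candidate thresholds: on two-level,
bimodal, overlapping and skewed histograms the iterate lands within one
gray level of an exhaustive minimiser.  When the two modes of a histogram
are separated by empty bins the criterion is exactly flat across the gap
(moving the threshold over empty bins changes no class statistics), so
any point of the plateau — the iterate lands mid-gap — is an equally
valid minimiser.

**Degenerate channels.**  A constant channel has no threshold; the
segmenter returns an empty mask with a warning rather than aborting a
batch, which matters for conditions where one species has been entirely
outcompeted.  A subtler failure is a channel containing *only noise*
(e.g. the channel of an absent species after crosstalk correction): Li
thresholding will happily split the noise band in half and report ~40% of
the stack as biofilm.  The segmenter therefore measures the contrast
between foreground and background means in units of the background SD and
treats the channel as signal-free below `minSeparation` (default 5).
Splitting pure Gaussian noise yields a contrast near 2.7 background SDs
regardless of the noise level, while any channel whose foreground is a
few-fold brighter than background scores far above 5, so the guard has a
wide safety margin on both sides.  Set `minSeparation = 0` to disable it.

**Blur default.**  The default sigma is 1 voxel in y and x and 0 in z,
reflecting that confocal z sampling is much coarser than the in-plane
resolution; both the sigma and fully 3D blurring are configurable.
Boundaries are handled by symmetric reflection, so constant regions pass
through unchanged.

## Quantification conventions

- "Cell ratio" is computed as the *volume share of segmented biovolume*
  — occupied voxels of a channel over the sum across channels — not as a
  cell count; nothing in the imaging pipeline resolves single cells.
- Masks are segmented independently per channel, so voxels can be claimed
  by several channels.  Each channel counts its own voxels, and the
  overlap fraction is reported so users can audit the double counting
  (exclusive synthetic scenes have overlap 0 by construction).
- Replicate SD uses the $n-1$ denominator; $n = 3$ positions per
  condition is the documented default of the study design.
- Welch's unequal-variance t-test is used for volume comparisons between
  conditions; identical groups return $t = 0$, $p = 1$, and two constant
  groups with different means are rejected as undefined.
- `layerOrder()` summarises vertical structure: occupancy-weighted mean
  z per channel and the channel's occupancy shares in the bottom, middle
  and top thirds of the *occupied z-extent* (not the full imaged stack,
  whose empty headspace above the biofilm would dilute the shares).  A
  channel whose bottom- and top-third shares both exceed its mid-third
  share is flagged "sandwich" — the operational version of one species
  colonising the layers around another.  The thresholds are deliberately
  simple and configurable; they operationalise a qualitative microscopy
  observation, nothing more.

## The synthetic scene generator

`makeScene()` realises species occupancies from geometry primitives —
full-width layers, laterally bounded slabs, exact-voxel-count bands,
spherical microcolonies, persistent-random-walk hyphal tubes, and
satellite attachment of one species to another's surface (a minimal
stand-in for rod-shaped cells docking onto hyphae; sufficient for imaging
tests, not for morphology research).  Species occupancies are pairwise
disjoint by default.  `renderScene()` pushes the truth through the
forward imaging model:

```
signal (lognormal brightness on occupied voxels)
  -> linear channel mixing by the true crosstalk matrix
  -> PSF-like Gaussian blur
  -> + constant background
  -> (optional Poisson shot noise) + Gaussian read noise
  -> clip at 0
```

Mixing precedes the blur because fluorophore emission mixes at detection
while the blur models optics; the background is added after mixing,
as an offset of the detection channel — mixing the offset itself would
make the calibration ratio differ from $k$ even on noise-free data.
Brightness is lognormal (sdlog 0.2 by default) to mimic expression
heterogeneity; the parameters are plausible defaults, not fitted values.

Default imaging conditions for the bundled presets: mean foreground
brightness 200 (arbitrary detector units, comfortably inside a 16-bit —
or 8-bit — range), background 8, symmetric crosstalk 0.05, in-plane PSF
sigma 1 voxel, Gaussian read noise SD 10, i.e. 5% of the mean foreground
brightness.  Preset grids are $64 \times 128 \times 128$ voxels
(z, y, x), with calibration controls on $32 \times 64 \times 64$ grids —
large enough that a ratio histogram has tens of thousands of foreground
voxels behind its mode, small enough that the full acceptance pipeline
runs in seconds on one CPU.

The presets encode the reported community phenotypes with ground-truth
shares taken from the printed composition ratios of the corresponding
strain pairs: `dual_sandwich` (K279a bottom + top bands around an SH1000
mid band, shares 76/24, the 24 h composition), `dual_layered` (thin
K279a bottom band under dominant PAO1, shares 7/93, the 72 h
composition), `exclusion_72h` (SH1000 absent, PAO1 100%),
`triple_layered` (stacked bands at 65.2/4.4/30.4, the 72 h triple
composition) and `dual_hypha` (hyphae with satellite attachment).  Exact
shares are achieved with full-width slabs and exact-voxel-count bands;
sharp slab boundaries also keep the segmentation error of the blurred
render near zero, which is what makes voxel-exact recovery a meaningful
test rather than a coincidence.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: depth-dependent attenuation and
scattering, axially varying (and non-Gaussian) PSFs, autofluorescence,
nonlinear detector response, matrix fluorescence between cells, and
growth-driven irregular colony boundaries.  Results on real stacks
should be sanity-checked against the reported thresholds and overlap
fractions in the run report.

## Worked example

```{r example}
preset <- biofilmPreset("dual_sandwich", seed = 1)
truth <- makeScene(preset$spec)
shares(truth)

rendered <- renderScene(truth, preset$model)
controls <- renderControls(preset$spec@species, preset$model, seed = 901)
k <- buildCrosstalkMatrix(controls)
coefficients(k)

corrected <- correctStack(rendered$stack, k)
masks <- segmentStack(corrected)
composition(masks)
layerOrder(masks)
```

The recovered composition matches the ground truth to well under a
percentage point under the default noise level, and the K279a channel is
flagged as the sandwich-forming species.

## File-based runs

`simulateCondition()` writes a preset condition to disk (16-bit TIFF
stacks, three replicate positions, single-label controls, ground-truth
CSV, manifest YAML), and `runPipeline()` consumes such a manifest:
calibration, correction, segmentation and quantification per replicate,
replicate averaging per condition, CSV tables plus a JSON run report
(version, seeds, thresholds, crosstalk matrix, overlap fractions,
warnings).  Conditions fail independently: one broken condition is
reported at the end while the others complete.  Identical manifest and
seed give byte-identical outputs; all randomness flows from explicit
seeds through one private RNG stream that never touches the caller's
`.Random.seed`.

## Known limitations

- Calibration requires dedicated single-label control stacks; estimating
  crosstalk from within a mixed image is not supported.
- Subtractive correction slightly over-subtracts where several bright
  channels coincide; use `method = "unmix"` when off-diagonal
  coefficients exceed about 0.1.
- The TIFF writer stores 16-bit integers; continuous-valued synthetic
  stacks are quantised (`quantizeStack()`) before writing, an error of at
  most half a gray level.
- Thresholding is global per channel by default; `perSlice = TRUE`
  thresholds each optical section independently, which tolerates depth
  attenuation but lets slice-to-slice threshold jitter into the
  profiles — prefer attenuation correction upstream when possible.
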