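# biofilmq

Quantification of multispecies biofilm structure from multichannel
confocal z-stacks.

Fluorescently tagged bacterial and fungal species growing together in a
biofilm are imaged by confocal laser scanning microscopy as 3D stacks
with one channel per fluorophore.  Extracting community structure from
such stacks — how much volume each species occupies, how it is layered
along z, and how the composition shifts over time — takes a short
analysis chain in which each step can bias the result.  `biofilmq`
implements that chain for R users working on microbial communities:

1. **Crosstalk calibration** — for each ordered dye pair, the
   bleed-through coefficient k[i→j] is the mode of the per-voxel ratio
   I<sub>unpopulated</sub>/I<sub>populated</sub> over the foreground of a
   single-label control stack;
2. **Crosstalk correction** — subtractive,
   I′<sub>j</sub> = max(0, I<sub>j</sub> − Σ<sub>i≠j</sub> k[i→j]·I<sub>i</sub>),
   or full linear unmixing;
3. **Segmentation** — Gaussian blur followed by automated Li minimum
   cross-entropy thresholding, one global threshold per channel, with
   guards that turn signal-free channels into empty masks instead of
   noise masks;
4. **Quantification** — per-z-slice and total biovolume fractions,
   species composition shares in percent ("cell ratios"), layer-order
   and sandwich descriptors, replicate mean ± SD (n − 1), and Welch
   t-tests between conditions.

A synthetic scene generator (`makeScene`, `renderScene`,
`biofilmPreset`) reproduces the characteristic community phenotypes —
distinct layers, triple-layer sandwiches, hyphae with attached satellite
cells, complete exclusion of one species — and renders them through a
linear bleed-through / PSF blur / noise imaging model, so every stage of
the pipeline can be validated against exact voxel-level ground truth.

## Worked example

A sandwich-structured dual biofilm (K279a colonising the bottom and top
bands around an SH1000 mid band, true shares 76/24) is generated,
rendered with 5% crosstalk, in-plane PSF blur and 5% Gaussian noise,
and then recovered by the full pipeline:

```r
library(biofilmq)

preset   <- biofilmPreset("dual_sandwich", seed = 1)
truth    <- makeScene(preset$spec)
rendered <- renderScene(truth, preset$model)

controls <- renderControls(preset$spec@species, preset$model, seed = 901)
k <- buildCrosstalkMatrix(controls)
k
#> CrosstalkMatrix (row = source, column = target):
#>         K279a SH1000
#> K279a  1.0000 0.0498
#> SH1000 0.0439 1.0000

corrected <- correctStack(rendered$stack, k)
masks <- segmentStack(corrected)
composition(masks)
#> CompositionSummary (percent of segmented biovolume):
#>  K279a SH1000
#>     76     24

layerOrder(masks)
#>   channel meanZ bottomShare  midShare  topShare sandwich
#> 1   K279a  24.5   0.4473684 0.1315789 0.4210526     TRUE
#> 2  SH1000  24.5   0.0000000 1.0000000 0.0000000    FALSE
```

The calibrated coefficients land on the true mixing value 0.05 to within
a histogram bin; the recovered composition matches the 76/24 ground
truth; and the layer descriptor flags K279a — and only K279a — as the
sandwich-forming species (its bottom- and top-third occupancy shares
both exceed its mid-third share).

File-based batch runs work from a manifest:
`simulateCondition("dual_sandwich", "mydir")` writes replicate TIFF
stacks, single-label controls, ground truth and a manifest YAML;
`runPipeline(readRunManifest("mydir/manifest.yaml"), config, "out")`
produces the CSV tables (per-slice profiles, compositions, replicate
summaries) and a JSON run report with thresholds, the crosstalk matrix,
overlap fractions and warnings.  A thin command-line wrapper lives in
`inst/scripts/biofilmq.R`.

## Package layout

- `R/` — S4 classes (`MultiChannelStack`, `CrosstalkMatrix`,
  `BinaryMask`, `SliceProfile`, …) and the pipeline stages;
- `vignettes/biofilm-quantification.Rmd` — the methods vignette: model
  assumptions, parameter defaults, numerical choices, what the synthetic
  generator does and does not emulate;
- `tests/testthat/` — unit, property and end-to-end recovery tests with
  independent oracles (exhaustive cross-entropy scan, closed-form
  statistics, voxel-exact ground truth).
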