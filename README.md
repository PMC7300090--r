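# histoquant

Quantitative image analysis of tumor-microenvironment architecture for R.

Tumor progression reorganizes the extracellular matrix: collagen fibers
change their alignment, length, width and bundling as tissue moves from
healthy to high-grade disease, and tumor cells shift their marker
expression (E-cadherin loss, N-cadherin gain, nuclear β-catenin, FAK) as
they adopt a mesenchymal phenotype. `histoquant` provides the complete
measurement chain used to characterize both sides of that interaction from
routine histology:

* **Collagen fiber architecture** — segment birefringent picrosirius-red
  (PSR) signal from polarized-light images, trace individual fibers by
  skeleton analysis, and summarize angle/length/width distributions with
  axial circular statistics (doubled-angle mean, resultant *R*, circular
  variance 1 − *R*) and Tukey box-plot summaries.
* **Collagen bundling** — hue-bin analysis of PSR signal (red/orange =
  bundled, mature; yellow/green = thin, reticular) and blue/red pixel
  ratios of Masson's trichrome.
* **IHC phenotyping** — Beer–Lambert stain deconvolution of dual-chromogen
  slides (`OD = Σ densities × stain vectors`, per-pixel inversion), cell
  segmentation into nucleus / membrane ring / cytoplasm, tumor gating by
  CK-18/Vector Red, and the per-marker positivity rules: nuclear (Ki67,
  β-catenin), complete-membrane via 36-sector coverage (E-cadherin, CD44,
  CD133), membrane-or-nuclear (N-cadherin), stained area fraction (FAK),
  and membrane+cytoplasm (Caspase 3).
* **Morphometry** — spheroid average diameter (mean Feret after
  protrusion-suppressing opening) tracked over time, and vessel-lumen
  counting.
* **Synthetic histology generator** — renders every modality (PSR fiber
  fields, trichrome, dual-chromogen IHC composed through the OD mixing
  model, spheroids, vessels) with exhaustive ground truth, so each stage
  is validated by parameter recovery.

## Worked example

Generate a moderately aligned fiber field, recover its architecture, and
score a synthetic Ki67 slide:

```r
library(histoquant)
cfg <- defaultConfig()

spec <- fiberFieldSpec(n_fibers = 200, image_hw = c(1024, 1024), seed = 42,
  angle_model = list(type = "von_mises_axial", mu_deg = 45, kappa = 4))
field <- simulateFiberField(spec)
mask <- segmentBirefringent(field$image, cfg)
fibers <- extractFibers(mask, cfg)
fibers
#> FiberSet with 157 fiber(s)
#>   median length 61.1 px, median width 5.59 px
#>   circular mean 44.5 deg, resultant R = 0.821
```

The generating model had its circular mean at 45° with lognormal lengths
(median 60 px) and widths (median 6 px); the recovered mean is 44.5°, the
resultant R = 0.821 reflects the κ = 4 concentration, and the medians land
within a few percent of the model. Box-whisker summaries flag outliers by
the 1.5 × IQR rule:

```r
s <- summarizeDistribution(fiberMeasurements(fibers)$width_px)
#> width: median 5.59 [q1 4.37, q3 6.35], 2 outliers
```

IHC scoring runs deconvolution → segmentation → gating → marker rule:

```r
ihc <- simulateIhcField(ihcFieldSpec(n_cells = 150, tumor_fraction = 0.7,
  marker = "Ki67", positive_fraction = 0.25, seed = 7))
dens <- deconvolveStains(rgbToOD(ihc$image), defaultStainVectors())
cells <- gateTumorCells(segmentCells(dens, cfg), dens$vector_red, cfg)
scoreMarker(cells, dens, "Ki67", cfg)
#> MarkerScore Ki67 (nuclear): 26 / 105 positive (0.248)
```

All 150 cells are found, 105/150 gate as tumor (the generated fraction was
0.7), and the recovered Ki67 fraction 0.248 matches the generated 0.25.

Real images enter the same way via `readRasterImage("slide.tif", "PSR")`
(TIFF/PNG, 8- or 16-bit); physical units come from `pixel_size_um`.

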