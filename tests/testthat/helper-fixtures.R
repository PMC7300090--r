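# Fixtures are generated in code; no image files are shipped.

# A single deterministic capsule: near-degenerate lognormals and a huge
# von Mises concentration pin angle, length and width to the given values.
capsuleFieldSpec <- function(width, angle, length = 100, hw = c(196, 196),
                             seed = 5, bundling = 0.5) {
  fiberFieldSpec(
    n_fibers = 1, image_hw = hw, seed = seed, bundling = bundling,
    angle_model = list(type = "von_mises_axial", mu_deg = angle, kappa = 1e9),
    length_model = list(mu_log = log(length), sigma_log = 1e-9),
    width_model = list(mu_log = log(width), sigma_log = 1e-9),
    background_noise_sd = 0)
}

# PSR-like image whose pixels carry exactly the requested hue fractions.
# The 160 x 160 frame makes every fraction of 25600 integral.
constructedHueImage <- function(fractions = c(0.40, 0.30, 0.20, 0.10),
                                hues = c(10, 35, 55, 100),
                                hw = c(160, 160)) {
  N <- hw[1] * hw[2]
  counts <- round(fractions * N)
  stopifnot(sum(counts) == N)
  hvec <- rep(hues, times = counts)
  rgb <- histoquant:::.hsv2rgb(hvec, 1, 1)
  px <- array(0, c(hw[1], hw[2], 3))
  for (ch in 1:3) px[, , ch] <- matrix(rgb[, ch], hw[1], hw[2])
  RasterImage(px, modality = "PSR")
}

# Full IHC scoring pipeline on a generated field.
runIhcPipeline <- function(spec, config = defaultConfig()) {
  field <- simulateIhcField(spec)
  dens <- deconvolveStains(rgbToOD(field$image), spec$stain_vectors)
  cells <- gateTumorCells(segmentCells(dens, config), dens$vector_red,
                          config)
  list(field = field, densities = dens, cells = cells,
       score = scoreMarker(cells, dens, spec$marker, config))
}
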