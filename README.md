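# clemquant

Quantitative analysis of electron-dense particle tags in correlative
light-electron microscopy (CLEM).

Genetically encoded ferritin tags label a protein of interest with a ~7 nm
electron-dense dot visible in transmission EM sections. `clemquant` turns
manual annotations of such micrographs — segmented membrane polylines,
coat/pit marks and particle centres — into the quantitative results a
labeling study needs:

* **Compartment densities** — particles classified into cytoplasm /
  membrane-proximal (50 nm zone) / coated regions; per-region areas by grid
  quadrature, volumes = area x section thickness (70 nm), densities from
  pooled counts, and condition comparisons by one-way ANOVA + Tukey HSD.
* **Stereological labeling test** — relative labeling intensity (RLI) after
  Mayhew & Lucocq: 24 interior points of an 8 x 6 overlay grid give expected
  compartment fractions, scaled to the observed particle total; enrichment
  is tested by Pearson's chi-squared with Yates' continuity correction on
  the 2 x 2 {observed, expected} x {cytoplasm, coated} table,

      chi^2 = sum (max(|O - E| - 1/2, 0))^2 / E,   df = 1.

* **Labeling resolution** — membrane-anchored tag geometry (length states
  7-18 nm, at most 22 nm; cone orientation with membrane exclusion) is
  simulated through EM-section detection, and distance distributions are
  summarized by median and kernel-density FWHM; per-particle SNR =
  |mean(disc) - mean(annulus)| / SD(annulus).
* **Pit mapping** — particles around clathrin-coated pits get normalized
  arc positions, pit/distal labels and membrane proximities, are projected
  onto an idealized 100 nm pit (each particle mirrored, so n particles give
  2n points), and pit-vs-distal proximity is compared by Welch's t-test.
* **Tagging kinetics** — two-channel live-cell stacks: Otsu spot detection,
  background-subtracted channel ratios per spot, median-zeroed traces with
  mean +/- SEM across cells, and a randomized-channel control.
* **Synthetic data** — annotated scenes and step-response stacks with known
  ground truth (Poisson particle placement at configurable per-region
  densities, tag-displacement draws, seeded and reproducible), so the whole
  pipeline is testable without any imaging data.

Input annotations use a model2point-style text dialect (`object contour x y
z` per line) plus a flat key-value metadata file per image; outputs are CSV
tables.

## Worked example

Generate a synthetic experiment at the published labeling regime
(cytoplasm 72.5 vs coated 1308.6 particles/um^3) and run the density and
stereology stages:

```r
library(clemquant)

anns <- lapply(1:6, function(s)
  generate_scene(scene_config(), seed = s, image_index = s)$annotation)

density_table(anns)$table[, c("region", "count", "volume_um3", "density")]
#>      region count volume_um3    density
#> 1 cytoplasm    26 0.31899280   81.50654
#> 2  membrane     1 0.01370544   72.96373
#> 3      coat    28 0.01849456 1513.95870

stereology_table(anns)[, c("n_images", "obs_cyto", "obs_coat",
                           "exp_cyto", "exp_coat", "chi2", "p_value")]
#>   n_images obs_cyto obs_coat exp_cyto exp_coat    chi2      p_value
#> 1        6       26       28 44.49438 8.033708 14.3068 0.0001553025
```

The recovered densities sit within counting error of the configured 72.5
and 1308.6 /um^3; the coated-region observed count (28) far exceeds the
grid-expected 8.0, and the Yates chi-squared (14.3, p ~ 1.6e-4) calls the
enrichment. The labeling-resolution simulation under the default tag model:

```r
simulate_detected_distances(tag_geometry_model(), 1e5, seed = 1)
#> <distance_sample> n = 100000, median = 10.52 nm, mean = 10.65 nm, FWHM = 9.23 nm
```

i.e. a detected particle sits ~10 +/- 5 nm from its anchor — the labeling
resolution this class of tag achieves.

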