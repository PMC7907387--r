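# msimaps

Preprocessing and spectral-similarity pseudocoloring for MALDI mass
spectrometry imaging (MSI), fully headless and scriptable.

MSI records one mass spectrum per pixel of a tissue section.  Before such
data can be explored, three problems must be dealt with: per-spectrum
intensity variability, the ubiquitous signal of the sprayed chemical
matrix (e.g. DHB) plus isolated hotspot artifacts, and the sheer channel
count.  `msimaps` addresses them in order — normalization, embedding-based
matrix/artifact subtraction, mean-spectrum peak picking — and then renders
*dynamic spectral-similarity maps*: pick a reference pixel `(q, r)` and
every pixel `(i, j)` is pseudocolored by the inverse angular distance of
its spectrum to the reference,

```
c'[i,j] = round( 255 * (1 - 2/pi * arccos( cos(p'[i,j], p'[q,r]) )) )
```

computed on an 8-bit byte representation `p'` (each spectrum scaled by
`255/max` — harmless here, since the angular measure ignores per-vector
scale).  The raw field is min-max normalized over the spectral pixels,
mapped through a "fire" or "gray" lookup table and written as PNG with a
256-bin histogram legend.  Regions that share a molecular co-location
profile with the reference light up, whatever channel they live on.

The package is aimed at MSI practitioners and imaging bioinformaticians
who want these operations reproducible in scripts and pipelines rather
than behind a GUI.  It reads and writes imzML (continuous and processed
mode), keeps datasets in a documented HDF5 store, and ships a synthetic
phantom generator with per-pixel ground truth so every stage can be
validated quantitatively.

## Worked example

```r
library(msimaps)

# a 64 x 64 phantom: tissue regions + border matrix + hotspot artifacts
ph <- make_phantom(phantom_spec(seed = 1))
ds <- ph$dataset
ds
#> <msi_dataset 'phantom'> 64 x 64 grid, 4096 spectral pixels, 500 m/z channels (100.0000-600.0000 Da)

# embed pixel spectra in 2-D and classify matrix/artifact pixels
emb <- embed_pixels(ds, seed = 1)
cls <- auto_classify(ds, emb)
cls
#> <pixel_classification> (auto) sample=2594, matrix=1340, artifact=162

# subtract the mean matrix spectrum from every pixel (clamped at zero)
cleaned <- subtract_class_mean(ds, cls, "matrix")

# picking at the same relative threshold finds more peaks afterwards:
nrow(detect_peaks(mean_spectrum(ds),      0.019, relative = TRUE))   # 26
nrow(detect_peaks(mean_spectrum(cleaned), 0.019, relative = TRUE))   # 39

# render a similarity map against a reference pixel inside a region
m <- render_map(to_bytes(cleaned), "similarity", ref = c(22, 22),
                out_prefix = "map")
m$raw$values[22, 22]   # 255 - the reference against itself
m$raw$values[43, 43]   # 1   - a pixel of the other region
```

The phantom plants 1340 true matrix pixels and 40 artifact hotspots
(the classifier above recovers the matrix band exactly and flags all
hotspots; the extra artifact labels are small embedding fragments).
Matrix subtraction raises the picked-peak count from 26 to 39 at the
same threshold (1.5x) and sharpens the similarity contrast: the fraction
of normalized similarity values in the middle of the histogram drops
from 0.91 to 0.32 for the same reference pixel.

A full pipeline run — convert, normalize, clean, pick, render, with a
JSON manifest of parameters, seeds and output hashes — is one call:

```r
run_pipeline(run_config(input = "phantom", seed = 1, out_dir = "out"))
```

or from the shell via the thin wrapper `inst/cli/msimaps`
(`msimaps run|synth|convert|normalize|clean|pick|render`).

See `vignettes/msimaps-methods.Rmd` for the models, parameter defaults,
numerical choices and known limitations.

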