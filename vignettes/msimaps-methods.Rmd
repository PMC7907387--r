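---
title: "Models and methods behind msimaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msimaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msimaps)
```

## The data model

A mass spectrometry imaging (MSI) dataset is a `w` x `h` grid of pixels in
which a subset `p+` of *spectral pixels* carries a mass spectrum of `d`
intensity values over a shared, strictly increasing m/z axis.  `msimaps`
stores this as a dense `|p+| x d` matrix plus a coordinate table
(1-based, `i` = column, `j` = row); pixels outside `p+` are implicitly
zero.  The same layout is used on disk: imzML/ibd for exchange and an
HDF5 store (`/<dataset_id>/mz`, `/coords`, `/intensities`, intensities as
32-bit floats) for fast multi-dataset access.  One indexing convention is
worth stating explicitly: channels, like pixels, are indexed from 1
throughout the package, including the `l`/`v`/`r` fields of picked peaks.

All downstream statistics operate on the spectral pixels only; the mean
spectrum is

$$\mu_k = \frac{1}{|p^+|} \sum_{(i,j) \in p^+} p_{i,j,k}.$$

## Normalization

MSI intensities carry a strong per-spectrum multiplicative component
(matrix crystal size, laser coupling, detector drift).  `intra_normalize()`
divides each spectrum by a scaling factor estimated as

* `mean` / `median`: mean or median of the spectrum's *nonzero*
  intensities.  Nonzero-only statistics are used because MSI spectra are
  sparse; the zeros would otherwise dominate the estimate.
* `mfc` (default): the median, over channels nonzero in both, of the fold
  change against the dataset's per-channel median spectrum.  We chose the
  nonzero-in-both restriction because a fold change against a zero
  reference channel is undefined and a zero sample channel carries no
  scale information.

A spectrum with no usable factor (all-zero, or sharing no nonzero channel
with the reference) is left unchanged with a warning rather than divided
by an arbitrary guard value.

`inter_normalize()` applies the same three estimators at the dataset
level: one factor per dataset, computed from its mean spectrum against a
cross-dataset reference.  The reference is the per-channel *lower* median
(the `floor((n+1)/2)`-th sorted value) of the dataset mean spectra.  With
an even number of datasets this keeps the reference at an observed value
rather than an average of two; a direct consequence is that identical
datasets all get factor 1 and, for two datasets where B = 3A, the factors
are exactly (1, 3).

`build_common_mz()` merges nearly identical channels across datasets by
pooling all channel masses, smoothing them with a Gaussian kernel density
of user-chosen bandwidth and placing one common channel at each density
mode (snapped to the nearest observed mass).  Two numerical guards
matter: modes closer than the bandwidth are merged (they are not
resolvable at that kernel width, and grid-level ripples on a flat-topped
mode must not split it), and maxima below $10^{-8}$ of the peak density
are discarded (the density underflows to numerical noise far from any
channel).  This is deliberately a simple alignment: it assumes the
instruments' mass error is well below the spacing of distinct ion
species, and it does not model mass drift within a run.

## Matrix and artifact removal

Spectral pixels fall into three categories: tissue (sample), chemical
matrix (e.g. DHB sprayed over the whole section, so its ions appear in
*every* spectrum but pure-matrix spectra appear only in the border area
around the tissue), and artifacts — isolated intensity hotspots whose
spectra resemble neither.

`embed_pixels()` projects the spectra to 2-D with UMAP; above 1000
channels a truncated SVD (default 100 components, `irlba`) runs first,
purely to cut the cost of neighbor search without visibly changing the
embedding.  UMAP runs single-threaded with a mandatory seed and its
library-default hyperparameters; duplicate spectra are collapsed before
the embedding and share one output point, which both saves time and makes
the "identical spectra embed identically" property exact rather than
approximate.

`auto_classify()` maps the embedding to labels with three rules whose
thresholds all sit in `clean_params()`:

1. **Hotspot rule (per pixel).**  A pixel whose spectrum has angular
   distance $1 - \cos$ above `hotspot_cos` (default 0.15, a spectral
   angle of about 32 degrees) to the median spectrum of its up-to-8
   spatial neighbors is an artifact.  This is the operational definition
   of an "isolated intensity hotspot", and it is robust to where UMAP
   happens to place such a pixel: a tight clump of hotspots that the
   neighbor graph pulls into a larger cluster is still caught.  For
   scale, tissue-boundary pixels on the validation phantoms stay below
   0.05 while planted hotspots exceed 0.29.
2. **Cluster rules.**  The embedding is clustered with DBSCAN (in-package
   implementation; radius defaults to 5% of the embedding span — UMAP
   packs clusters densely and separates them by distances on the order of
   the span, so a span-relative radius transfers across datasets).
   DBSCAN noise points, clusters spatially scattered over the grid (mean
   within-cluster nearest-neighbor distance above `hotspot_dist` = 3 px)
   and tiny clusters (below 1% of `|p+|`) are artifacts.
3. **Border rule.**  Among the remaining clusters, *every* cluster with
   at least 10% of its pixels on the 2-px border frame is matrix.
   Accepting several clusters matters: residual per-spectrum scale
   variation can stratify the pure-matrix band into parallel embedding
   clusters, and insisting on a single winner would leave most of the
   band mislabeled.

Everything else is sample.  If DBSCAN finds fewer than two clusters the
cluster and border rules cannot separate anything; the classifier then
labels everything except hotspots as sample and warns.

Subtraction follows the category semantics: the mean spectrum of the
matrix pixels is subtracted channel-wise from **all** spectral pixels
(matrix ions sit in every spectrum, including the matrix pixels
themselves) and negative results are clamped to zero.
`iterative_clean()` runs artifact removal first and re-embeds before
matrix detection, because strong artifacts can stretch the embedding and
blur the sample/matrix separation; with no artifacts found, it reduces
exactly to the single-pass pipeline.

These heuristics are this package's own automatic rules, designed from
the physical description of the categories; interactive review remains
the gold standard for sensitive data, and `classify_by_selection()`
(polygon in embedding space, or an explicit coordinate list) plus the
PNG/CSV label masks provide the headless equivalent.

## Peak picking

Peaks are picked on the mean spectrum only — never per pixel.  A peak is
a strict local maximum of $\mu$ above the threshold `z_t`; for a flat
apex run the leftmost channel is the apex (a fixed tie-break keeps the
result deterministic).  The extent $[l, r]$ is the contiguous run of
channels with $\mu \ge 0.5\,\mu_{apex}$ around the apex — an FWHM-style
reading; "the first channel at 50%" could also be read as "the first
channel *below* 50%", and we document our choice rather than claim it is
canonical.  The representative channel $v$ is the integer median of
$\{l,\dots,r\}$, lower-middle for even runs.  Where the extents of
adjacent peaks would overlap, both are truncated at the valley minimum
between the apexes (valley channel to the left peak), so peak intervals
partition cleanly and per-pixel peak intensities
$\rho_{i,j,v} = \sum_{u=l}^{r} p_{i,j,u}$ never double-count a channel.

`winsorize_mean()` caps the mean spectrum at its `z_w`-th highest value
before threshold selection, so a handful of towering channels does not
dictate the visual scale on which `z_t` is judged.  `deisotope()` removes
isotope satellites greedily: peaks are visited by descending height
(ties: lower mass first, so the monoisotopic peak of an equal-height pair
survives), and each kept peak at mass $m$ removes not-yet-kept peaks
within `tol` of $m + n \cdot 1.00335$ Da, $n \le$ `max_iso`.  Charge 1 is
assumed (appropriate for MALDI); the spacing is configurable.

## Similarity rendering

Rendering works on an 8-bit representation: each spectrum is scaled by
$255/\max$ and rounded (half away from zero — platform-independent
determinism), which caps the per-spectrum intensity resolution at 256
distinct values.  Because the similarity measure below is angular, i.e.
invariant to per-vector scale, this per-spectrum scaling cannot distort
Similarity mode; on the default phantom the Pearson correlation between
byte-based and full-precision similarity fields exceeds 0.999.

Similarity mode assigns each pixel the inverse angular distance to a
chosen reference pixel $(q, r)$:

$$c'_{i,j} = \left[\,255\left(1 - \frac{2}{\pi}
  \arccos \frac{p'_{i,j} \cdot p'_{q,r}}
               {\lVert p'_{i,j}\rVert\,\lVert p'_{q,r}\rVert}\right)\right]$$

so a pixel equals 255 against itself and 0 when orthogonal.  Zero-norm
pixels (and non-spectral positions) map to 0 — maximally dissimilar,
matching the black background.  Browsing mode shows one byte channel;
grouping mode the rounded mean over a channel set, which for a singleton
set reduces exactly to browsing.  (Taking the plain mean of byte values
keeps grouping inside 0..255; multiplying a byte mean by another factor
of 255 would overflow the byte range, so the two modes could not agree on
singleton sets.)

The raw field is min-max normalized to $c'' = 255\,(c' - \min)/(\max -
\min)$ over the spectral pixels only — including the implicit zeros of
non-spectral pixels would pin the minimum at 0 and waste contrast; a
constant field maps to all zeros.  The result passes through a 256-entry
color lookup table: `"gray"` is bit-exact on the value channel, `"fire"`
runs black, red, yellow, white with linear RGB interpolation between
stops at 0, 96, 192, 255.  These stops are this package's documented
stand-in for the classic Fire scale, whose exact control points vary
between implementations.  The 256-bin histogram of $c''$ always sums to
`|p+|`.

## The phantom generator

`make_phantom()` builds validation data with known truth: a border band
of pure matrix spectra; two circular tissue regions plus a background
tissue, each with its own peak channels (Gaussian peaks of width 1
channel, two isotope satellites at ratio 0.5 per +1.00335 Da step); a
dominant matrix signal (height 4 vs tissue height 1) added to *every*
pixel, since the matrix is sprayed over the whole section; 40 artifact
hotspots in 4 spectral types (hotspots of one physical cause share spike
channels) at 10x the tissue peak height; a log-normal per-spectrum scale
(sigma 0.2) emulating the intensity variability that normalization
addresses; and additive Gaussian noise (sigma 0.02, i.e. 2% of a tissue
peak).  The default grid is 64 x 64 with 500 channels over 100-600 Da —
large enough that embedding, clustering and rendering behave as on real
data, small enough that the full validation suite runs in minutes on one
CPU.

Two RNG streams are used: artifact *positions* come from a fixed internal
stream, so different user seeds change noise, scales and spike channels
but never the truth geometry; everything else derives from the user seed,
and a fixed seed reproduces the dataset bit for bit.

What the phantom deliberately does not emulate: mass-accuracy drift,
laser ablation patterns, detector saturation, chemical noise baselines,
and spatial intensity gradients.  Tests passing on phantoms therefore
validate the algorithmic contracts (recovery of planted structure,
invariances, determinism), not instrument-level robustness.

## Problem sizes and numerical choices

The validation suite exercises the full 64 x 64 x 500 phantom for the
recovery, contrast and fidelity experiments and 28 x 28 x 120 phantoms
for the faster unit checks.  Peak-picking correctness is established
against a brute-force quadratic oracle on 200 random spiky spectra over
ten seeds.  Determinism is asserted at the byte level for rendered PNGs
and at bit level for phantom intensities.

Degenerate inputs are handled explicitly rather than by accident:
all-zero spectra survive normalization and the byte transform unchanged;
constant fields normalize to zero; datasets with fewer than four distinct
spectra skip UMAP and embed at fixed points; an empty selection, an empty
peak set, a missing `.ibd`, or a store with a foreign schema tag raise
errors that name the problem.

## Known limitations

* The common-axis builder is a deliberate simplification of kernel-based
  spectral alignment; it has no model of per-run mass drift.
* The automatic classifier's thresholds are calibrated on phantom-like
  structure (contiguous tissue, border matrix, isolated hotspots);
  tissue sections whose matrix area does not touch the image border, or
  hotspot artifacts milder than a ~32 degree spectral angle, need either
  adjusted `clean_params()` or interactive selection.
* Matrix subtraction can, in principle, remove genuine tissue signal that
  co-occurs on matrix channels; the package always leaves the original
  store untouched so analyses can return to unprocessed data.
* Peak picking is local-maximum based by design (fast, interactive-grade);
  it does not fit peak shapes or areas.
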