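---
title: "Quantifying processing bodies and phase-separated droplets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying processing bodies and phase-separated droplets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pbquant quantifies two kinds of fluorescence microscopy experiments from
processing-body (PB) biology in budding yeast:

* **in vivo**: widefield images of cells expressing GFP/mCherry-tagged PB
  components (Dhh1, Pat1, Dcp2, ...). The quantities of interest are the
  number of PB foci per cell, the colocalization of foci between two
  channels, and the ratio of two proteins' PB intensities over a starvation
  time course (their in vivo stoichiometry).
* **in vitro**: confocal images of liquid-liquid phase-separated droplets
  reconstituted from purified proteins and RNA. The quantities are an
  area-times-intensity condensation metric, per-droplet protein
  concentrations read off a linear calibration curve, the two-protein
  stoichiometric ratio, and droplet size distributions.

Raw microscopy for such studies is rarely deposited, so the package carries
a seeded synthetic-scene generator with complete ground truth, and every
stage is validated by parameter-recovery experiments on those scenes.

## Cell segmentation by edge-normal voting

Yeast cells in a cytoplasmic-fluorescence channel are bright convex blobs
(4--6 µm across) on a dark background. Segmentation proceeds in four steps:

1. **Edge detection.** The image is smoothed with a Gaussian
   (`edge_sigma_px`, default 3 px) and edges taken as zero crossings of the
   Laplacian of the smoothed image. Each crossing carries the local gradient
   direction, oriented dark-to-bright, i.e. pointing into the cell. Zero
   crossings whose gradient magnitude falls below `magnitude_quantile`
   (default 0.85) of all crossings are discarded: under shot noise the
   crossing population is dominated by near-flat noise ripple, and the
   strong-gradient tail is almost exclusively true cell boundary. On *clean*
   (noise-free) images this relative filter instead throws away true edge
   pixels of the dimmer cells -- for such data a lower quantile (0.15--0.3)
   should be set explicitly.
2. **Normal voting.** Every edge pixel casts one vote along the ray in its
   gradient direction at integer distances `r_min_px..r_max_px`
   (defaults 1.5--3.2 µm converted by the pixel size). Rays from a convex
   boundary converge at the cell centre. Votes are cast only dark-to-bright
   (into the interior), halving spurious votes compared with bidirectional
   casting. The accumulator is smoothed with a sigma-2 px Gaussian and
   rescaled by 2*pi*sigma^2 so its values stay on a local-vote-count scale.
3. **Seed finding.** Accumulator local maxima at or above `min_votes` are
   kept after greedy non-maximum suppression within `nms_radius_px`,
   strongest first, ties broken by (row, col). The derived `min_votes`
   default is 0.3 * 6 * 2*pi*r_min_px: requiring ~30% of an r_min perimeter
   to vote, where one perimeter pixel deposits ~6 accumulator counts (the
   Laplacian yields a double edge, and ~3 consecutive ray steps land within
   the smoothing window of the centre). When `min_votes` is left to be
   derived it is additionally capped at half the accumulator maximum, which
   keeps clean low-vote images (where the quantile filter leaves few edge
   pixels) workable without affecting noisy ones. The NMS radius defaults to
   the mid-radius (r_min+r_max)/2.
4. **Reconstruction.** Each seed grows over pixels brighter than the
   midpoint of the seed's level (median of a 5 px disc, robust to a focus
   sitting on the seed) and the image's background mode (histogram mode,
   256 bins); growth is halted at edge pixels, and competing claims are
   resolved by geodesic distance to the seed (`EBImage::propagate`). Edge
   pixels adjacent to a grown region are then folded back into it -- they
   *are* the cell boundary -- otherwise areas are depleted by a one-to-two
   pixel ring (~20% for these cell sizes). Regions outside
   `[min_cell_area_um2, max_cell_area_um2]` (defaults 3--40 µm²) are
   discarded; border-touching cells are flagged and excluded from counts
   when `exclude_border` is set (default), since partially visible cells
   would bias the per-cell focus rate.

On synthetic fields with shot noise (interior/background contrast >= 3,
peak SNR >= 10) this recovers planted counts of 1--50 cells exactly in
>= 95% of seeded trials (`cell_count_experiment`).

## Focus detection

PB foci are diffraction-limited spots riding on the bright cytoplasm.
Candidates are local intensity maxima (strictly greater than every pixel
within `maxima_radius_px`, plateaus collapsed to their lexicographically
smallest member; a flat field has no candidates). Each candidate is
measured on a disc/annulus geometry:

* background = median of the annulus `[r_bg_in, r_bg_out)` (defaults 3 and
  5 px);
* peak = maximum of the disc `< r_int` (default 2.5 px);
* integrated intensity = background-corrected sum over the disc;
* contrast = (peak − background) / background;
* subpixel centroid = centre of mass of the background-subtracted
  (clamped at zero) disc pixels.

Retention requires peak >= `intensity_min` AND contrast >= `contrast_min`,
both inclusive; the contrast default is 0.05 (5%), and a focus at exactly
5% contrast is kept. `intensity_min` defaults to the image median plus
3 MAD-based noise standard deviations -- an absolute counts threshold would
be instrument-specific.

Before detection the frame is smoothed with a 1.5 px Gaussian
(`smooth_sigma_px`), an approximate matched filter for the ~1.3 px PSF.
This matters quantitatively: on raw shot-noise images, noise bumps inside a
400-count cytoplasm reach 5--12% contrast (the disc maximum rides the noise
tail, and for candidates within ~7 px of the cell boundary the annulus
median dips into the PSF falloff), which floods detection with false
positives. After matched filtering, noise bumps stay well under the 5%
cutoff while true foci at peak SNR 5 retain ~15% contrast; measured
precision and recall are both >= 0.95 over 20 seeded fields
(`focus_detection_experiment`). The compact annulus `[3, 5)` keeps the
background estimate local enough not to straddle the cell edge for most
interior positions. Note the integrated intensity under smoothing is
attenuated by a fixed geometric factor; all downstream uses are ratios or
rank statistics, for which a common factor cancels.

Colocalization matches foci across two channels greedily over all
cross-channel pairs by ascending centroid distance, one-to-one, accepting
pairs within `d_max_um` (default 0.25 µm, sub-resolution at these optics).
On well-separated instances this equals the exhaustive optimal assignment
(`coloc_matching_experiment`). The headline "PB count" of a two-channel
image is the colocalized count; per-channel counts are also reported.
`PBs_per_cell` divides that count by the number of retained cells; images
with zero cells are flagged and excluded from aggregates.

## In vivo stoichiometry: top-k median

Two strains carrying the same fluorophore on different proteins, imaged
under identical settings, have intensity ratios equal to abundance ratios
(no spectral correction needed). Per image, the k = 10 brightest foci by
integrated intensity are taken; per condition and timepoint these top-k
sets are pooled and their median is the condition's representative
intensity; the reported ratio is median_A / median_B. The per-image (rather
than pooled-first) ranking matches acquisitions guaranteeing at least 10
foci per image, and `pool_first = TRUE` provides the alternative reading.
Images with fewer than k foci are an error unless `use_all` is enabled
(flagged in output). The even-k median is the mean of the central pair.
When replicate labels are present, the dispersion is the standard error of
replicate-level ratios.

Planted ratios of 1, 2 and 3 are recovered within 10% from images at peak
SNR 10 (10 images/timepoint, ~15 foci/image, 5 seeds;
`invivo_ratio_experiment`), covering the 2:1 to 2.5:1 regime typical of
Dhh1:Pat1 measurements.

## In vitro droplets

Droplets are segmented on one channel by Otsu threshold (or `fixed:<v>`),
8-connected components, and a minimum-area filter (default 9 px). The
per-channel background -- the median of non-foreground pixels -- is
subtracted from droplet mean intensities, putting them on the same
background-free scale as `slope * concentration` from the calibration
model.

* **Condensation metric**: sum over droplets of background-subtracted mean
  intensity times area in pixels, i.e. integrated excess fluorescence in
  the dense phase. The background subtraction makes the metric additive
  over disjoint fields and offset-invariant, and normalization to a named
  reference condition makes it invariant to global intensity rescaling.
* **Calibration**: ordinary least squares of homogeneous-solution mean
  intensity on concentration; exact on collinear input. Concentrations
  invert the line; values outside the calibrated range are flagged as
  extrapolated. Droplet concentrations use the droplet *mean* intensity,
  matching the homogeneous calibration geometry.
* **Stoichiometry**: per-droplet concentration ratios, reported as
  mean ± sd with droplets of non-positive denominator concentration
  excluded and counted. Planted ratios 1, 2 and 2.7 are recovered within
  10% at 5% signal noise over 50 droplets (noiseless: exact).
* **Size distributions**: equivalent diameters 2*sqrt(area/pi), binned
  half-open with a fixed bin width.

## The synthetic generator

The generator is first-class, tested code; its defaults are the study
conditions for every validation experiment.

* **Optics**: widefield profile 0.13 µm/px (100x objective, 6.5 µm sCMOS
  pixels with 2x2 binning -- a standard live-yeast acquisition; the actual
  camera binning of such datasets is rarely reported) and confocal profile
  0.18 µm/px. PSF modelled as an isotropic Gaussian, sigma 1.3 px.
* **Cells**: non-overlapping ellipses (rejection sampling, centre spacing
  >= 2.2 r_max), semi-major axis 2--3 µm, axis ratio <= 1.3, uniform
  interior level 300--500 counts on a 100-count background -- contrast >= 3
  as the segmenter assumes.
* **Foci**: analytic Gaussian spots planted strictly inside cells, at
  least 6 px apart. Two sigma-1.3 px spots less than ~2 FWHM apart merge
  into a single intensity maximum and are one focus to any detector, so the
  generator never plants sub-resolution pairs. Colocalized partners sit at
  the channel-1 position plus 0.5 px Gaussian jitter, with amplitude
  divided by the planted channel ratio.
* **Noise**: Poisson shot noise on expected counts followed by additive
  Gaussian read noise (sd 2 by default), both optional -- the sCMOS noise
  model. Peak SNR statements refer to amplitude over the local shot-noise
  sd (~20 counts at a 400-count interior).
* **Droplets and calibration fields**: sharp discs at
  `slope*c + intercept` on an `intercept`-level background; uniform fields
  for the calibration series.
* **Time lapses**: static cells; per-frame Poisson focus counts with the
  scheduled mean.

Determinism is pixel-exact under a fixed seed; generators restore the
caller's RNG state. What the generator does **not** emulate: optical
aberrations and depth-dependent PSFs, photobleaching, stage drift, cell
growth, budding necks, vacuole-dark interiors, autofluorescence texture,
and non-circular droplet coalescence. Passing recovery tests on these
scenes therefore demonstrates correctness of the *computations* under the
stated image model, not robustness to every artefact of real microscopy.

## Numerical choices and degenerate inputs

* Pixel coordinates are 0-free (row, col) 1-based in R; disc membership is
  Euclidean `< r` (half-open), annuli `[r_in, r_out)`.
* Intensities are handled as doubles, never rescaled; 8/16-bit TIFF
  round-trips are exact on integer data.
* A constant image yields zero edges, zero cells, zero foci -- never an
  error. Machine-epsilon Laplacian ripple on noise-free flats is dropped by
  an absolute floor (1e-9 of the dynamic range) before the magnitude
  quantile.
* Ranking and NMS ties break by (row, col) ascending; matching ties by
  channel-a then channel-b centroid, making orders total and runs
  bit-reproducible.
* Experiments derive per-stage seeds from the master seed by a stable
  integer hash (`derive_seed`), so stages can be rerun alone.

## Problem sizes

Validation experiments use: 20 seeded trials per cell count in {1, 5, 20,
50}; 20 fields for focus detection (6 cells x 3 foci, peak SNR 5) and for
colocalization (20 pairs + 5 decoys/channel); 5 seeds x 10 images x ~15
foci for each planted in vivo ratio; 50 droplets x 5 seeds per in vitro
ratio; 8-point calibration series. These sizes hold the Monte-Carlo error
of each recovered quantity comfortably inside its stated tolerance while
keeping a full validation run in the low minutes on one core.

## Known limitations

* The magnitude-quantile edge filter assumes noise outnumbers signal among
  zero crossings; on clean synthetic images it must be relaxed by hand.
* Segmentation does not split touching cells or budding pairs; the
  generator's non-overlap matches its scope.
* Focus intensities are attenuated by matched filtering and disc
  truncation by a common geometric factor; absolute (single-channel,
  unratioed) intensities should not be compared across different geometry
  settings.
* Droplet analysis is 2D; concentrations assume droplets thicker than the
  confocal section.
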