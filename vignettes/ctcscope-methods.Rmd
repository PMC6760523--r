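---
title: "ctcscope: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctcscope: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcscope)
```

ctcscope re-implements, as a tested library, the software stack of an
automated widefield fluorescence microscope for enumerating circulating
tumor cells (CTCs) retained on a microfiltration membrane: the camera
signal/noise model, the four-channel classification and counting
pipeline, a brightness-based autofocus, and tile mapping/stitching.
Because the instrument's raw membrane images are not publicly deposited,
the package ships a ground-truthed synthetic membrane simulator (a
virtual microscope) that stands in for the hardware; every stage of the
pipeline is exercised end to end against the simulator's known truth.
This vignette records the models, the tunable parameters and the design
choices, and what the synthetic validation does and does not establish.

## Camera model

The expected signal collected by one pixel in exposure time $t$ is

$$S(t) = \gamma\,\delta^2\,\mathrm{QE}\,t \quad [e^-],$$

with photon flux $\gamma$ (photons µm⁻² s⁻¹), pixel pitch $\delta$ and
quantum efficiency QE. Uncorrelated noise sources add in quadrature,

$$N = \sqrt{\sigma_{\mathrm{camera}}^2 + \sigma_{\mathrm{shot}}^2},
\qquad \sigma_{\mathrm{shot}} = \sqrt{S},$$

where $\sigma_{\mathrm{camera}}$ lumps dark and read noise into a single
configured constant; its temperature and exposure dependence is not
modelled, since only the combined figure (3.30 e⁻ for the reference
sensor) enters any downstream computation. The *noise-equivalent photon
floor* is the signal at which $S = N$; the positive root of
$S^2 = \sigma^2 + S$ gives

$$S^\ast = \tfrac12\left(1 + \sqrt{1 + 4\sigma_{\mathrm{camera}}^2}\right),$$

converted to photons by dividing by QE:

```{r}
cam <- camera_spec()  # QE 0.79, pixel 2.4 um, sigma 3.30 e-, 4x4 binning
noise_equivalent_photons(cam)
```

With the defaults this evaluates to about 4.86 photons; the instrument's
published figure of 4.83 corresponds to an unrounded quantum efficiency
(QE ≈ 0.794 reproduces it exactly), so agreement is expected only to
about 1% and the package does not force it closer.

Object-space geometry derives from the field of view and frame
resolution (818 × 547 µm at 1368 × 912 px, i.e. ≈ 0.359 µm²/px).
`circle_area_px()` converts a minimum cell diameter to the pixel-area
gate used by the classification rules, rounding half away from zero and
multiplying the x and y pixel pitches; under this convention the 7 µm
and 2.5 µm diameters map to 107 and 14 px, the two gates used
throughout:

```{r}
circle_area_px(c(2.5, 7), optics_geometry())
```

Digital numbers are electrons divided by the conversion gain
(default 1 e⁻/DN), rounded, and clipped to $[0, 2^{\mathrm{bits}}-1]$.

## Synthetic membranes and the virtual microscope

`make_scene()` draws a ground-truthed cell population on a membrane of
given extent. Its defaults are the package's fixed study conditions:

* **Phenotypes.** CTCs emit in the nuclear (blue), cytokeratin (green)
  and PSMA (orange) channels and are dark in the CD45 (red) channel;
  WBCs emit in blue and red; other nucleated cells only in blue.
  Consistency between phenotype and emission is enforced at
  construction.
* **Diameters.** Uniform per phenotype: CTC 8–16 µm, WBC 6–12 µm,
  other nucleated 4–8 µm. The floors sit clear of the 7 µm / 2.5 µm
  counting gates because thresholding erodes the measured area of cells
  near a gate (see below); cells at the gate boundary are a documented
  failure mode of the counting design, not the subject of the recovery
  studies.
* **Brightness.** Per-channel peak fluxes (blue 20000, green 8000,
  orange 600, red 10000 photons µm⁻² s⁻¹, per phenotype as applicable)
  are chosen so that, at the default per-channel exposures
  (blue 50 ms, green 100 ms, orange 1.5 s, red 100 ms), peak cell
  signals are ~4000–4600 e⁻ — bright immunostained cells well above
  the few-photon noise floor, on a membrane autofluorescence background
  of ~9–10 e⁻/px. Per-cell, per-channel brightness varies log-normally
  (sdlog 0.2).
* **Placement.** Uniform with an optional minimum centre separation
  (rejection sampling with a bounded retry count and an explicit
  failure), and a 12 µm edge margin.

Cells are rendered as spheres: the projected fluorophore column density
of a uniformly stained sphere of diameter $d$ is the chord length
$\sqrt{1-(r/R)^2}$, scaled to the cell's peak flux. Defocus is a
Gaussian blur whose width grows linearly with the axial distance between
the stage and the cell's focal plane,
$\sigma(z) = \sigma_0 + s\,|z - z_{\mathrm{cell}}|$ (defaults
$\sigma_0 = 0.5$ µm, $s = 0.3$ per µm of defocus). Two properties of
this combination matter downstream:

* the blur redistributes but conserves flux (verified to 1% away from
  image borders), and the peak amplitude decreases *strictly* with
  defocus at every scale — a flat-top disc profile would make the
  brightness autofocus metric insensitive to small defocus after 16-bit
  quantisation, which is why the spherical profile is used;
* the thresholded area of a cell imaged at threshold fraction $f$ of
  its peak is $\pi (d/2)^2 (1 - f^2)$, so the pixel-area gates remain
  meaningful as long as cells are not marginal relative to the gate.

Pixel values follow the camera model: the expected electron count per
pixel is background plus cell contributions; noise draws
$\mathrm{Poisson}(S) + \mathcal{N}(0, \sigma_{\mathrm{camera}})$
electrons before quantisation. (Detecting each of
$\mathrm{Poisson}(N_\gamma)$ photons with probability QE yields exactly
$\mathrm{Poisson}(\mathrm{QE}\,N_\gamma) = \mathrm{Poisson}(S)$, so the
rendered background reproduces both the mean of the signal equation and
the variance of the noise equation — this is asserted against the
closed forms at $10^5$ pixels.)

Coordinates are stated once and used everywhere: sample-frame positions
are µm with origin top-left and y downward; pixel indices are 0-based;
`virtual_acquire()` treats the stage position as the *centre* of the
captured field of view, so a cell at the stage position appears at the
image centre and stepping the stage by one field of view produces
abutting tiles. Stage error is modelled as a uniform displacement within
± the stage's bi-directional repeatability (2.2 µm for the reference
stage) per axis, which keeps the placement error bounded as a
repeatability specification implies.

All randomness is seeded: a fixed seed reproduces scenes, renders and
reports bit-identically, and the CLI requires `--seed` for simulation.

## The classification pipeline

`classify_and_count()` implements the six-step recognition scheme:

1. acquire one grayscale image per channel (a "snap");
2. denoise each channel with a 3×3 median filter (edge-replicated) and
   stretch contrast with a window/level mapping anchored at the 1st and
   99.5th intensity percentiles;
3. compose each phenotype's *classification mask* by pixel-wise channel
   arithmetic — the sum of the rule's required channels minus the sum of
   its excluded channels, saturated to the dtype range;
4. threshold the mask with Otsu's method (from scratch over the
   intensity histogram: maximise the between-class variance
   $\omega_0\omega_1(\mu_0-\mu_1)^2$ with class 0 the pixels at or below
   the threshold; ties resolve to the smallest threshold; a constant
   image is flagged non-separable);
5. extract 8-connected components (area = foreground pixel count,
   centroid = pixel-centre mean, border components kept) and discriminate
   by size — strictly greater than the pixel area of the rule's
   minimum-diameter circle — and by per-channel coincidence;
6. label the surviving components and render a colorized overlay.

Rules are applied in priority order (CTC first); a component that
contains the centroid of a higher-priority detection is withheld from
lower-priority rules, so a WBC that leaks into the nucleated-cell mask
(bright blue minus dimmer red can remain positive) is not double
counted. The default four-color rule set is: CTC = blue+green+orange,
red-excluded, ≥ 7 µm; WBC = blue+red, green/orange-excluded, ≥ 2.5 µm;
remaining blue-only objects ≥ 2.5 µm are other nucleated cells. The
two-color mode reuses the machinery with CTC = orange+blue ≥ 7 µm and
nucleated = blue ≥ 2.5 µm.

Two numerical choices deserve explanation, both config-exposed in
`pipeline_config()`:

* **Window floor** (`window_min_span_frac`, default 0.05). Automatic
  percentile anchors assume the image has real foreground. On a channel
  with none (e.g. the green channel of a field without CTCs) both
  anchors land inside the background noise and a pure percentile
  stretch amplifies that noise to full scale, which destroys the mask
  subtraction and the coincidence test. The stretch window is therefore
  never allowed to shrink below 5% of the dtype range; channels with
  real signal are unaffected (their windows are wide), while empty
  channels stay compressed near zero.
* **Coincidence criterion** (`coincidence_frac`, default 0.5). A
  component keeps its label only if it is *expressed* in every required
  channel and *dark* in every excluded channel. Darkness is tested as
  mean intensity ≤ the channel's Otsu threshold. Expression is tested
  against the midpoint between the channel's background (median) and
  its Otsu threshold rather than the threshold itself: with log-normal
  brightness variation a global Otsu threshold sits above the mean of
  legitimately dim cells, and the stricter test produced ~4% false
  negatives on ground-truthed scenes. The midpoint keeps dim-but-real
  cells while still rejecting components whose mean sits at the
  background level.

Degenerate inputs are handled explicitly: a constant channel passes
through window/level unchanged (with a warning), a non-separable mask
yields no detections, an empty snap yields an all-zero report, and
filtering at gate 0 conserves every extracted component.

Known limitations mirror the counting design: touching cells merge into
one contour (two CTCs closer than one radius are counted as one — this
is asserted in the tests as documented behaviour, not corrected), and no
channel-crosstalk compensation or machine-learning classifier is
included.

## Autofocus

The brightness metric scores an image by its maximum pixel value after a
3×3 median denoise (hot-pixel robust; flagged if the image saturates the
digitiser, since saturation caps the metric). In-focus cells concentrate
their light, so on noise-free stacks the metric is unimodal in z with its
maximum at the focal plane. `autofocus_search()` runs a coarse pass of
`n_coarse` equidistant acquisitions over the predefined range (default
15, the instrument's per-snap sampling count), then a fine pass of
`n_fine` acquisitions over ± one coarse step around the coarse optimum;
ties resolve to the lowest z and the search issues exactly
`n_coarse + n_fine` acquisitions. A normalised-variance contrast metric
(variance/mean) is provided for comparison; on sparse fields the
brightness metric's focus error does not exceed the contrast metric's
over seeded noisy stacks — consistent with brightness-based focusing
being the more robust choice for nearly empty membranes.

## Mapping and stitching

`plan_grid()` covers a requested extent with
`ceiling(extent / fov)` abutting tiles traversed serpentine-fashion
(stage targets at tile centres); `stitch()` places tiles at exact grid
offsets with no overlap, registration or blending, relying on stage
repeatability as the instrument does, so the panorama is exactly
(rows·tile_h) × (cols·tile_w) pixels and a whole-scene render equals its
stitched tiles pixel-for-pixel in noise-free, zero-jitter mode.
`run_mapping()` drives the virtual microscope over the grid (optional
per-tile autofocus on the blue channel), classifies each tile, and
aggregates per-tile reports into membrane totals; edge tiles may
overhang the membrane and image background. Detections are *not* merged
across tile seams: a seam-straddling cell may be counted once or twice,
a documented bias of per-snap counting.

## What the synthetic validation shows — and what it does not

On seeded synthetic membranes at the full frame size (1368 × 912 px,
5 CTC + 100 WBC + 200 other nucleated cells, centre separation above
the sum of radii), the pipeline recovers every phenotype count exactly
without noise, and with the full noise model recovers ≥ 95% with no
CTC↔WBC confusion; the simulator's background statistics match the
signal/noise equations and the printed pixel gates and photon floor are
reproduced. These checks validate the *software*: the mask arithmetic,
thresholding, size gating, priority logic, focus search and stitching
geometry.

They do not validate performance on real membranes. The simulator omits
channel bleed-through (up to ~12% between specific fluorophore/channel
pairs on the real instrument), membrane pore texture and structured
autofluorescence, optical aberrations and field-dependent illumination,
photobleaching, debris, and the irregular morphology and brightness
distributions of real cells. Real-image classification agreement in the
high-90% range reported for the reference instrument is an empirical
result about that instrument and its samples; the synthetic recovery
rates here should not be read as a prediction of clinical performance.

## Problem sizes used by the test suite

Unit tests run on small fields (tens of µm, ~100–700 px per side) with
the same ~0.6 µm object pixel pitch as the full frame; the end-to-end
recovery study uses 20 seeded full-frame scenes in each noise mode, the
Otsu implementation is checked against exhaustive maximisation on 100
random images, and the autofocus comparison uses 20 seeded single-cell
stacks of 15 planes. These sizes make the whole suite run in a few
minutes on one core while keeping every statistical check at ≥ 10⁵
pixels where the model equations are asserted quantitatively.
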