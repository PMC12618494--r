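---
title: "Models and methods behind chromtrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromtrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromtrap)
```

chromtrap analyses fluorescence time-lapse data of single cell-free bacterial
chromosomes held in flat, semi-open microfluidic compartments: small circular
chambers (radius R, height ~1.5 µm) connected to flow channels through thin
capillaries, so that solutes exchange purely by diffusion while the
chromosome stays put. This vignette explains the models implemented, the
parameters that matter, what the synthetic-scene generator does and does not
emulate, and the numerical choices made where the design was open.

## The compartment lifetime model

The mean residence time of a molecule of diffusivity $D$ in a chamber of
radius $R$ with an exchange capillary of length $L$ and width $W$ is

$$\tau = \frac{\pi R^2 L}{2 D W}.$$

All lengths are micrometres, times seconds, diffusivities µm²/s; minute
conversions happen only at the reporting layer. The formula treats a single
open capillary: the second, constricted capillary that retains the cell has a
~0.4 µm ceiling and contributes negligibly to exchange, so it is recorded in
the geometry but not summed into the lifetime. With the small layout
(R = 10, L = 40, W = 1.5) an mRNA-like species ($D \approx 10$) resides about
7 minutes and a plasmid ($D \approx 1.7$, the value the MSD analysis of
tracked plasmids yields) about 40 minutes:

```{r lifetime}
geom <- compartment_geometry(10, 40, 1.5)
compartment_lifetime(geom, 10)
compartment_lifetime(geom, 1.7)
```

`solve_radius_for_lifetime()` inverts the formula for layout design. Whether
the large diamond-shaped compartments share the same capillary dimensions is
not constrained; the helper is agnostic.

## The synthetic-scene generator

Every analysis stage is validated against scenes whose ground truth is known
exactly, because the generator records it:

* **Brownian tracks** — per-frame Gaussian displacements with variance
  $2D\Delta t$ per axis; the chamber wall reflects. Escape through the
  capillary is never simulated particle by particle: the analytic lifetime
  model covers it, and no downstream analysis needs per-particle escape.
* **Surface arrivals** — nascent proteins captured on the antibody-coated
  floor appear as a homogeneous Poisson process, visible from arrival until
  an exponential photobleaching time (default mean 120 s, the few-minute
  bleaching scale of far-red dyes at these excitation powers), with a 10%
  per-frame blinking probability.
* **Image formation** — emitters are integrated 2-D Gaussian PSFs; Poisson
  shot noise acts on signal plus background; the EM register is approximated
  as a gamma-distributed multiplicative stage (shape = photon count,
  scale = gain) rather than a full cascade model, which is sufficient for
  SNR-realistic detection tests; Gaussian read noise follows and counts are
  clamped at zero and rounded to integer ADU. The pixel size default is
  0.16 µm (two pixels = 0.32 µm, the colocalization distance), and the
  frame intervals follow the acquisition modes used with such samples: 2 s
  per channel in alternating two-colour mode, 2.5 s or 5 s in the large
  compartments. Photon budget (400/frame), background (20/pixel), EM gain
  (50) and read noise (30 counts) have no printed experimental anchors; they
  are deliberate, config-exposed inventions chosen to put single molecules
  near SNR 10.
* **Nucleoid scenes** — each chromosome is a union of soft-edged, flat-top
  sub-blobs (disks with a one-pixel Gaussian edge), decorated
  *multiplicatively* with Gaussian intensity bumps (amplitude 0.8, σ 0.3 µm)
  at the sub-blob centres. A Gaussian mixture was rejected as the sub-blob
  profile: its area above a threshold varies logarithmically with the
  threshold, so no threshold-robust ground-truth area exists, whereas a
  flat-top object pins the half-plateau contour. The decoration is
  multiplicative for the same reason — additive bump tails would displace
  the contour on small chromosomes. The true area is defined as the
  super-threshold pixel count of the final noiseless field at the 50%-plateau
  rendering threshold, matched to the drawn target by bisection on a global
  size scale, and sub-blobs are pulled together until the mask is a single
  connected component (a chromosome is one object). Condensin-like spots sit
  on sub-blob centres (with 0.05 µm localization jitter) or at 0.5-1 µm
  clearance; the colocalized count is allocated across the whole population
  so the realized blob fraction matches the target even when per-chromosome
  rounding would not.
* **Stretch kymographs** — the super-threshold extent of a 1-D profile rises
  mono-exponentially toward a plateau while the field is on and decays when
  it is off, with a soft one-pixel front.

What the generator does **not** emulate: polymer mechanics of the chromosome,
electroosmotic flow during field stretching, optics beyond a Gaussian PSF,
photophysics beyond single-exponential bleaching plus blinking, uneven
illumination, and camera pattern noise. Passing tests therefore demonstrate
that the pipeline recovers known truth under realistic noise, not that it is
robust to every artefact of real microscopes.

## Spot detection, tracking and arrival counting

Frames are variance-stabilized with a square-root transform before the
difference-of-Gaussians band-pass (σ and 2σ): the Poisson-gamma noise of an
EM-CCD has a heavy right tail that otherwise produces spurious maxima past
any fixed SNR gate. Candidates are 3×3 local maxima of the band image gated
at `snr_min` (default 5) against a robust per-frame scale
(median/1.4826·MAD), then refined by an intensity-weighted centroid in a
(4σ+1)-pixel window. Weighted-centroid localization (sub-half-pixel RMSE at
SNR 10) was chosen over Gaussian fitting because the downstream precision
requirement is the 0.32 µm (2 pixel) colocalization rule; Gaussian fitting is
a noted extension.

Linking is greedy nearest-neighbour with squared-distance cost, a
`max_disp_um` gate and gap bridging up to `max_gap_frames`; ties break by
distance then detection index, so results are deterministic. Sparse scenes
(a single plasmid, a handful of surface captures) do not warrant global
assignment. Coordinates are continuous micrometres with the origin at the
top-left pixel centre; pixel indices are 0-based in all tables; frame *i*
occurs at *i*·Δt.

Arrival counting clusters detections in (x, y, frame): neighbours within
0.32 µm and ≤5 frames, connected components, clusters under 2 detections
discarded. These defaults are not experimentally printed; they are
config-exposed and logged. One event per cluster is timed at its first
frame. With a 120 s bleach time and 2 s frames about 3-4% of molecules still
bleach before yielding the 2 detections the floor requires, which is the
dominant systematic of the arrival-rate recovery (a few percent, inside the
10% band).

The exponential waiting-time distribution is fitted on the empirical CDF
(value $k/n$ at the $k$-th sorted waiting time) by least squares, the stated
estimation approach, not maximum likelihood. Waiting times are differences
between consecutive events, with the first measured from observation start
and no dead-time offset. Dropping the final (censored) interval biases the
pooled rate upward by roughly $1/n$ per 60-min movie (~2-5% at these rates);
this is inherent to the method and stays well inside the tolerance. The
mono/bi model choice prefers mono unless the bi fit cuts the residual sum by
half with resolved components (τ₂/τ₁ > 4, amplitude in [0.2, 0.8]). These
defaults were calibrated once against the two design cases — pure
mono-exponential data must keep the mono description in ≥95% of
realizations, and a τ₂/τ₁ = 20, A = 0.5 mixture must be detected in ≥80% —
because looser windows (gain 25%, ratio 3, A in [0.1, 0.9]) admit spurious
small-amplitude components: least-squares ECDF residuals are strongly
autocorrelated, so a flexible second exponential can absorb sampling wiggle.

## Dissociation kinetics

Ensemble bound-protein intensity after the cell-free system flows in is
modelled as

$$I(t) = (1 - A)\,e^{-t/\tau} + A,$$

with $A$ the tightly bound (immobile) fraction. Traces are
background-subtracted, normalized by their initial value, and averaged over
chromosomes *before* fitting (the average-then-fit order; the alternative
per-chromosome-fit order is not implemented). The fit is bounded nonlinear
least squares ($A \in [0,1]$, $\tau > 0$), uniformly weighted, initialized
with $A_0$ = mean of the last 10% and $\tau_0$ = first crossing of
$(1+A_0)/2$. A constant trace is reported as $A$ with $\tau$ flagged
unidentifiable rather than an error. Out-of-range bound fractions from the
pre-/post-lysis comparison are clipped to [0, 1] and flagged, since noise can
push per-cell ratios past 1 and medians are reported.

`elongation_rate()` divides a typical gene length by the fitted release
timescale: ~1000 nt over ~2 min gives on the order of 10 nt/s.

## Nucleoid segmentation and conformation readouts

Segmentation replaces the original star-convex neural model with a classical
operator having the same output contract: large-scale morphological opening
(default radius 8 µm — it must exceed the half-width of the largest
chromosome) for background, Gaussian smoothing (0.16 µm), a global
threshold, 8-connected components, a 1 µm² minimum area, and an optional
watershed split. It is deterministic, dependency-light, validated against
generator truth, and swappable for a learned segmenter through the same
interface. The default threshold is Otsu-seeded with a midpoint refinement:
raw Otsu shifts with the foreground/background pixel proportions (chromosomes
cover a few percent of a field, which dilates small masks by ~10%), so the
threshold is moved to the midpoint of the two classes' median levels, which
is proportion-independent and lands on the half-intensity contour. Region
area is the plain mask pixel count times the pixel area; no intensity
weighting is applied.

Time linking uses the literal overlap rule — same series when masks share at
least one pixel — with largest-overlap, then lowest-label tie-breaks, and no
gap bridging. Summed-area series are normalized by the frame-0 sum and
smoothed with a normalized Gaussian kernel with reflective edges.

Blob detection is a Laplacian-of-Gaussian (difference-of-Gaussians) response
restricted to the eroded region mask with three gates: a prominence floor
(0.45 of the strongest in-mask response), a contrast floor (10% above the
region median, which removes the boundary-curvature maxima a uniform region
produces), and Hessian edge rejection (trace²/determinant ≤ 5, the SIFT
criterion: an isotropic peak scores 4, a boundary ridge much more).
Sub-pixel positions come from parabolic peak interpolation, which is robust
to the asymmetric plateau background where an intensity centroid is biased by
one to two pixels.

Colocalization is greedy one-to-one matching under the strict rule
distance < 0.32 µm; a pair at exactly 0.32 µm is a non-match. Dose-response
aggregation reports per-condition means with 15.9%/84.1% empirical quantiles
(linear interpolation between order statistics; no estimator is prescribed,
so the conventional type-7 rule is used). Group comparisons use the
two-sided Mann-Whitney U test (exact for small tie-free samples, normal
approximation with tie and continuity correction otherwise) with no
multiple-testing correction, as a reporting-layer statistic.

Manual exclusion of non-lysed cells is reproduced as a polygon-mask input
(`mask_filter()`, even-odd rule, strictly interior points), not an automated
classifier.

## Problem sizes, tolerances and degenerate inputs

The validation suite runs at sizes chosen to make recovery statistics tight
while staying lightweight: 50 tracks × 100 frames for diffusion (pooled MSD
fitted through the origin on lags up to a quarter of the track, weighted by
pair counts; the render-and-redetect round trip is omitted there because
0.05 µm localization noise is negligible against 2.6 µm frame steps, and
free 100-frame excursions would need ~80 µm fields to render); 20 seeds of
4 averaged replicate traces for decay recovery; 20 one-hour movies at the
chromosome synthesis rate and 36 at the slower plasmid rate for arrival
recovery (movie counts scale inversely with the rate so both fits rest on
~800 pooled events); 20 four-chromosome scenes for colocalization; 20
three-chromosome scenes for area recovery. Numerical safeguards: empty
stacks yield empty detection tables, not errors; degenerate MSDs return
D = 0 flagged; a collapsed bi-exponential is flagged `effectively_mono`
rather than reported as resolved; identical-valued group comparisons return
p = 1 flagged; all stochastic stages take explicit seeds and stage seeds are
derived deterministically from one global seed, so identical configurations
reproduce byte-identical scenes and tables.

## Known limitations

The segmentation operator assumes chromosomes brighter than a slowly varying
background and will merge truly touching chromosomes unless the watershed
split is enabled; the arrival chain undercounts by the few percent of
molecules that bleach before the cluster-size floor; the flat-top sub-blob
geometry makes area ground truth exact but is a stylized account of real
nucleoid texture; and the stretch module fits envelope kinetics only — the
mechanics behind the stretching (field coupling, polymer relaxation) are
outside its scope.
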