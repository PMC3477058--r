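---
title: "Methods: morphology-based retinal screening and RNFL thickness estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphology-based retinal screening and RNFL thickness estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinodiag)
```

retinodiag implements two classical screening pipelines: diabetic-retinopathy
(DR) lesion detection and five-level severity grading from color fundus
photographs, and glaucoma screening from OCT B-scans via retinal
nerve-fiber-layer (RNFL) thickness. Both are built from transparent image
primitives — grayscale morphology, adaptive histogram equalization,
Perona–Malik diffusion, a greedy active contour — rather than learned models,
so every stage is testable against closed-form oracles and seeded phantoms.

## The fundus model

A fundus photograph is modeled as a background field carrying five feature
classes: the optic disc (the brightest region, diameter ODD, used as the
pipeline's unit of distance), a dark vessel tree whose main arch is
approximately parabolic with its vertex at the disc, bright sharp-edged
exudates, small dark microaneurysms and hemorrhages (MAHM, detected jointly),
and the dark fovea on the arch axis.

**Preprocessing.** Contrast-limited adaptive histogram equalization is applied
per channel (8 × 8 tiles, clip limit 0.005, 256 bins, bilinear interpolation
between tile mappings). The clip limit matters more than usual here: at the
common 0.01 the equalization re-spreads the optic disc's *own* interior
across the intensity range, destroying the uniform-brightness property the
disc detector depends on (we measured the detected center drifting ~9 px and
the ODD shrinking by 11 px on phantoms). 0.005 flattens illumination ramps
while keeping the disc coherent; it is a config field (`fundus$clip_limit`).

**Optic disc.** The HSI intensity plane I = (R+G+B)/3 is blurred
(Gaussian, σ = 0.005·min(H, W), ≥ 1 px) and thresholded at I~max~ − 0.02; the
maximum-area component above threshold is the disc candidate, and an
Otsu re-threshold of a window around it delineates the boundary. The ODD is
the equivalent-circle diameter of that component. Because the threshold is
relative to I~max~, detection is invariant to global brightness shifts. A
near-flat image (range < 0.02) raises a typed `no_disc` error instead of
guessing.

**Vessels.** C = close(G, s₂) − close(G, s₁) on the green channel, with disk
structuring elements s₁ = 3 px (below the vessel caliber) and s₂ = 9 px
(above it) at the 700-px reference width, scaled linearly with width. C is
thresholded by Otsu over its positive support and cleaned of components
smaller than 150 px (reference scale). The cleanup size is deliberately
larger than a bare noise filter: punctate dark lesions respond to the closing
difference exactly like short vessel segments, and if they survive here the
MAHM stage's vessel removal erases them — the pipeline is only coherent when
"small areas" includes dot lesions.

**Exudates.** P = dilate(G, s₄) − dilate(G, s₃) with s₃ = 13, s₄ = 25 px
(both above s₂, so vessels vanish from both dilations). P is Otsu-thresholded,
holes are filled, candidates are confirmed by green brightness
(> mean + 2 SD; the text's "intensity in the green channel" is ambiguous
between a confirmation step and the P threshold itself — we implement the
confirmation, switchable off via `confirm_green`). The optic-disc region is
then removed with a 0.5 ODD dilation margin: the delineated disc boundary is
conservative and can sit a few pixels off-center, and remaining disc pixels
grade exactly like exudates.

**Fovea.** The main vessel is found as the strong vessel components
emanating from the disc (intersecting the disc mask dilated by 0.25 ODD,
scored by area × mean caliber from a distance transform; components within
50% of the best score are merged, because the bright disc interrupts the
arch and splits it in two). A parabola col = a(row − r₀)² + b(row − r₀) + c₀
is fit by least squares in a disc-centered frame. We deliberately transposed
the fit relative to the obvious row-as-function-of-column choice: the
temporal vessel arch opens horizontally, so its axis of symmetry is
horizontal and the fovea lies on it — a vertical-axis parabola would place
the "2–3 ODD along the main axis" search above or below the disc. The fovea
is the darkest pixel of the intensity plane inside the 2–3 ODD, ±45° sector
along the axis; the plane is smoothed at σ = 0.15·ODD first, because the
fovea is an ODD-scale region and any pixel-scale dark lesion inside the
sector would otherwise win the darkest-pixel criterion. The foveal region
radius is 1 ODD.

**MAHM.** R = fill(G) − G, where fill is grayscale hole filling
(morphological reconstruction by erosion from a border marker): small dark
blobs surrounded by brighter tissue light up. R is thresholded at the mean
of the red channel — the one threshold the method pins down explicitly —
vessel coordinates are removed (after a 3-px protective dilation of the
vessel mask, since the extracted mask is slightly thinner than the true
vessel), and specks below 5 px (reference scale) are dropped.

**Grading.** Ten sub-regions about the fovea: the central foveal disc of
radius 1 ODD (region 1), the 1–2 ODD annulus in four quadrants (2–5), the
2–3.5 ODD annulus in four quadrants (6–9), and the remainder (10), with
quadrant axes aligned to the fovea→disc direction. The severity rule is:
no lesions → none; lesions confined to region 10 with total area < 500 px →
mild; lesions outside the fovea with zero region-1 pixels → moderate; any
region-1 pixels or total area > 10 000 px → severe; proliferative only via
an explicit neovascularization flag, since no neovascularization detector
exists here. The region geometry and the two area cutoffs are conventions:
the only anchor is the published worked example (5196 exudate px + 3991
MAHM px, none foveal → moderate), which this table honors; both cutoffs and
the radii are config fields. The rule is monotone by construction — adding
lesion pixels can never lower the grade — and the tests check this
exhaustively over a grid of area configurations.

## The OCT model

A B-scan (rows = depth at 6 μm/px by default, columns = lateral position;
reference geometry 329 × 689) shows a dark vitreous above a bright RNFL band,
darker inner retina, and a bright RPE band deeper down, all corrupted by
multiplicative speckle.

**Pre-smoothing.** 10 × 10 Gaussian (σ = 4, reflective borders) followed by a
3 × 3 median. The even kernel size implies a half-sample center shift; with
reflective borders this makes global mean preservation approximate rather
than exact (measured ~10⁻⁵ on noise fields, up to ~10⁻³ on strong ramps), so
the tests assert exact constant-field preservation and equality with a
direct-summation oracle instead of exact mean conservation.

**Anterior boundary.** Binarize the gradient magnitude (central differences,
Otsu level by default); remove components of area < 0.07% of the image
(158 px at reference size, recomputed by round-down elsewhere) or horizontal
extent < 25 px; take the first white pixel from the top per column; fill
missing columns with a least-squares cubic (exact when the boundary is
itself cubic). Fewer than 4 defined columns is a typed failure.

**Greedy snake.** Each point moves within a 7-px vertical window to minimize
α·continuity + β·curvature − γ·(normalized gradient), visited sequentially —
greedy coordinate descent on a fixed functional, so total energy is
non-increasing by construction (the tests assert it for every iteration).
Two deviations from the obvious formulation were forced by analysis:
(1) the gradient field is min–max normalized *globally* rather than per
window, because a per-window normalization changes the objective between
iterations and no monotonicity statement survives; (2) the smoothness terms
are scaled by h⁻⁴ (h = window half-width), i.e.
α·Σ(Δr)²/h⁴ + β·Σ(Δ²r)²/h⁴. With raw pixel-squared smoothness terms the
snake is provably frozen: the cost of the *first* point to move toward an
edge 3 px away exceeds the maximum possible image-term gain (γ·1) for any
α = β ≥ 0.6, so the textbook defaults α = β = 1, γ = 1.2 would never
converge. Under the h⁻⁴ scaling the image term dominates window-sized moves
and the defaults behave as intended; smoothness still regularizes sub-window
jitter. Defaults: α = β = 1, γ = 1.2, window 7, ≤ 50 iterations, stop when
< 2% of points move.

**Posterior boundary.** Everything above (and 5 px below) the anterior trace
is removed and the *unsmoothed* scan is diffused with the 8-neighbor
Perona–Malik scheme — diffusion is the posterior stage's own edge-preserving
smoother, and feeding it the Gaussian-blurred image would both widen the
edge ridge (biasing the first-from-top boundary upward) and defeat its
purpose. The gradient magnitude of the diffused field is normalized,
binarized at mean + 1 SD (the "statistical" level; configurable), and
cleaned: components < 100 px; components whose mean row lies > 60 px below
the anterior trace (classified RPE); then extent < 25 px or area < 70 px.
Two masking details matter: the artificial 0→tissue edge created by the
masking itself is excluded by zeroing the gradient 2 rows past the mask, and
the statistical K for the diffusion is estimated from the *unmasked* scan so
the zeroed region cannot bias the gradient histogram. The first remaining
white pixel from the top per column is the boundary; gaps are filled with a
cubic and the trace passes a 50-point median (windows shrink symmetrically
at the ends). The snake is not applied to the posterior by default
(`snake_posterior` enables it); the text describes refinement only for the
anterior.

**Diffusion scheme.** I⁽ᵗ⁺¹⁾ = I⁽ᵗ⁾ + λ Σ_d c_d ∇_d I over the 8 one-sided
neighbor differences, c_d = g(|∇_d I|), g(s) = exp(−(s/K)²). The printed
update equation duplicates the SE term and omits SW; all 8 distinct
directions are implemented, which the directional-difference and coefficient
definitions clearly intend. The printed coefficient definitions pass the
neighbor *intensity* to g; we pass the directional difference, which is what
the conduction function's argument (∇I) and the method's purpose require.
Diagonal differences carry no 1/√2 metric weighting (literal scheme; a
corrected mode exists but is off). λ ∈ (0, 0.25] is accepted, but the
8-neighbor maximum principle needs λ ≤ 1/8, so 0.125 is the default and
larger values warn. K defaults to the 90th percentile of the full
gradient-magnitude histogram (zeros included, floored at 10⁻³): on a
noise-free image this collapses to the floor and every real edge is
preserved exactly; on speckle it tracks the noise level. The iteration count
defaults to 40: on the 4-look phantom world 20 iterations demonstrably
under-smooth (posterior RMSE ≈ 2.6 px against the 2 px criterion), 40
reaches ≈ 1.95 px, and both 10 and 60 are worse (under-/over-smoothing).

**Thickness and classification.** thickness[c] = (posterior[c] −
anterior[c]) · 6 μm, negative separations clipped to zero with a warning;
the mean over all columns is compared with 105 μm (mean < 105 →
glaucomatous; the boundary value counts as healthy). A per-patient protocol
(mean of per-image means across scans) is provided by the pipeline wrapper.

## What the phantoms emulate — and what they don't

The fundus phantom renders background (R 0.50, G 0.60, B 0.30), a linear
illumination ramp (±0.03), the disc (ODD 90 px at 700 × 700), the parabolic
arch with two branches (width 5 px, between the closing scales), the fovea
at 2.5 ODD on the arch axis, 3 exudates and 4 MAHM blobs placed ≥ 50 px
apart (twice the largest dilation scale, so counts are exactly recoverable),
and additive Gaussian noise (SD 0.01). Channel levels are a stated world:
the disc is the brightest intensity region, exudates pass the green
mean + 2 SD confirmation, MAHM holes are deeper than the red-channel mean
(the detector's threshold), and the fovea is dark but shallower than that
threshold. The green channel intentionally exceeds the red so the
fill-depth/red-mean inequality can hold at all; real fundus photographs are
red-dominant, which is one of several reasons a green phantom suite says
nothing about clinical accuracy. No circular field-of-view aperture, no
texture, no vessel caliber variation, no lesion subtypes.

The OCT phantom renders the band stack (vitreous 0.08, RNFL 0.85, inner
0.30, RPE 0.80 starting 80 px below the anterior, deep 0.15) with a cubic
anterior boundary rounded to integer rows — so a pixel-accurate detector can
be held to ≤ 1 px — uniform 28-px (168 μm) thickness by default, optional
edge gaps for testing the cubic fill, and unit-mean Gamma(L, 1/L)
multiplicative speckle (4 looks by default; the Gamma intensity-speckle
model is the standard coherent-imaging choice matching the multiplicative
premise). Real OCT speckle is spatially correlated and the retina has more
than four layers; a green phantom-recovery suite establishes algorithmic
correctness, not clinical performance.

## Numerical and degenerate-input choices

- Morphological windows are restricted to the image at borders, so flat
  fields are exact fixed points of erosion/dilation/closing/median.
- Diffusion and gradient operators replicate borders (one-sided differences
  vanish at the edge), preserving the constant fixed point.
- Otsu thresholds use 256 bins over the data range; constant input returns
  the minimum (detectors then see an empty foreground rather than noise).
- Tiny or flat images fail with typed errors (`no_disc`, `no_main_vessel`,
  `no_boundary`, `underdetermined`) rather than returning fabricated
  landmarks.
- All phantom randomness flows through a single seed; generators save and
  restore the caller's RNG state.
- The snake rounds its trace to integer rows and breaks window ties toward
  the smaller row (`which.min`); boundary truth is rendered on integer rows,
  so ties cost at most 1 px.

## Known limitations

- The posterior estimator cannot resolve RNFL thinner than the anterior
  margin + gradient support (≈ 8 px ≈ 48 μm); the classifier sweep below
  105 μm is therefore exercised on synthetic traces, not on phantoms.
- The ten-region geometry and the mild/severe area cutoffs are conventions
  validated against a single worked example; they are config, not science.
- CLAHE's clip limit trades illumination correction against disc coherence;
  outside roughly 0.003–0.008 the disc detector degrades on phantoms.
- No raster codecs are bundled: I/O is PNM (PGM/PPM, ASCII or binary, 8/16
  bit) plus in-memory arrays; convert other formats externally.
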