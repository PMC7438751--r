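---
title: "Panoramic dental image reconstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panoramic dental image reconstruction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panodont)
```

## The problem

A panoramic radiograph shows the whole dental arch in a single flat image.
When a patient already has a cone-beam CT (CBCT) volume, the panoramic
view can be synthesised from it instead of taking an extra X-ray
exposure. Doing that automatically requires (i) finding the dental arch
in the axial slices, (ii) describing its centre-line with a smooth curve,
and (iii) resampling the volume along that curve and its parallel
offsets, collapsing the arch's thickness into one image.

`panodont` implements this chain end to end, plus a synthetic phantom
generator so every stage is testable without patient data.

## The model

**Segmentation.** Dental enamel is the most radio-opaque dental tissue,
above roughly 1500 HU, so a global threshold at 1500 HU isolates teeth.
The axial slice with the most supra-threshold voxels — in practice the
slice cutting the crowns — becomes the reference slice. Missing teeth
leave gaps, so the binary mask is dilated with a 20 x 20 px all-ones
rectangle, smoothed with a Gaussian of sigma 4 px (on the {0,1} cast of
the mask, re-binarised at the symmetric 0.5 level), and reduced to its
largest 8-connected component: a single connected arch silhouette.

**Skeleton.** The arch silhouette is thinned to its medial axis with
Zhang–Suen iterative thinning, which is topology-preserving: a connected
mask yields a connected, 1-px-wide skeleton. The skeleton may carry small
side spurs; the main arch branch is recovered as the longest shortest
path between endpoint pixels of the skeleton's 8-neighbour graph (the
graph-diameter path), oriented from the image-left end so that the curve
parameter increases consistently.

**Curve fit.** A skeleton is not smooth — its derivatives are not even
continuous — so a panoramic image sampled along it would be jagged. The
arch is therefore described by a Bezier curve of degree $n$,

$$B(t) = \sum_{i=0}^{n} \binom{n}{i} (1-t)^{n-i}\, t^{i}\, P_i,
  \qquad t \in [0, 1],$$

whose $n+1$ control points $P_i$ are free parameters. They are chosen to
minimise the discrete mean distance between the sampled curve and the
skeleton,

$$f(P_i) = \frac{1}{m} \sum_{i=0}^{m} \lvert e_i - b_i \rvert,$$

where $b_i = B(i/m)$ and $e_i$ is the skeleton point closest to $b_i$.
Note the divisor is $m$ while the sum has $m+1$ terms; the formula is
implemented literally in that printed form (the 0.1% difference is
irrelevant in practice but is pinned for reproducibility). The sampling
density is $m = 1000$.

**Offsets and projection.** The arch has thickness. Parallel offset
curves are built from the curve derivative (hodograph form)

$$B'(t) = n \sum_{i=0}^{n-1} b_{i,n-1}(t)\,(P_{i+1} - P_i),$$

rotated 90 degrees counterclockwise and normalised: curve $k$ has points
$B(t_i) + k\,q\,N(t_i)$ for $k = -K..K$. Every axial slice is sampled
bilinearly along every offset curve, and the panoramic pixel at (slice
$z$, sample $i$) is the mean across $k$ — an average intensity
projection (AIP) through the arch's thickness. Rows follow the volume's
slice order; columns run along the arch.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `threshold_hu` | 1500 | HU | enamel threshold; the comparison is inclusive (`>=`) so the limit value itself stays in-mask |
| `dilation_size` | 20 x 20 | px | bridges gaps from missing teeth; reach is 19 px per axis (floor-centre origin of an even kernel) |
| `gaussian_sigma` | 4 | px | boundary smoothing before thinning |
| `rebinarize_level` | 0.5 | – | symmetric level set of the blurred mask |
| `n_control_points` | 11 | – | the studied settings are 3, 7, 11, 15; 11 balances fidelity and smoothness |
| `m_samples` | 1000 | – | cost sampling density $m$ |
| `offset_q` | 2 | px | offset spacing |
| `offsets_per_side` | 5 | – | $K$; 11 curves span ~20 px, the same scale as the dilation element |
| `init_mode` | `skeleton_uniform` | – | deterministic initialisation (see below) |

The number of offset curves and their spacing are not prescribed by the
method itself (a thickness-detection step is mentioned in the literature
but not specified); both are exposed as configuration, with defaults
tying the sampled thickness to the 20 px morphology scale — the only
internal anchor the method offers.

## Optimisation choices

The cost is piecewise smooth: wherever the nearest-neighbour assignment
is locally constant, the gradient with respect to control point $P_j$ is
$\frac{1}{m}\sum_i B_{j,n}(t_i)\,u_i$ with $u_i = (b_i - e_i)/|b_i -
e_i|$. `fit_bezier()` feeds this analytic subgradient to a BFGS
quasi-Newton minimiser (`stats::optim`), with `reltol = 1e-6` and at most
500 iterations. The problem is deliberately unconstrained — control
points may leave the image; only final curve samples are clipped (to the
air fill value) at volume-sampling time. Bezier endpoints are *not*
pinned to the skeleton endpoints: fixing them is known to be difficult
and the free fit lets curve ends drift slightly past the skeleton, which
the offset sampling tolerates.

Nearest neighbours are exact: a chunked vectorised exhaustive search,
with ties resolved to the lowest skeleton index for determinism. At the
sizes involved (hundreds of skeleton points, 1001 samples) this is fast
and keeps the brute-force oracle in the test suite meaningful.

Two initialisation modes exist. `skeleton_uniform` (default) places the
control points on the skeleton at uniformly spaced indices — fully
deterministic, and close enough to the optimum that BFGS converges in a
few hundred iterations. `random_in_bbox` draws control points uniformly
in the skeleton bounding box under a seed; it reproduces the original
random-start protocol, with a much larger initial cost and a final cost
that varies slightly across seeds as the optimiser lands in different
local minima of the piecewise-smooth landscape.

If the optimiser fails or would worsen the cost, the best curve seen so
far is returned with `converged = FALSE`; `f_final <= f_initial` is an
invariant of the result type, never an exception.

## The phantom

`generate_phantom()` builds an axial stack emulating a CBCT study: air
background (-1000 HU), a soft-tissue ellipse (40 HU), a bone-density
band (900 HU, half-width 10 px) following a known arch curve across the
middle slices, and tooth cylinders (2200 HU discs of radius 3 px stacked
across the central third of slices) centred at the 14 equally spaced
arc-length fractions $(j - 0.5)/14$ of the arch. Seeded Gaussian noise
(sigma 30 HU) is added, truncated at 4 sigma so that no bone or
soft-tissue voxel can reach 1500 HU and no tooth voxel can fall below
it — thresholding outcomes are therefore deterministic, which keeps the
segmentation tests exact while the noise still exercises interpolation
and projection.

The geometry was chosen once, from the morphology constraints: tooth
spacing along the arch is ~7.9 px, so neighbouring teeth are separated
by ~1.9 px (they stay distinct components before dilation, which the
8-connectivity cannot bridge) while a missing *adjacent pair* of teeth
leaves a ~17.6 px gap — still within the 19 px per-axis reach of the
20 x 20 dilation, so the arch remains a single component, the behaviour
the dilation step exists to produce. This forces an arch arc length of
~110 px, i.e. control points spanning roughly the central quarter of a
256 x 256 slice.

The truth arch is a deliberately *asymmetric degree-4* Bezier. Real
dental arches are not parabolas — that is the reason for optimising a
higher-degree curve in the first place — so the phantom's arch should
not be exactly representable by the lowest-degree fit either. Even so, a
free quadratic Bezier approximates any gentle quartic to a fraction of a
pixel, so on phantoms the cost differences across 3/7/11/15 control
points are small (hundredths of a pixel) though consistently monotone;
on patients, where the skeleton wiggles through real anatomy, the
differences are tens of times larger. Passing the phantom trend test
therefore demonstrates the *direction* of the effect, not its clinical
magnitude.

The phantom does **not** emulate: separate maxilla/mandible structures,
metal restorations and their artifacts, tooth-by-tooth shape variation,
or HU calibration drift. Tests passing on phantoms show the pipeline's
geometry and projection are correct; they do not validate enamel
thresholds or morphology sizes against clinical variability.

## Numerical conventions

- Pixel coordinates are 1-based with integer pixel centres; `x` indexes
  columns, `y` rows. Volumes are `[row, col, slice]` arrays with spacing
  in mm; the arch fit itself works in pixel units of the reference slice
  (row/col anisotropy beyond 10% triggers a warning).
- Threshold comparison is inclusive (`>= 1500`).
- The even-sized structuring element uses the floor-centre origin
  (offsets -10..+9 for size 20).
- Connected components and skeleton adjacency use 8-connectivity.
- Bilinear interpolation outside the slice returns -1000 HU (air), so
  curve overshoot darkens rather than corrupts the panoramic.
- Image quantisation rounds half away from zero (fixes the 32767.5
  ambiguity at the window midpoint).
- Zero-derivative samples (cusps) reuse the nearest non-degenerate
  sample's normal; a curve with identically zero derivative is an error.
- Component-size and nearest-neighbour ties resolve to the smallest
  raster-order pixel / lowest index.

## Tooth localisation in the panoramic

A tooth at arc-length fraction $a$ of the arch appears in the panoramic
at the *column* whose sample $B(i/m)$ is nearest the tooth — and column
index is the curve parameter $t = i/m$, not the arc-length fraction.
The two coincide only for an arc-length-parameterised curve; a fitted
Bezier deviates by tens of columns out of 1001. The phantom's
localisation check therefore computes each tooth's expected column by
projecting its known centre onto the sampled fitted curve, and
separately verifies that the fitted curve passes within a few pixels of
every tooth centre so the projection is anchored to the geometry.

## Worked example

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec(seed = 1))
res <- run_pipeline(ph$volume)
res$fit
#> fit_result: 11 control points, f_initial = 2.143, f_final = 0.407 px
dim(res$panoramic$pixels)      # 60 slices x 1001 arc samples
arch_distance(res$fit$curve, ph$truth)  # ~1.1 px from the true arch
write_image(res$panoramic$pixels, "panoramic.tiff")
```

## Problem sizes and test scale

The default phantom is 256 x 256 x 60 (about 3.9 M voxels) rather than a
clinical 512 x 512 x 100–250 stack; a `full-scale` preset doubles the
geometry for manual runs. The cost-trend check fits 3/7/11/15 control
points on ten phantom noise seeds with the deterministic initialisation;
because the truncated noise cannot alter the thresholded mask, the ten
skeletons — and hence the fits — are identical by construction, making
that check a deterministic monotonicity assertion rather than a
statistical one. The m = 1000 sampling density is kept at its standard
value throughout.

## Known limitations

- One 2D curve, fitted on the reference slice, is reused for every
  slice; strongly tilted arches would need per-slice or 3D curves.
- No automatic thickness detection: `offset_q` and `offsets_per_side`
  are user choices.
- Costs are reported in pixels of the reference slice, not millimetres.
- The DICOM reader handles single-frame uncompressed little-endian
  axial series only; compressed transfer syntaxes and multi-frame files
  are rejected with explicit errors.
- The 16-bit image writer emits TIFF only.
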