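---
title: "hemoquant: models, measurement conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hemoquant: models, measurement conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hemoquant` automates a family of phagocyte assays that were originally
scored by hand in ImageJ: vacuole and vesicle morphometry in hemocyte
z-stacks, marker colocalization, time-lapse phagosome-maturation scoring,
and the organism-level survival and bacterial-load readouts. This vignette
records the measurement model behind each module, the conventions adopted
where the original manual protocol left them open, and what the synthetic
validation data do and do not establish.

## The image model

All imaging operations work on an `image_stack`: a (channel, time, z, y, x)
intensity array with isotropic x–y pixels (default 0.1 µm/px) and an
independent z step (default 0.5 µm, the fine end of the 0.5–1 µm live-cell
confocal spacing the assays use). The original acquisitions state objective
magnification and NA but no pixel size, so 0.1 µm/px is a configurable
default chosen as typical for a 63×/1.4 NA confocal with modest zoom; no
result in the package depends on it beyond voxel bookkeeping, because every
measured quantity is converted to physical units through the calibration.
Stacks round-trip to multi-page 32-bit-float TIFF with a JSON sidecar
(axis lengths, intensity range, voxel sizes, frame interval); intensities
are stored normalized, so the round trip is exact to float32 precision.

## The synthetic-scene generator

The generator is first-class, tested code: it defines the study conditions
under which everything downstream is validated.

The cell body is an oblate spheroid with equatorial semi-axis $a$ and axial
semi-axis $b$ (defaults 5 and 3 µm, giving a rendered volume
$4/3\,\pi a^2 b \approx 314$ µm³, close to the 311.06 µm³ wild-type
reference used by the occupied-volume index). $b$ is a semi-axis
throughout the package — generator and segmentation agree on the
convention, and $a=b$ reduces to a sphere — so the "height" reported by
`segment_cell_body` is half the top-to-bottom mask extent. Vacuoles are
spherical voids punched out of the cytoskeleton channel; vesicles are
filled spheres or spherical shells (ring thickness 0.3 µm by default —
rings are observed but no thickness is specified anywhere, so it is a
parameter). Randomized cells (`random_cell_spec`) keep a 0.25 µm
cytoskeletal wall between every vacuole and the cell surface so voids stay
topologically enclosed after voxelization, and resample the whole
configuration when greedy placement dead-ends.

The forward model is: geometry → signal-dependent Poisson count noise →
additive zero-mean Gaussian read noise → in-plane Gaussian blur
(σ = 0.15 µm default). Each term has a spec parameter and can be switched
off, which the deterministic tests rely on. Deliberately **not** modelled:
a physical 3-D PSF, spectral bleed-through, photobleaching, depth-dependent
attenuation. Passing tests on these scenes therefore demonstrate that the
measurement chain is correct and well-calibrated on data satisfying its
geometric assumptions; they do not certify robustness to the optical
artifacts of real microscopes.

The colocalization generator renders Gaussian puncta and builds the second
channel as an exact in-sample linear mixture of the first channel's
structure with an orthogonalized independent punctum field, so the
noise-free within-mask Pearson correlation equals the target exactly for
any puncta count (convergence with $n$ is therefore trivial; under noise
the realized value is mildly attenuated and is recorded in the truth).
Intermediate targets need at least 10 puncta; ±1 and 0 are exact by
construction. Mixture intensities may dip below the background — they are
not clipped, since clipping would break the exactness.

The time-lapse generator docks a pHrodo particle (default 1.5 µm — large
enough that the 0.9 µm² measurement ROI sits fully inside it) at a known
frame, ramps its intensity along a logistic curve
$I(t) = b + (p-b)/(1+e^{-(t-t_{1/2})/\tau})$ (baseline 10, plateau 100,
half-rise 20 min, τ = 5 min — the source observations describe a monotone
rise with no functional form, and a logistic is the simplest saturating
choice), and coats it with a FYVE shell for a dwell time drawn from a
normal truncated at zero (mean 20, sd 5 min; sd = 0 gives determinism).
Dwell is rounded to the frame grid; a dwell outrunning the movie is
truncated and flagged in the truth. Frame intervals are stored per movie
(90–120 s is typical) and used, never assumed.

Survival cohorts draw death days from a Weibull parameterized by its
median (scale $= \mathrm{median}/\log 2^{1/k}$; shape 1 = exponential),
discretized by ceiling — daily scoring records the first day an individual
is found dead — with a degenerate family for exact cases. Colony counts
are Poisson with mean $\mathrm{CFU} \times \mathrm{fraction} /
\mathrm{dilution}$.

All generators are bit-reproducible given spec + seed, and restore the
caller's RNG state.

## Segmentation conventions

Thresholds default to Otsu on the analysed volume or plane (the manual
protocol binarized by eye; Otsu is the deterministic stand-in). Because
Otsu operates on the rescaled histogram, particle measurements are
invariant to positive gain changes. The cell is the largest 6-connected
supra-threshold component after slice-wise hole filling (vacuole voids
belong to the cell); ties break to the lowest label. Vacuoles are
sub-threshold components interior to the cell mask eroded by one pixel
(rim-artifact guard, not part of the original protocol).

Connected components use 8-connectivity in 2-D (the particle-analysis
convention) and 6- or 26-connectivity in 3-D, implemented as array-shift
adjacency over igraph's components and tested against a brute-force flood
fill.

**Widest-diameter convention.** A vacuole's radius is half its widest
in-plane diameter across z-slices, the automated counterpart of measuring
"the widest point" by hand. The digital diameter is the maximum pairwise
distance between boundary-pixel centres (via convex hull) plus half a
pixel. The half-pixel term was calibrated on digitized spheres of known
radius *before* the recovery tests were written: zero correction biases
the radius −0.45 % on average, a full pixel +1.8 %, half a pixel +0.07 %
with all errors within ±1.3 %. Residual error is dominated by the z grid
missing the true equator (up to $r(1-\sqrt{1-(\Delta z/2r)^2})$), which is
why end-to-end OVI recovery is validated at 5 %, not at the formula-level
1e-9.

**Perimeter and circularity.** Particle perimeter is the crack length
(count of exposed pixel edges) scaled by π/4 — the standard correction
that makes digitized discs measure $2\pi r$, so a circle scores
circularity 1 (values are clipped at 1; convex polygons are mildly
overestimated). The particle area filter operates in the unit declared in
the filter (default px² with a lower bound of 20, mirroring ImageJ's
pixel-unit "size: 20-infinity" behaviour — the original units are
ambiguous); `filter_to_um2` converts when physical units are wanted.

## Index definitions and open conventions

The OVI divides the summed sphere volumes of vacuoles with $r \ge 1.5$ µm
by a **fixed** reference cytoplasmic volume of 311.06 µm³ by default: the
original analysis measured the wild-type average once and applied it to
all genotypes (mutant averages diverged only slightly), and the fixed
denominator preserves cross-group comparability. A per-cell mode divides
by the cell's own ellipsoid volume instead, for methodological comparison.

The printed cytoplasm formula, $4/3\,\pi a b^2$ with $a$ the radius and
$b$ the height, is the prolate-style arrangement of symbols although the
named solid is oblate ($4/3\,\pi a^2 b$). Both variants are implemented;
`"as-printed"` is the default to replicate the original arithmetic
literally, and nothing in the package asserts which one produced the
published reference volume — with a fixed denominator the choice does not
touch any default result.

The FYVE diameter ratio needs "three representative vesicle diameters per
cell"; the deterministic default takes the 3 largest equivalent diameters
(robust to clutter), with a seeded random selection available. The
reference mean is the mean over reference-group cells of their per-cell
means, which makes the reference group self-normalize to 1 exactly.

## Time-lapse scoring

Docking (t0) is the first frame where the thresholded particle mask
touches the cell mask by ≥ 1 pixel (the original call was visual). The
particle channel is binarized per frame — its intensity ramps several-fold
over a movie, so a global threshold would drop the dim early frames — with
a minimum component size so empty frames do not binarize their noise. The
intensity readout is the mean over a square ROI of 0.9 µm² (side
`round(sqrt(0.9)/px)` pixels; the original ROI shape is unstated) centred
on the rounded intensity-weighted centroid, on the particle's mid-plane;
border-clipped ROIs are flagged. Raw intensities are reported — whether
the original series were background-subtracted is unstated, and
subtraction is left to the caller.

"Surrounded by FYVE" has no published operational definition. The package
counts a frame positive when ≥ 50 % (parameter) of a one-pixel annulus
just outside the particle boundary lies above the FYVE threshold. That
threshold is a single movie-wide Otsu computed **within the cell mask**
when one is supplied: within-cell pooling separates the coat from the
cytoplasmic FYVE background, and pooling over time keeps coat-free frames
empty instead of binarizing them against themselves. Prevalence in minutes
is exactly `positive frames × interval / 60`, so the frame count is always
recoverable.

## Statistics

`one_way_anova` is the classic fixed-effects F (delegated to
`stats::oneway.test` with equal variances). The Bonferroni post hoc uses
the pooled within-group variance of all groups with $df = N - k$ and
multiplies each raw p by the number of *requested* comparisons, capped at
1 — the Prism-style "Bonferroni test", not Holm or Tukey. The
Mann-Whitney test uses midranks; p-values are exact by full enumeration of
group assignments (valid under ties) whenever both groups are ≤ 8 **or**
the total sample is ≤ 10 — the two small-sample regimes promised exact —
and otherwise use the tie-corrected normal approximation with continuity
correction. The two-tailed exact p is the probability of a U at least as
far from $n_1 n_2/2$ as observed.

Median lifespan is summarized per replicate (sample median, midpoint
convention), then as mean ± SEM across replicate medians — the structure
behind "median lifespan m ± e" reporting for replicate-tube assays.
Right-censoring is deliberately not modelled: cohorts are scored to the
last death, and survivors-at-end are a data error here, not a censoring
case. CFU estimation takes count × dilution at the lowest countable
dilution, with a spot ceiling of 150 colonies (configurable; counts above
it are treated as confluent) and a consistency ratio across the remaining
dilutions. The group × time curve comparison fits a fixed-effects two-way
ANOVA and reports per-timepoint Bonferroni-adjusted group tests and the
earliest significant timepoint; time grids must match exactly — no silent
interpolation.

## Problem sizes used in validation

The shipped tests validate on: 20 noise-free 128×128×24 cells for
end-to-end OVI recovery (5 % per cell); 50 noisy default movies for
dwell-mean recovery (within 2 SEM); 2000 null simulations for ANOVA
type-I calibration (5 % ± 2 %); full Mann-Whitney enumeration for every
sample-size shape with $n_1+n_2 \le 10$; and ten independent replicates
of a 25 + 25-cell small-vs-large vacuole contrast (72×72×12 scenes) that
must reach Bonferroni significance on OVI and OAI in every replicate.
These sizes were chosen to exercise each claim at desk scale while keeping
the suite fast; the generators accept larger scenes unchanged.

## Known limitations

- Spheres and spheroids only: no 3-D surface reconstruction of vacuoles or
  cells, matching the assays being automated.
- Single-particle tracking per movie; no identity switches, no
  photobleaching correction.
- Plain within-mask Pearson only — no Manders/Costes variants, no
  background thresholding before correlation (the original plugin's
  behaviour on this point is unstated).
- The optical forward model is deliberately minimal (see above); results
  on real stacks should be spot-checked against manual measurements before
  the defaults are trusted on a new imaging setup.
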