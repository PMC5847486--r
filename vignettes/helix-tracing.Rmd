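---
title: "Tracing helical filaments in cryo-micrographs: models and choices"
author: "helixtracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing helical filaments in cryo-micrographs: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(helixtracer)
```

This vignette explains the models behind the package, the parameters that
matter, what the synthetic data emulate (and do not), and the places where
the design was genuinely open and a choice had to be made.

## The tracing model

A helical assembly crosses a small enough window of a micrograph as an
approximately straight line. The package exploits this twice. First, the
in-plane axis angle of each overlapping tile is found in Fourier space:
helical objects produce layer lines in their power spectra, and because the
amplitude spectrum is invariant to real-space translation, rotationally
correlating the tile's power spectrum against a vertical reference helix
separates the angle search from the position search. Second, with the angle
fixed, one real-space normalized cross-correlation of the back-rotated tile
against the reference yields the signed normal offset $\Delta$ of the axis
from the tile center and a cc-score in $[-1, 1]$. Only the normal component
of the correlation peak is used; the axial component carries no information
for a locally straight filament and is discarded (at integer precision —
sub-pixel peak interpolation would be dominated by noise at these
signal-to-noise ratios).

Per-tile matches are accumulated into a correlation map by drawing, for
every tile, a line segment of tile length at the matched angle and offset,
weighted by the cc-score. Tiles sharing a helix reinforce each other along
its path; noise tiles, with incoherent angles and offsets, do not build
ridges. Two falloffs shape each drawn line:

* longitudinally, a Gaussian of $\sigma = 2 \times$ the tile step,
  truncated at half the tile length, so helix starts and ends taper off
  instead of ending abruptly;
* transversally, a narrow profile ($\sigma_\perp = 2$ px by default,
  exposed as an argument of `accumulate_map()`).

The narrow transverse profile is a deliberate design decision. With a wide
transverse falloff on the same scale as the longitudinal one, every drawn
line covers tens of times the per-tile map area, every map pixel
accumulates dozens of random-line hits, and the background distribution of
map values is pushed far from an exponential decaying from zero — at which
point no significance level in the working range separates helix ridges
from background (the ridge maximum sits around five background medians
while a $10^{-3}$ threshold needs ten). Thin lines keep the map sparse,
preserve the exponential background shape the thresholding model assumes,
and let collinear lines from neighboring tiles pile up into narrow, easily
skeletonized ridges.

## Thresholding against an exponential null

Non-zero background map values are modeled as exponential with scale
$\lambda$, estimated robustly as $\hat\lambda = \mathrm{median}/\ln 2$ (the
median of an exponential of scale $s$ is $s\ln 2$). Because the median is
insensitive to the high-value tail, the estimate barely moves even when a
sizable fraction of the map lies on helix ridges; replacing a random 5 % of
values by gross outliers shifts it by under 8 %. A pixel is kept when its
upper-tail p-value $\exp(-x/\hat\lambda)$ falls below the user's
significance level $\alpha$, i.e. above the cutoff
$\hat\lambda\ln(1/\alpha)$. On pure exponential noise the above-threshold
fraction equals $\alpha$ by construction; the test suite verifies this
calibration on $10^6$ simulated pixels. Useful working values of $\alpha$
range over roughly $10^{-1}$–$10^{-6}$ depending on specimen contrast,
which is why the package ships a grid-search optimizer rather than a single
default.

## Skeletons, branch points and crossings

The thresholded map is thinned to one-pixel-wide, 8-connected skeletons by
iterative two-subiteration (Guo–Hall-style) morphological thinning, which
preserves component counts and is idempotent on already-thin input.
Crossing filaments meet in branch points: skeleton pixels with at least
three emanating one-pixel paths. On a thinned skeleton a branch pixel's
3×3 neighborhood is tightly constrained: grouping the eight ring neighbors
into maximal runs of cyclically consecutive set positions (one run = one
emanating path), a branch point has $\ge 3$ runs and at most 4 set
neighbors (five or more cannot survive thinning). Exhaustive enumeration
of all 256 center-set neighborhoods under this criterion yields exactly
seven unique three-branch tiles up to 90° rotations and mirroring — the
T- and Y-junction family — plus the two four-branch crossings ('+' and
'X'). The full lookup set (all rotations and mirror images, 42 raw
patterns) is matched in a single pass by convolving the skeleton with a
3×3 kernel of powers of two, which gives every pixel a unique code in
$[0, 511]$.

A circular area of one helix diameter (radius = half the helix width) is
erased around every branch point, severing crossing helices into separate
components; the overlap region is discarded, never re-linked. An erase
radius of a full helix width was tried and rejected: it chops the flanking
fragments below typical minimum-length cutoffs and measurably destroys
recall on the synthetic benchmark.

When walking the final branch-free components into ordered paths, a pixel
is treated as an error only if it has $\ge 3$ emanating *runs*. Raw degree
$\ge 3$ is allowed when two of the neighbors are an adjacent pair: thin
8-connected skeletons legitimately contain such staircase corners, and
aborting on them would discard valid traces.

## From paths to traces

Paths shorter than the minimum helix length are dropped (contamination and
noise produce short paths); paths longer than the maximum are split into
near-equal pieces, which also imposes a comparable stiffness restraint on
the polynomial fits. Each path is rotated into its principal-axis frame —
a naive $y(x)$ fit fails for near-vertical traces — fitted with a
polynomial (order 1 below 500 Å, 2 up to 2000 Å, 3 above; a quadratic is
sufficient even for flexible polymers at these lengths), and resampled at
equal arc-length steps (default 70 Å, the lower end of typical tile
steps). The final resampled point is the curve end and is exempt from the
equidistance guarantee.

Trace ends deserve a caveat: because every tile whose window still contains
a filament draws a full-length line centered on its own tile center, ridges
extend up to about half a tile beyond the physical filament end. This end
ambiguity is axial, not lateral; the evaluation protocol excludes end discs
for precisely this reason, and downstream segmentation re-establishes ends
anyway.

## Flexibility: two estimators

Per trace, the closed form $\lambda = -\ln(2(R/L)^2 - 1)/L$, $p = 1/\lambda$
maps straightness to a persistence length. Its domain ends at
$R/L = 1/\sqrt 2$; below that the trace is flagged maximally flexible
(sentinel $p = 0$, always pruned) rather than raising an error
mid-pipeline. Population pruning operates on $\ln p$ (persistence lengths
are log-normal across a helix population) with median/MAD location and
scale and a default cutoff of 2 robust standard deviations below the
median, which removes about 2.3 % of a clean population.

At ensemble level, the persistence length is the decay constant of the
mean tangent-vector correlation, fitted as $\exp(-s/p)$ weighted by the
number of contributing pairs (linearized through the origin when all
correlations are positive, a 1-D nonlinear search otherwise; separations
with fewer than 10 pairs are excluded). The worm-like-chain simulator is
built to the matching operational convention: planar chains whose tangent
angle takes i.i.d. normal increments of variance $2\,\delta/p$ per segment
$\delta$, so that $\langle t(u)\cdot t(u+s)\rangle = e^{-s/p}$ exactly in
expectation and simulator and estimator are exact inverses. Conventions
differing by a factor of 2 exist for 2-D vs 3-D chains; this self-consistent
pair was chosen deliberately, and the per-trace and ensemble estimators are
exposed side by side rather than reconciled by a model-dependent constant.
The two agree only up to such a constant on real populations; pruning uses
relative values only and is unaffected.

## Evaluation protocol

Result and truth traces are rasterized onto 25 Å binary grids. Precision is
the fraction of result cells covered by the helix-width-inflated truth
grid; recall is the fraction of truth cells covered by the inflated result
grid; F1 is their harmonic mean, with $0/0$ defined as 0 for empty results.
A 400 Å margin at the micrograph boundary and discs of one helix width
("two helix radii") around every trace endpoint — of both sets, applied to
both grids — are excluded. Grid cells are half-open squares. The grid
search over $(\alpha, \text{min length})$ re-runs only the cheap extraction
stages on precomputed correlation maps; ties resolve toward larger $\alpha$
and then smaller minimum length (the more inclusive, less tuned corner).

## The synthetic scenes

`generate_synthetic_scene()` draws filament center lines from the
worm-like-chain simulator, renders each as a soft-edged ribbon
($\cos^2$ cross-section) of the requested width with a sinusoidal axial
modulation (default period 50 Å, modulation depth 0.5) — the modulation is
what produces layer lines in tile power spectra — and adds Gaussian white
noise so that var(signal)/var(noise) equals the requested SNR. Default
conditions used throughout the tests: 10 filaments of 800–1600 Å in a
4000 Å frame at 10 Å/px and SNR 0.1, traced with 500 Å tiles at 80 %
overlap; the quantitative flexibility checks use 1000 chains of 3000 Å at
20 Å segments, with 100-chain ensembles for visualization. These sizes keep
the full synthetic benchmark (20 micrographs plus a parameter grid search
and a 40-image noise-only calibration) to a few minutes on one CPU.

What the scenes do *not* emulate: contrast-transfer-function oscillations
(deliberately — tracing uses only low-frequency contrast and needs no CTF
correction), structured backgrounds (carbon edges, crystalline ice),
intensity ramps beyond what the high-pass removes, 3-D projection effects
of out-of-plane tilted filaments, and polymorphic mixtures. Passing the
synthetic benchmark therefore demonstrates the correctness and calibration
of the algorithm, not its performance envelope on any particular real
specimen; on real data the reference quality (a class average versus a
single boxed helix) and the $\alpha$/min-length optimization against a
small interactively traced subset carry that burden.

## Degenerate inputs and numerical choices

* Constant images: normalization defines SD = 1; outlier suppression
  returns the input when MAD = 0; zero-variance tiles report cc-score 0.
* All-zero power spectra raise an undefined-angle error rather than
  returning an arbitrary angle.
* Rotations use bilinear interpolation about the FFT-center pixel
  (`floor(n/2) + 1`), with log-scaled power spectra (`log1p`) to compress
  their dynamic range; angle ties resolve to the smallest angle, peak-shift
  ties to the smallest |Δ|.
* The angular step defaults to 1° over $[0, 180)$ (Friedel symmetry makes
  $\theta$ and $\theta + 180°$ indistinguishable).
* Closed skeleton loops are cut at an arbitrary pixel, flagged, and
  processed as open paths.
* The literal factor 1.41 (not $\sqrt 2$) is used for the tile mask width,
  and MAD is converted to an SD equivalent with 1.4826 throughout.
* The high-pass is applied to the binned image, with frequencies expressed
  relative to the binned Nyquist.
* Binning is block averaging with remainder rows/columns dropped:
  deterministic and locally mean-conserving, unlike Fourier cropping.

## Known limitations

Helices closer than about one tile step are not reliably separated; traces
are not re-linked across erased crossings; polarity, out-of-plane tilt and
3-D reconstruction are out of scope. End coordinates carry the half-tile
axial ambiguity discussed above. The brute-force joint $(\theta, x, y)$
search agrees with the separated search to one angular step and one pixel
on synthetic tiles, but both inherit the integer-precision peak.
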