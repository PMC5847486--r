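# helixtracer

Automated tracing of filamentous and helical assemblies in electron
cryo-micrographs, with ensemble flexibility analysis.

Helical specimens — viruses like TMV, cytoskeletal filaments like ParM,
amyloid-like polymers such as p62-PB1 — appear in cryo-micrographs as
elongated objects with a repeating axial pattern, buried in heavy shot
noise. Helical reconstruction needs their positions as *traces*: start and
end coordinates joined by equidistant segment coordinates along the (often
curved) helical axis. Picking these interactively over thousands of
micrographs is the bottleneck this package removes. It also measures, from
the same traces, the persistence length of the polymer ensemble — a direct
readout of the assembly's mechanical stiffness and of its prospects for
high-resolution reconstruction.

## Method

The micrograph is binned, normalized, high-pass filtered (Gaussian,
half-maximum at 4 % of Nyquist) and cleared of extreme dark outliers
(median/MAD normal model, lower-tail p < 0.001). It is then windowed into
overlapping square tiles (350–500 Å, 80 % overlap), small enough that a
helix crosses each tile as an approximately straight line. For every tile,
the in-plane axis angle θ is found by rotational correlation between the
power spectra of the tile and of a vertical reference helix — the layer
lines of helical diffraction make this search insensitive to translation —
and a single real-space cross-correlation of the back-rotated tile against
the reference yields the normal offset Δ of the axis from the tile center
plus a normalized cc-score.

Each (θ, Δ, cc) is drawn back into a micrograph-shaped correlation map as a
thin cc-intensity line; tiles sharing a helix reinforce each other along
its path, noise tiles do not. Background map values follow an exponential
distribution whose scale is fitted robustly as λ = median/ln 2, and pixels
with upper-tail p-value exp(−x/λ) below a user-chosen significance level α
are kept. The binary map is thinned to one-pixel skeletons
(connectivity-preserving morphological thinning), crossings are located by
a 3×3 power-of-two response filter against a precomputed branch-template
lookup (seven canonical three-branch tiles up to rotation/mirroring, plus
the two four-branch crossings) and erased with a helix-diameter disc.
Remaining components are length-filtered, split if over-long, fitted with
order-1–3 polynomials in their principal-axis frame, and resampled at
equal arc-length spacing.

Per trace, flexibility follows from the end-to-end distance R and contour
length L:

    λ = −ln(2 (R/L)² − 1) / L,   p = 1/λ

and the population is pruned of traces whose ln p falls more than
`n_sigma` robust standard deviations below the population median
(persistence lengths are log-normally distributed). At ensemble level, the
persistence length is estimated by fitting exp(−s/p) to the mean
tangent-vector correlation at arc separation s; a discrete planar
worm-like-chain simulator with the matching convention (angle increments
of variance 2·segment/p) provides calibration ensembles.

Tracing quality is scored against ground truth as a binary classification
on 25 Å grids (precision, recall, F1 = 2PR/(P+R), with helix-width
inflation, a 400 Å boundary margin and end-disc exclusion), and the
extraction parameters (α, minimum length) can be optimized by grid search
on a small annotated subset.

## Worked example

Trace a synthetic micrograph (10 worm-like filaments at SNR 0.1, 4000 Å
frame, 10 Å pixels) against a matched synthetic reference, and score the
result against the generator's ground truth:

```r
library(helixtracer)

scene <- generate_synthetic_scene(n_filaments = 10, snr = 0.1,
                                  image_A = 4000, pixel_size_A = 10,
                                  seed = 42)
ref <- synthetic_reference(helix_width_A = 100, axial_repeat_A = 50,
                           pixel_size_A = 10, size_px = 50)
params <- tracing_params(tile_size_A = 500, overlap_pct = 80,
                         binning_factor = 1, helix_width_A = 100,
                         min_helix_len_A = 594, max_helix_len_A = 1500,
                         alpha = 0.001)

traces <- trace_micrograph(scene$micrograph, ref, params, prune = FALSE)
print(traces)
#> trace_set: 13 helix traces
#>   contour length: 619-1272 A (median 828 A)
#>   persistence length: median 44.7 um (13 finite)

evaluate_traces(traces, scene$truth_traces, helix_width_A = 100,
                extent_A = c(4000, 4000))
#> precision 1.0000  recall 0.8320  F1 0.9083  (296/296 result, 307/369 truth cells)
```

Every reported trace cell coincides with the true filament paths
(precision 1), and 83 % of the true path area is recovered at this α
without any parameter tuning; 10 filaments come back as 13 traces because
over-long ones are split at `max_helix_len_A` and crossings are severed.

The flexibility side, recovering a known persistence length from a
simulated ensemble (1000 chains of 3000 Å, 20 Å segments, ParM-like
stiffness):

```r
ens <- simulate_wlc(1000, 3000, 20, 33.9e4, seed = 1)
p_hat <- fit_persistence(tangent_correlation(ens, max_sep_A = 3000))
p_hat / 1e4
#> [1] 35.1   # um; generating value 33.9 um
```

A thin command-line front end (`exec/helixtracer`) exposes `trace`,
`evaluate`, `optimize`, `simulate` and `synthesize` subcommands over MRC
micrographs and EMAN-style box files, e.g.

```sh
Rscript exec/helixtracer synthesize --output scene.mrc --truth-out truth.box
Rscript exec/helixtracer trace --input scene.mrc --reference ref.mrc \
    --output traces.box --pixel-size 10
```

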