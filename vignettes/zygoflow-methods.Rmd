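---
title: "Measuring zygote shape change and cytoplasmic flow: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring zygote shape change and cytoplasmic flow: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`zygoflow` measures two families of phenomena in bright-field time-lapse
recordings of mammalian zygotes: slow, repeated changes of the cell
profile (shape sequences, cytokinetic elongation and indentation) and
motion of the cytoplasm itself (mean flow, vortices, their signs and
persistence). This vignette explains each model, its assumptions, the
parameters that matter, and the design decisions taken where more than
one reasonable choice existed.

## Conventions

Images are single-focal-plane grayscale matrices indexed `(row, col)`,
1-based, origin top-left. Angles are degrees from image "up" (decreasing
row), increasing toward image-right — clockwise on the displayed image,
which is the counter-clockwise mathematical orientation once the y-axis
flip of image coordinates is taken into account. The vertical diameter is
therefore at 0°. All algorithms work in pixels and frames; conversion to
µm, µm², µm/min and 1/min happens only in the reporting layer, using the
configured µm/px and min/frame calibration (typical recordings:
0.26–0.5 µm/px, 1–2 min/frame).

## Outline detection

The boundary is modelled as a star-shaped radius function r(θ) about a
seed centre, discretised to A angular bins (default 360) and 1 px radial
bins in a user band [r_min, r_max]. The objective maximised is the sum of
Sobel gradient magnitudes sampled (bilinearly) on the polar unwrap, minus
a quadratic roughness penalty `s·Σ(Δr)²` and a quadratic temporal penalty
`w·Σ(r − r_prev)²` toward the previous frame's outline. A dynamic program
over the radial states solves this exactly for each admissible start
radius; circular closure r(0) = r(A) is enforced by solving once per
start radius on a coarse grid (every 4th radius) and refining around the
best, which bounds the cost while staying exact in practice (an exact
sweep, `coarse_step = 1`, is available and is what the optimality tests
use). Per-step radial moves are capped at ±2 px.

Numerical choices:

* The edge map is normalised to maximum 1 before the DP, making the
  result invariant to positive intensity scaling and making `s` and `w`
  dimensionless relative to peak edge strength. Defaults `s = 0.1`,
  `w = 0.02` (tracking).
* The penalties are quadratic; linear alternatives would tolerate sharp
  steps better, but quadratic matches the smooth membranes seen in
  bright-field embryo images and makes small roughness strictly cheaper.
* A frame whose radial band contains no edge energy raises a
  segmentation failure; during tracking such frames are interpolated
  linearly in r(θ) between flanking successes and flagged, and the run
  aborts if more than half the frames fail.
* The zona pellucida is detected with the same machinery in a larger
  radial band; because the zona has an inner and an outer edge, an
  `edge_polarity` option restricts candidate edges by the sign of the
  radial intensity gradient (default: unrestricted).
* An annotated second polar body can widen the admissible radius band
  near its angle (`r_max_per_angle`), since both the "diameter based on
  the 2PB" and the "diameter plus 2PB width" conventions are in use.

The centre reported with each outline is the area centroid (CoA) of the
boundary polygon by the shoelace formula, accurate to numerical
round-off, and the seed for the next frame during tracking — so the
detector follows a drifting cell.

## Radial morphometrics

36 radii at 10° steps are measured from the CoA to the boundary polygon
by exact ray–segment intersection; diameters are opposite-radius sums, so
every diameter passes through the CoA by construction. Concave outlines
(cytokinesis) can cross a ray more than once; the farthest crossing is
the default so that diameters grow monotonically under elongation, with
"first crossing" exposed as an option. The per-frame shape index is the
sample SD (n−1) of the 18 diameters; population SD would differ only by
the constant √(17/18) ≈ 0.972, and the choice is recorded here and in the
output metadata.

## Shape sequences and elongation

Candidate sequences are trough–peak–trough triplets of the
moving-average-smoothed SD trace (window 3 frames), with peaks required
to have a topographic prominence of at least 0.3 µm — enough to reject
pixel-level noise while keeping small real sequences (the smallest
reported in-out-in changes are ≈ 2.7 µm). For each triplet, each of the
18 diameters is tested for a rise of ≥ 1.5 µm from first trough to peak
(the defining rule) followed by a fall of at least 0.5 µm — the
retraction side is only required to clear a measurement-noise floor,
since the defining rule quantifies the extension half only. The sequence
carries the angle of the maximal in–out–in change, `min(rise, fall)`,
ties broken toward the smaller angle. Flat SD troughs take their widest
extent. Overlapping sequences are reported independently per triplet, and
no merging is attempted.

The elongation axis is the diameter with the greatest extension between a
chosen pre-division frame and the first-furrow frame; the "first step" is
the earliest ≥ 1 µm increase of that diameter within a 2-min window
(whole-frame windows; the nearest is used and recorded when the frame
interval does not divide 2 min). Surface indents are angular local maxima
of the depth below the convex-hull radius, supporting automatic one-/two-
indent staging when manual annotations are absent.

## PIV

Motion between consecutive frames is estimated by normalized
cross-correlation of square interrogation windows, multi-pass: the first
pass uses `initial_window` px (default 64), each later pass halves the
window down to `final_window` (default 32; 16 for low-noise recordings),
shifting the second frame's window by the bilinearly interpolated coarse
displacement before correlating. Windows overlap 50 % by default.
Correlation planes are computed by FFT on mean-subtracted windows and
normalised by the window norms; the peak is restricted to a quarter-window
search radius, localised to sub-pixel precision by a three-point Gaussian
fit per axis (parabolic fallback when a log is undefined), and validated
by requiring a positive peak and a peak-to-second-peak ratio ≥ 1.2.
Textureless windows are invalid vectors, not errors. Vectors are bounded
by half the initial window. Fields store px/frame; summaries (mean vector
inside the cell outline, mean magnitude in a cytoplasm rectangle) report
µm/min with units embedded in output column names.

On synthetic rigid translations the recovered field is accurate to
≈ 0.05 px RMS; the multi-pass schedule is required for strongly sheared
flows, where a single 64-px pass smears the correlation peak.

## Vorticity and sign comparisons

Vorticity at a grid point is taken from a least-squares fit of a local
linear velocity model (u and v each affine in x, y) over the valid
vectors of the surrounding 3×3 neighbourhood; the curl is read off the
fitted gradients. Because only 4 valid supports (with full rank) are
needed, the estimator tolerates the incomplete, intermittent vector
patterns characteristic of two-cell cytoplasm — a partial arc of vectors
still yields the local rotation. On complete grids and linear fields it
reduces exactly to central differences. Points with fewer than 4 valid
neighbours are undefined rather than extrapolated. Positive vorticity is
counter-clockwise on the displayed image, stated in output headers.

Per-region series average the defined vorticity inside a mask and
threshold the sign at a noise floor (default 0.005 /min, or 2× the SD of
a user-designated quiescent interval); frames with fewer than 4 defined
grid points get sign 0 and never enter tests. Because interrogation
windows that straddle the static membrane are biased toward zero
displacement, region masks should be eroded away from the boundary
(`erode_mask`, default 8 px in the pipeline) — this is the masked-region
analogue of placing the measurement rectangle "inside the cytoplasm".

Half-cells are produced by cutting the mask with the perpendicular
bisector of its longest axis (maximal-distance chord between convex-hull
points, or an annotated axis, which takes precedence). Signs of two
regions are compared per 100-min window — the first window
conventionally starting 30–99 min after the two-indents stage — with
Pearson's chi-squared on the 2×2 (+, −) count table, 1 df, applying
Yates' continuity correction when any expected count is below 5 (the
stated significance threshold being 0.05); windows where either region
has fewer than 5 defined signs are reported untestable rather than
tested. Fisher's exact test was considered for small counts and is easy
to substitute, but chi-squared is the convention in this literature; with
the Yates rule above, a fully-opposed 20-vs-20 window gives X² = 40.

## The synthetic generator

`render_scenario()` emulates the features of real recordings that the
analysis depends on: a textured cell (blurred-noise cytoplasm plus dark
granules) inside a static, slightly oval zona ring (axis ratio default
1.07, in the observed 1.05–1.09 range); per-diameter shape modulation
with a smooth angular bump (half-width 18°, so a modulated diameter's
10°-neighbours are partially affected, as real protrusions are);
cytokinetic elongation `R(θ) ∝ e(t)cos²(θ−α)` with perpendicular slimming
and scripted indents; and flow models — translation, solid-body rotation
(optionally with a transient speed burst, emulating the sharp speed
spikes around pronuclear envelope breakdown), Rankine vortex pairs, and
piecewise-rigid "mirror rotation" about two centres for the idealised
one-dominant-vortex-per-cell regime. Texture is advected by composing the
backward displacement map across frames and sampling the original texture
once per frame, so interpolation blur does not accumulate; under
incompressible flows the mean interior intensity changes by < 1 % per
frame. Ground-truth outlines, per-cell masks, flow vectors at grid points
(written from the model, never re-estimated) and injected event lists are
returned alongside the stack. A fixed seed gives bit-identical stacks.

Defaults are a 38 µm cell radius, 0.5 µm/px, 2 min/frame, additive
Gaussian intensity noise of SD 0.01 — chosen so PIV validity stays above
90 %, mirroring usable real footage. What the generator does **not**
emulate: optics (no point-spread function, no defocus), 3-D structure
(granules leaving the focal plane), illumination drift, and embryo
"acrobatics" (whole-embryo rolling). Passing tests on these scenes
therefore demonstrate correctness of the measurement chain, not
robustness to every real-world nuisance; the temporal-bias and validation
parameters exist precisely for the latter.

Presets: `interphase_cycles` (two 3 µm cycles on the 140° diameter),
`pnebd_burst` (4× rotation speed spike mid-recording),
`cytokinesis_vortices` (mirrored Rankine vortices, 61 frames = 60 frame
pairs at 2 min), `two_cell_persistence` (mirror rotation sampled every
10 min for 560 min, so opposed signs persist across all 100-min windows;
10-min sampling keeps the desk-scale run small while the per-pair
displacement stays within the PIV search range). The vortex presets use a
softer membrane and higher texture contrast than the one-cell presets:
two-cell scenes are analysed through masks rather than the outline
detector, and the softer boundary keeps boundary-straddling interrogation
windows from locking onto the static edge.

## Pipeline and problem sizes

`run_pipeline()` composes the stages purely over the frame stack — no
stage mutates another's outputs — writes CSV/JSON/PNG artifacts with
units in column names, and is deterministic given config and seed
(reruns are byte-identical). Optional PIV caching stores fields under the
run's output directory keyed by an MD5 of the PIV-relevant config subset,
so threshold-only changes do not recompute the slow stage; it is off by
default to keep default runs self-contained.

The test-suite and acceptance scenes use 257² px frames, 10–61 frames per
scene, and 256²–1024² px frames for PIV accuracy checks; these sizes were
chosen as the smallest at which every phenomenon of interest (multi-pass
gain, vortex cores, 100-min windows) is cleanly expressed.

## Known limitations

* The outline model is star-shaped about the seed: deeply re-entrant
  shapes (late cytokinesis necks) are followed only as far as a single
  radius per angle allows; two-cell stages are better handled as two
  masks.
* PIV near the membrane is biased toward the static boundary; erode
  masks before averaging vorticity (done by default in the pipeline).
* The chi-squared sign test treats frames as independent; slowly varying
  vorticity makes neighbouring frames correlated, so p-values on real
  data are optimistic and should be read as scores, as is conventional.
* Classification of sequences into interphase/PNEBD/mitotic is a join
  against user annotations, not an algorithm.
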