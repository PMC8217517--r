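---
title: "Waveform variables, COSA classification and neck morphometry: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Waveform variables, COSA classification and neck morphometry: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosawave)
```

`cosawave` measures how the neck of a mammalian sperm deforms in concert
with the flagellar beat. This vignette explains the models behind each
layer, the parameters that matter, what the synthetic-specimen generator
does and does not emulate, and the numerical and design choices that were
genuinely open.

## Coordinate conventions

Everything lives in the head-anchored frame: the head long axis is the +x
axis (pointing caudally, toward the tail), the neck sits at the origin,
and +y is the sperm's **right**. All lengths are nm; angles are stored in
radians and reported in degrees, signed positive toward the right. Signed
displacements *d* between paired left/right structures are projections on
the rostral direction of the neck midline: *d* > 0 means the right-side
structure sits more rostrally ("higher") than its left partner. Every
signed quantity in the package is odd under a mirror flip of the specimen
— a property the test suite checks exhaustively.

One sign consequence worth spelling out: when the head kinks to the left
while the tail beats left, the *neck midline seen from the head frame*
rotates toward the head's right. Left-bent cells therefore show positive
head-neck angles under this convention, while their tail deflection ȳ and
curvature κ̄ are negative.

## The sliding-filament waveform variables

The flagellum is abstracted as two filaments r±(s) = r(s) ± (a/2)·n̂(s)
separated by the flagellar diameter a = 600 nm. Because the filaments run
on opposite sides of a curved centerline they travel different contour
lengths, giving the arclength mismatch

Δ(s) = a·(θ(s) − θ₀),

with θ(s) the tangent angle and θ₀ its value at the base. Δ(s) is the
flagellar sliding in the absence of basal sliding: the basal offset Δ₀ is
fixed at zero here, and basal sliding is measured *independently* from
neck landmarks, never inferred from the waveform. The signed curvature is
κ(s) = dθ/ds. Per cell we report the signed arclength means ȳ, Δ̄, κ̄
(signed, not absolute — a left-biased population is skewed negative in all
three). Averages run over the full traced arclength.

Numerics: waveforms live on a uniform arclength grid (default ds =
100 nm, linear resampling); θ comes from central differences with
second-order one-sided stencils at the ends, unwrapped to remove ±π
jumps; κ is the central difference of θ. On constant-curvature arcs these
operators are exact to rounding; on generic waveforms the residual of
∫κ ds against θ(L) − θ₀ is the trapezoid's O(ds²) term (about 10⁻⁴ rad at
ds = 100 nm), and the tests verify the second-order convergence rather
than pretending the identity is exact.

## Tracing centerlines from images

The tracer replaces a human-assisted step with a deterministic one: Otsu
threshold → Zhang-Suen thinning → 8-connected skeleton graph (diagonal
edges that merely shortcut an orthogonal two-step are dropped, otherwise
staircase corners masquerade as branch points) → spurs shorter than 10
pixels pruned → the longest geodesic path from the skeleton endpoint
nearest a seed point, which stands in for the human click. Pixel paths are
smoothed with a centered moving average before conversion to nm.

The smoothing window is an explicit parameter because curvature is
derivative-sensitive. The default is 9 samples: at 100 nm pixels the
skeleton staircase leaves ≈ 2.8° RMS tangent error with a 5-sample
window, 1.7° with 9, while the bias on a 10 µm arc radius stays near
0.1%. Pixel size is a mandatory, explicit parameter — nothing on disk is
ever in pixels.

## COSA: orientation and bend classification

Cells are first made chirality-comparable: if the proximal centriole
marker lies on the −y side the specimen is mirror-flipped (the PC always
leans to the head's right after normalization; the bigger rod lands on
the left). Without a PC marker, rod-size asymmetry is the proxy; if both
are unusable the cell is rejected rather than guessed.

Classification uses the normalized deflection D = ȳ/L. The thresholds are
conventions, not measured quantities — the original scoring was by eye —
so they are parameters, reported in the output metadata: straight for
|D| < T₁ = 0.03, slight right for D ≥ T₁, mild left for −T₂ < D ≤ −T₁
with T₂ = 0.12, sharp left for D ≤ −T₂. ȳ was chosen as the statistic
because it is the frame's own amplitude measure. Left bends are subtyped
type 1 (kink-dominated, |head-neck angle| ≥ K = 30°) or type 2. A
rightward deflection beyond T₂ is *reported* as slight right with a
warning flag rather than erroring: the absence of sharp right bends in
real populations is a finding, not an impossibility.

## Neck morphometry

Landmark-based metrics: rod sliding d at the rostral and caudal rod ends
(microtubules rostral-only, since they are continuous with the axoneme);
the caudal rod d carries the rods' built-in length asymmetry (left 700 nm
vs right 450 nm in the template) on top of any sliding. PC rocking is the
signed angle between PC axis and neck midline; PC lateral shift the
signed perpendicular distance of the PC midpoint from the midline.
Segmented columns give nine per-segment d values and eight step angles
measured against the neck midline — defined that way because nine
segments yield eight inter-segment steps, and in left-bent cells the
kink sits between segments 8 and 9.

Cloud-based metrics use the 50%-of-peak rule: localizations are projected
on an axis, binned into an intensity-weighted histogram (default bin
20 nm, about the localization precision of the imaging this emulates),
and the extent runs between the 50%-of-peak crossings outward of the
first and last local maxima, linearly interpolated between bin centers.
The rule is invariant to rescaling all intensities by a positive
constant. Three-dimensional localizations are projected to the beat plane
before 2-D metrics, on the grounds that the beat is planar; z is retained
in the tables. ROI intensities are plain pixel sums inside a 1.5 µm
disc.

## The statistics layer

Pearson correlation/regression, the unpaired two-tailed t test
(pooled-variance Student by default, Welch behind a flag), Bartlett's
sphericity, KMO, principal-component factor extraction and varimax
rotation are implemented from first principles; base R's `cor.test`,
`t.test` and `stats::varimax` appear in the tests as independent
cross-checks only. Extraction is principal-component (loading column j =
eigvec_j·√eigval_j) — the common default of commercial EFA software, and
the natural partner of the eigenvalue-greater-than-1 retention rule used
when the factor count is "auto"; the scree vector is always returned so a
user can override the count, which is how scree-plot judgment is meant to
work. Varimax applies Kaiser row-normalization before rotating (on by
default, switchable) and iterates closed-form pairwise rotations until
the criterion gain drops below 10⁻¹⁰; the rotation matrix stays
orthogonal to 10⁻¹⁰ and communalities are preserved. Variables contribute
to a factor when |loading| > 0.40. No multiple-testing correction is
applied; p-values are reported raw with the usual star conventions.

KMO is undefined on an exactly diagonal correlation matrix (0/0); that is
an explicit error, and a singular matrix in Bartlett's test reports
χ² = ∞ with a flag rather than failing silently.

## What the synthetic generator emulates

Each specimen carries a latent bend phase ψ ∈ [−1, 0.6], drawn uniformly
within a class-specific sub-interval (sharp left [−1, −0.7], mild left
[−0.7, −0.2], straight [−0.2, 0.2], slight right [0.2, 0.6]) — the
population is a set of snapshots frozen at different beat phases, never
reaching the sharp-right extreme. Class weights default to the observed
mixture (15/30/36/19%). All neck deformations are affine in ψ
(metric = −ψ·span/2), which makes the truth metrics perfectly correlated
across the population — the strong-coupling limit of one coordinated
tail-to-head movement.

Two calibrations deserve emphasis:

* **Coupling spans.** With the class sub-intervals above, the expected
  sharp-left vs slight-right contrast of any coupled metric is
  0.625 × span. The default spans are therefore the observed swings
  divided by 0.625 — PC rocking 38.4° (contrast 24°), head kink 72°
  (45°), rod sliding 472 nm (295 nm), PC lateral 272 nm (170 nm) — so the
  *measurable population contrast*, not the raw parameter, reproduces the
  reported magnitudes.
* **Bend gain.** The centerline's tangent profile is
  θ(s) = α + b·w(s) + A_θ·sin(2πs/λ), with α the head-kink angle, w(s) a
  smoothstep envelope saturating at 12 µm (a linear ramp cannot reach the
  sharp-left deflections once the kink tilts the proximal tail), and the
  gain b solved numerically so that D = ȳ/L lands on a piecewise-linear
  target in ψ whose gaps straddle the classifier thresholds. Zero-noise
  specimens therefore classify back to their true class with margin — by
  construction, which is exactly what a classifier-validation fixture
  should do.

Noise is isotropic Gaussian on landmark coordinates (default 10 nm) and
localization positions (20 nm); the template neck geometry (rod lengths
700/450 nm, thicknesses 120/80 nm, DC width 300 nm with the microtubule
bundle 10% wider rostrally, PC offset 250 nm to the right) is fixed.
Determinism is strict: per-specimen random substreams derive from the
master seed by counter, so populations are byte-identical under a seed
and specimen k is unchanged when the population grows.

What the generator does **not** emulate: time-resolved beating (no
movies), 3-D rod geometry, localization drift or blinking artifacts,
optical PSF structure beyond a Gaussian line profile, cell-to-cell
variation in the neck template, or any force balance — couplings are
kinematic impositions, not mechanics. Passing recovery tests therefore
shows the *measurement* layer is unbiased at realistic noise, not that
real sperm obey a single-phase affine model. One consequence: because one
ψ drives everything, the variance structure across cells of the three
PC-line-to-microtubule distances is shared, and analyses that depend on
some metrics being decoupled (for instance a stable-DC-center factor)
cannot be reproduced by this generator.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run populations of 25–248
specimens, 100 per group for contrasts, 10⁴ draws where only class labels
or noise moments are needed, and n = 500 for the planted 21-variable
factor-recovery study; these sizes put Monte-Carlo error well inside the
assertion tolerances while keeping the default run in the tens of
seconds. Degenerate inputs fail loudly and early: blank images, seeds off
the foreground, zero-length axes, duplicate polyline points, non-uniform
grids, empty clouds, constant vectors, singular or diagonal correlation
matrices, and factor counts out of range all raise explicit errors.

## Known limitations

* Classification thresholds (T₁, T₂, K) are conventions; with by-eye
  ground truth they could only be tuned, not derived. They are parameters
  everywhere.
* The tracer assumes one cell per image and a non-self-intersecting
  flagellum; strongly curled cells can fold the skeleton path.
* Rod length/width is measured on binned localization profiles;
  rendered-image line profiles would differ in the tails of the PSF.
* The ψ sub-intervals (within-class variability) are a modeling choice;
  group contrasts are insensitive to them only through the 0.625 factor
  above, which is why it is stated explicitly.

```{r session}
sessionInfo()
```
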