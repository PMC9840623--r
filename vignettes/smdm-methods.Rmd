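---
title: "Measuring intracellular diffusion by single-molecule displacement mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intracellular diffusion by single-molecule displacement mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdmap)
```

## The measurement problem

Cytosolic proteins in bacteria diffuse at several µm²/s. At that speed a
molecule traverses a 2 µm cell in tens of milliseconds, so camera-rate
single-particle tracking cannot follow it: between ordinary frames the
molecule moves farther than the typical distance to the *next* molecule and
the identity of a spot is lost. Single-molecule displacement mapping (SMdM)
sidesteps the problem by recording exactly **one displacement per molecule
per frame pair**: two short excitation pulses are placed at the end of one
camera frame and the start of the next, separated by a programmable
peak-to-peak time Δt (1.5–10 ms, far shorter than the 17.86 ms frame). A
molecule localized in both frames of a pair yields one displacement `r`
over a precisely known Δt; pooling tens of thousands of such displacements
gives the local diffusion coefficient, and binning them by starting
position gives a *map* of diffusivity at 50 nm resolution inside a single
bacterial cell.

`smdmap` implements the full analysis chain — spot localization, drift
correction, cell segmentation, displacement pairing, maximum-likelihood
fitting, map reconstruction, and slow-molecule single-particle tracking
(SPT) — together with a Brownian-dynamics generator of synthetic data so
that every stage can be verified quantitatively without any experimental
input.

## The displacement model

For isotropic 2D Brownian motion the step length over a fixed Δt follows a
Rayleigh distribution,

$$P(r,\Delta t) = \frac{2r}{4D\Delta t}\,e^{-r^2/4D\Delta t},$$

equivalently `mean(r²) = 4 D Δt`. Two experimental realities modify it:

* **Pairing uncertainty.** The second-frame partner of a molecule is found
  by searching a disc of radius `r_max` = 600 nm. Unrelated molecules or
  background localizations inside that disc create false pairs whose
  abundance grows linearly with `r` (a ring of radius `r` has circumference
  ∝ `r`). A term `b·r` with a free slope `b ≥ 0` absorbs them.
* **Truncation.** Displacements beyond `r_max` are never observed, so the
  density is renormalized on `[0, r_max]`.

With `N` diffusive components (fractions `f_i`, coefficients `D_i`) the
fitted density is

$$P(r,\Delta t) = \frac{\sum_{i=1}^{N} f_i \frac{2r}{4D_i\Delta t}
  e^{-r^2/4D_i\Delta t} + br}
  {1-\sum_{i=1}^{N} f_i\,e^{-r_{max}^2/4D_i\Delta t}
  + \frac{b}{2}r_{max}^2},$$

whose normalization on `[0, r_max]` is exact (the package tests verify it
to 1e-8 by adaptive quadrature across a parameter sweep). The cutoff itself
is safe for bacterial proteins: if *every* displacement sat at 600 nm the
implied D would be 60 µm²/s at Δt = 1.5 ms and 9 µm²/s at Δt = 10 ms — an
order of magnitude above anything measured in cells — so essentially no
genuine displacement is lost.

`fit_displacement_mle()` maximizes the log-likelihood over
`{D_i, f_i, b}` on transformed coordinates (log D, stick-breaking
fractions, log background weight) with `stats::nlminb`, starting from a
deterministic multistart (method-of-moments plus quantile-split
initializers) so results are reproducible without randomness. The best
log-likelihood wins. Components are reported sorted by descending D. The
N = 1, b = 0, untruncated special case has the closed-form solution
`mean(r²)/(4Δt)`, which `closed_form_diffusion()` exposes; the tests
require the optimizer to agree with it to 1% when truncation is
negligible. SPT step-size fits use the same machinery with `b = 0` and no
truncation, since ambiguous links are discarded during tracking rather
than modelled.

Choices worth knowing about:

* All candidate partners within `r_max` are retained (not just the nearest);
  the `b·r` term exists precisely to absorb the false ones. Mutually-nearest
  pairing is available behind `pairing = "nearest"` for sensitivity checks.
  With the all-candidates policy the background term is *essential*: the
  package tests show that at 20% contamination the free-`b` fit stays
  within 10% of truth while a `b = 0` fit inflates monotonically with the
  load.
* `b` is fitted per cell (or region) and held fixed during per-pixel map
  fits — a background slope is not identifiable from the ~tens of
  displacements inside one 50 nm pixel.
* Units are nm and ms internally; D is reported in µm²/s (1 µm²/s =
  1000 nm²/ms, applied in exactly one place and covered by tests).
* No correction for localization error or intra-pulse motion blur is
  applied to D̂; the displacement model treats positions as sampled
  instantaneously at the two pulse peaks.

## Localization and drift

Spots are detected per frame by a difference-of-Gaussians band-pass
followed by an 8-neighbour local-maximum test at a threshold of 4 robust
noise SDs, then fitted by Levenberg–Marquardt (`minpack.lm::nlsLM`) with an
elliptical 2D Gaussian PSF model

$$f(x,y) = B + A\,e^{-\left(\frac{(x-x_0)^2}{2\sigma_x^2}
 + \frac{(y-y_0)^2}{2\sigma_y^2}\right)}.$$

Because the camera integrates photons over each 100 nm pixel, the model is
evaluated in its pixel-integrated (erf) form rather than sampled at pixel
centres; with σ ≈ 130 nm the centre-sampled approximation would bias σ by
~2.5%, which the integrated form avoids. Coordinates follow the
pixel-centre convention: 1-based pixel `i` spans `[(i-1)·100, i·100)` nm
and its centre is `(i-0.5)·100` nm, origin at the field's top-left corner.

Fits are rejected with a reason code when the optimizer fails, the centre
leaves the ROI, the amplitude is indistinguishable from background, or a
width sticks to its bound. Two safeguards address near-coincident
emitters: candidate peaks closer than `2σ_PSF` are both discarded, and the
default width acceptance window in `localize_stack()` is deliberately tight
(0.6–1.1 σ_PSF), so that two emitters too close to resolve — which blur
into one wider spot — are rejected rather than reported as a fictitious
midpoint molecule.

Lateral drift is estimated without fiducials by redundant cross-correlation:
the table is cut into 2000-frame segments, each rendered as a 20 nm 2D
histogram, all segment pairs (up to lag 6) are cross-correlated by FFT with
parabolic sub-bin refinement, and the per-segment offsets are solved by
least squares with the first segment pinned at zero, then interpolated
piecewise-linearly over frames. The estimate runs twice: the first pass
removes the bulk drift (which smears segment histograms into streaks), the
second re-estimates on the de-streaked coordinates. On synthetic data with
2 nm/frame of injected drift over 10,000 frames the recovered slope is
within a few percent and the corrected coordinates match the pre-drift
truth with an RMS below the 20 nm localization error; with no injected
drift the estimated series stays below 5 nm at realistic localization
densities (~10⁴ per segment).

## Segmenting cells from the point cloud

Cells are found directly in the localization cloud, with no transmitted-light
image. Each point's local density is the inverse area of its Voronoï
polygon (`deldir`); points with unbounded polygons (the convex hull) get
density zero. Points denser than `alpha_density` (default 2) times the
field-average density — total bounded points over the area they tessellate —
seed clusters as connected components of the Delaunay adjacency graph
restricted to those points. Because a rod-shaped cell seen in projection has
genuinely thinner chords near its outline, rim points fall below the core
threshold; points above a floor of 0.25× the threshold are therefore
attached to the component owned by the majority of their Delaunay
neighbours, which recovers the rim without bridging to the sparse
background. Components are then screened: fewer than `min_points` (default
300) localizations, or an aligned bounding box exceeding 4 µm × 1.5 µm
(two or more cells merged across a small gap), mark the cluster rejected
with a reason; rejected clusters are excluded from all downstream fitting
but reported, so every input row is accounted for.

Accepted clusters are aligned by the eigenvectors of their coordinate
covariance: the leading eigenvector is rotated onto +x, choosing the
rotation in (−90°, 90°] since a cell has no intrinsic left or right.
Alignment operates on the cluster's current coordinates and accumulates
the applied angle, which makes it idempotent; near-isotropic clusters
(eigenvalue ratio < 1.05) are left unrotated with a warning.

Regions follow the cell geometry. A hemispherical pole spans one radius of
the total length; for average cell dimensions (2.02 µm long, 0.32 µm
radius) the ratio is 0.32/2.02 ≈ 0.16, rounded up to a default
`pole_fraction` of 0.2: the leftmost and rightmost 20% of the aligned
x-extent are the poles, the middle 60% the mid-cell region. Displacements
inherit the region of their starting position.

## Diffusivity maps

`build_diffusion_map()` bins displacements by starting position into
50 × 50 nm² pixels of the aligned cell frame and fits each pixel's
displacements with the single-component truncated model (cell-level `b`
held fixed). Pixels with fewer than `min_count` displacements (default 20)
are masked rather than reported; the count map is emitted alongside the D
map. The per-pixel estimate at `n` displacements has a relative SD of about
`1/sqrt(n)`, so maps are only as trustworthy as their counts — which is why
the mask and the count map are first-class outputs.

## Single-particle tracking for slow molecules

Slow, e.g. membrane-associated or complexed, molecules are tracked with
long exposures (30–50 ms) and one pulse per frame. Localizations in
consecutive frames are linked when the match is unambiguous in both
directions within an 800 nm radius; any frame with more than one candidate
in either direction cuts the affected trajectories at that frame, a missed
frame ends a trajectory (no gap closing), and only tracks of 5 to 30 frames
are kept — longer ones are dropped, not truncated, so one bright immobile
particle cannot dominate the pooled statistics. The frame interval used for
fitting is exposure plus camera dead time, taken from configuration rather
than inferred from data. Pooled steps across trajectories are fitted with
the untruncated mixture model.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes:

* **Geometry.** Each cell is a spherocylinder (cylinder of radius R capped
  by hemispheres) with its axis in the focal plane; fields may contain
  several non-overlapping cells at arbitrary orientations. Defaults follow
  the average cell: 2.02 µm length, 0.32 µm radius.
* **Motion.** Cytoplasmic molecules diffuse in 3D with reflecting walls,
  integrated by Euler–Maruyama substeps of Δt/20 (a compiled stepper).
  Membrane molecules perform surface Brownian motion via tangent-plane
  steps re-projected onto the surface at each substep — statistically
  equivalent to intrinsic-coordinate integration but without chart
  bookkeeping at the cap joints; on an open cylinder (`caps = "none"`) the
  intrinsic axial/azimuthal update is exact and used directly. Immobile
  clusters pin all member molecules to one anchor.
* **Acquisition.** Frames are 1-based; pulses sit at the end of odd and
  start of even frames, Δt apart (pair k = frames 2k−1, 2k); the interval
  between pairs is `2·frame_time − Δt`. Timing defaults are the
  experimental ones (17.08 ms exposure, 0.78 ms dead time, ~56 Hz).
  Localizations are the orthographic 2D projection of the 3D positions plus
  isotropic Gaussian error (default σ = 20 nm — a typical localization
  precision, chosen here as a configuration default, not a measured value).
  Each molecule is detected per pulse with `detection_prob`; uniform false
  localizations arrive at `background_rate` per frame per µm². The ground
  truth records the correct pair of every genuine localization, so pairing
  and fitting can be validated independently.
* **Rendering.** `render_frames()` draws localizations as pixel-integrated
  Gaussians with optional shot and read noise, closing the loop for
  localizer round-trip tests (grid of emitters in, same positions out
  within 1 nm noiselessly).

What the generator does *not* model: photobleaching kinetics and blinking
beyond a geometric on-time (SPT mode), depth-dependent detection through
the inclined light sheet (an optional hook exists but is off), dipole or
astigmatic PSFs, and pixel-dependent sCMOS noise. Passing tests therefore
demonstrate correctness of the *analysis* under the stated model, not
robustness to every instrumental pathology of real data.

## The projection bias, quantified

Only in-plane displacement components are observed. For a molecule
diffusing on a cylindrical membrane of radius R with the axis in the focal
plane, the axial step projects fully but the circumferential arc projects
as a chord compressed by cos φ. Averaging over the circumference, the
expected projected square step is

$$\langle r^2 \rangle = 2D\Delta t + R^2\!\left(1 - e^{-D\Delta t/R^2}\right)
 \approx 3D\Delta t \;(\text{small steps}),$$

so a single-component fit of projected membrane displacements
underestimates the true surface D by ~25% at R = 320 nm, D = 0.2 µm²/s,
Δt = 10 ms — the package's simulation reproduces this number, consistent
with the ~30% figure usually quoted for this geometry. `scripts/acceptance.R`
recomputes it from scratch at every run. Cytoplasmic D̂ in a real-sized cell
is likewise suppressed relative to the infinite-medium value by confinement
(about 15% at D = 5 µm²/s, Δt = 1.5 ms); this is physics, not an analysis
error, and the end-to-end pipeline tests therefore compare fitted values
against what the simulated ground-truth displacements actually contain.

## Numerical and testing choices

* All randomness flows from explicit seeds (`rng_seed` in the acquisition
  spec, `seed` in run configs); identical seeds give bitwise-identical
  localization tables and reports.
* Parameter-recovery tests draw from the fitted model itself through an
  independently coded rejection sampler, so the sampler and the likelihood
  cannot share a bug silently. Map-reconstruction tests use displacement
  sets with a known local D field (uniform starts, Rayleigh steps) so that
  per-pixel truth is exact; test sizes (6·10⁴ displacements per map,
  10⁴ per fit) keep every per-pixel estimate's sampling noise well inside
  the asserted bands while the whole suite runs in a few minutes.
* Degenerate inputs are contracts, not accidents: empty tables propagate to
  empty results, collinear point sets yield zero densities with a warning,
  starved drift segments degrade to the identity correction with a warning,
  and fits refuse to run below 50 displacements (200 pooled SPT steps).

## Limitations

D̂ is the apparent lateral coefficient: no correction is applied for
localization error (which inflates small D), projection or confinement
(which deflate it), consistent with the measurement convention above.
Two-component fits need a D contrast of roughly an order of magnitude for
reliable fraction recovery at 10⁴ displacements; closer components demand
far more data. Segmentation assumes cells are the only dense structures in
the field; dense extracellular debris would segment as (and be rejected
like) malformed cells.
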