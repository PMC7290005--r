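---
title: "Measuring TH+ morphology in cleared brains: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring TH+ morphology in cleared brains: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Light-sheet imaging of an iDISCO-cleared whole-mount brain yields a
single-channel intensity stack in which tyrosine-hydroxylase (TH)
immunolabel marks dopaminergic perikarya (substantia nigra, SN; ventral
tegmental area, VTA; the diencephalic A11–A14 groups), the fascicles of
the mesotelencephalic (MT) tract, and unwanted bright structures such as
blood vessels. `clearcount` turns such a stack into four kinds of
numbers: per-nucleus perikarya counts, a tract-abundance index
("pathway units"), tract-dispersal metrics, and group-level percent
changes with permutation p-values.

This vignette records the models behind each stage, the parameters that
matter, the conventions and tie-breaks that make every run exactly
reproducible, and what the validation on synthetic phantoms does and
does not establish.

## Conventions

* Arrays are ordered `(z, y, x)`, 1-based in R; voxel `i` on an axis
  with spacing `s` has its center at `(i − 0.5)·s` µm, and occupies the
  half-open interval `[(i−1)·s, i·s)`.
* All geometry — distances, extents, sphere radii, slab thickness — is
  computed in physical µm, never in voxel units; anisotropy is handled
  by this rule rather than by resampling, which avoids interpolation
  artifacts in the counting stage.
* A voxel belongs to a reference cuboid iff its center lies inside the
  half-open box. Nested crops therefore compose exactly.
* The rostrocaudal axis and its direction, the midline axis and plane
  are explicit metadata of every volume (defaults: rostrocaudal = `y`
  with rostral at low coordinate, midline on `x` at the volume center),
  matching a specimen mounted for horizontal-section scanning with a
  7 µm z-step.

## Segmentation

`segment()` thresholds the (optionally background-subtracted) volume
and labels connected components (26-connectivity by default), keeping
components whose voxel count lies in `[min_voxels, max_voxels]`.

* `threshold` — absolute intensity (the study configuration uses 550 on
  a 16-bit-like scale with a background offset of 200); alternatively a
  percentile of the nonzero voxels (default: 99th). No universal value
  exists: like any intensity-based pipeline this one is calibrated once
  per imaging configuration, here against phantom ground truth (see
  "Calibration" below).
* `min_voxels` — defaults to the voxel volume of a 7 µm sphere at the
  volume's spacing (≈ 1 voxel at 7 × 5 × 5 µm), removing speckle
  without touching small somata.
* `background_sigma_um` — scale of the Gaussian background estimate
  subtracted before thresholding (`max(v − smooth(v), 0)`); 0 (default)
  disables it. Phantom backgrounds are flat, so the study configuration
  leaves it off; real tissue autofluorescence gradients would want
  ~100–300 µm.

Per-component descriptors are computed in µm: centroid, volume,
mean/max intensity, and principal extents (ranges of voxel-center
projections onto the eigenvectors of the second-moment tensor, plus the
voxel footprint along each eigenvector, so single-voxel components have
spacing-scale extents). Elongation is the ratio of longest to shortest
principal extent.

**Vessel exclusion.** A component is discarded iff its longest
principal extent exceeds `max_extent_um` (default 100 µm) *and* its
elongation exceeds `max_elongation` (default 5); both inequalities are
strict, so a component exactly at a threshold survives. Perikarya
(~12 µm, elongation ≈ 1) and traversing vessels (hundreds of µm,
elongation ≫ 5) occupy disjoint shape regimes, which is what makes the
purge a pure filter: on phantoms it removes every generated vessel and
no somata. The exclusion is applied for cell counting only — fascicles
are themselves long and thin, so the tract analysis runs on the
unpurged mask.

## Measuring-sphere counting

The counting primitive places an array of fixed-diameter,
non-overlapping spheres into the mask inside a reference cuboid:

1. Candidate centers are the in-cuboid mask voxels, visited in order of
   decreasing underlying intensity, ties broken by lowest `(z, y, x)`
   tuple.
2. A sphere is accepted iff at least `fit_fraction` of its stencil
   voxels (voxels whose centers lie within `diameter/2` of the center;
   out-of-bounds stencil voxels count against the fraction) are
   uncovered mask voxels, and its center lies at least one diameter
   from every accepted center.
3. Accepted spheres mark their stencil voxels covered; the scan is a
   single pass, because coverage only grows and a rejected candidate
   can never become acceptable later.

The procedure is deterministic, order-stable, and equals a naive
exhaustive implementation voxel for voxel (tested on 50 random
fixtures). One accepted sphere is one counted perikaryon. SN cuboids
are tagged left/right and must not overlap; bilateral cuboids must
straddle the midline plane and are counted once.

**Parameter choice at a 7 µm z-step.** The generic defaults are a
12 µm sphere (the scale of a P7 dopaminergic soma) with
`fit_fraction = 0.5`. The study configuration uses **13 µm / 0.4**
instead, for a reason worth recording: at 7 × 5 × 5 µm spacing a
12–13 µm sphere stencil holds only five voxels in a single z-plane, and
a small soma lying between two z-planes rasterizes to as little as a
1 × 2 in-plane patch, which can never reach 50% of that stencil.
Lowering the fit to 0.4 admits those quantization-starved somata, while
the 13 µm non-overlap distance (greater than the in-plane mask width of
a blurred soma) keeps a single soma from spawning two spheres. This
pairing was calibrated once against phantom ground truth and then
frozen; with it, per-nucleus recovery over twenty phantoms of 30–60
non-touching somata stays within ±5% (worst observed ≈ 2.6%), with
vessel injection changing no count.

## Pathway units

The tract statistic intersects the segmented fascicle mask with a thin
slab:

* The slab lies orthogonal to the rostrocaudal axis at the rostral
  limit of the A11/A13 groups — located automatically as the
  most-rostral labeled voxel center inside the A11–13 reference cuboid
  (a manual coordinate override exists). Automation makes repeated runs
  of the same volume identical.
* Slab thickness must not exceed the measuring-sphere diameter;
  equality is allowed (the study uses 12 µm against a 13 µm sphere).
  The slab interval is `[limit, limit + thickness)` along the axis.
* Admission into the fascicle mask is by voxel intensity
  (`min_fascicle_intensity`, study value 1300): tightly bundled axons
  concentrate label and are brighter than dispersed single fibers, so
  the intensity cut is the primary fiber/fascicle discriminator, as in
  a predetermined-intensity gate. Windows are the 26-connected
  components of the admitted mask clipped to the slab.
* Each window must pass an in-plane diameter cut
  (`min_fascicle_diameter_um`, study value 8 µm), measured as the
  **area-equivalent diameter** `2·sqrt(area/π)` of the window's
  in-plane cross-section. An inscribed-disc metric was considered and
  rejected: at a 7 µm axial step the rasterized cross-section of an
  11–13 µm tube loses its corner cells, capping any inscribed disc near
  8 µm and rejecting genuine fascicles; the area-equivalent diameter is
  stable under that quantization while still separating 8 µm fibers
  from ≥ 11 µm fascicles.
* Units: the same greedy sphere packing runs inside each window; a
  nonempty window whose packing accepts no sphere still contributes
  exactly one unit (floor rule — "one or more spheres per window"
  resolved at the small end). The unit total is the abundance index.

On tract-only phantoms with well-separated fascicles no wider than the
sphere, units equal the fascicle count exactly (30/30 seeded runs). On
crowded tracts windows can merge or spawn extra spheres; the statistic
remains exactly reproducible and monotone in fascicle abundance, but it
is an index, not a neurite count.

**Defasciculation metrics.** `tract_width_um` is the 5th–95th
percentile range of window centroids along the mediolateral axis;
`bundled_fraction` is the fraction of admitted in-slab voxels belonging
to windows that pass the diameter cut. Width grows strictly with the
generator's lateral-scatter parameter, which is the phantom analogue of
tract widening by axon dispersal.

## Group statistics

Effects are reported as signed percent change on the control scale,
`100·(treated − control)/control`. Significance comes from a
permutation test stratified by day-of-preparation batch: group labels
are permuted only within batches, so batch-level intensity or handling
shifts cannot masquerade as treatment effects. When the admissible
relabeling count is ≤ 20,000 the null distribution is enumerated
exactly (p = fraction of relabelings, including the identity, with
|Δmean| at least the observed); otherwise 10,000 seeded Monte Carlo
draws are used with the add-one correction. A batch containing a single
group carries no within-batch information and is pooled, with a
warning. This assumption-free test was chosen over a linear model with
a day random effect deliberately: it needs no distributional
transformation, it is exactly checkable against brute-force
enumeration, and at n = 6 + 6 in three balanced batches its resolution
(minimum two-sided p = 2/216 ≈ 0.009) is adequate for the effect sizes
of interest. Endpoints are reported raw, without cross-structure
multiplicity correction.

Null calibration is assessed at the level the test operates on:
per-animal summary abundances drawn from the same variance model that
drives the phantom cohorts (lognormal per-animal variation, cv 8%;
lognormal batch effect, sd 5%; rounding to integer counts). Over 200
null simulations the fraction of p < 0.05 falls in the 2–4% range —
conservative, as expected for a discrete exhaustive null.

## The phantom generator

`generate_phantom()` produces volumes with complete ground truth. What
it emulates:

* **Geometry** — ellipsoidal nucleus envelopes (per-side SN, midline
  VTA and A11–13) filled with non-touching spherical somata by
  rejection sampling (capped at 10,000 draws, failing loudly);
  a ventral corridor of tubular fascicles whose centerlines are
  strictly monotone rostrocaudally (each crosses any coronal plane
  exactly once) with smooth lateral wander; dispersed thin fibers in
  the same corridor; straight bright vessels traversing the SN
  envelopes.
* **Optics** — separable anisotropic Gaussian blur specified in µm
  (study value σ = 5 axially, 3.5 laterally — the axial figure matches
  a 7 µm step, the lateral one the resolution of a low-magnification
  (≈ 1.25×) light-sheet objective at 5 µm pixels), normalized so total
  intensity is conserved.
* **Noise** — additive background offset, Gaussian read noise and
  optional Poisson photon noise, drawn from a generator seeded from the
  spec, so identical specs give bit-identical volumes.

Default intensities (somata 2000 ± 200, fascicles 2600, fibers 1000,
vessels 2000, background 200, read noise sd 30 on a 16-bit-like scale)
are free parameters of the simulation — no published intensity
statistics exist for this preparation — chosen once so that the
contrast ordering (fascicles > somata ≈ vessels > fibers > background)
and the signal-to-background ratio (~10:1) resemble a good immunostain,
and then frozen. Soma diameters are 12 ± 0.6 µm; objects much below
10 µm fall under the axial resolution floor of a 7 µm step and cannot
be counted reliably by *any* parameterization of this pipeline — a real
limitation of the imaging geometry that the generator's jitter keeps
visible but rare.

What the generator does **not** emulate: light scattering and
absorption gradients, stripe/shadow artifacts of sheet illumination,
autofluorescence texture, clearing-induced deformation, multi-channel
bleed-through, or biologically realistic axon branching (fibers are
unbranched tubes). Passing phantom validation therefore demonstrates
the correctness and calibration of the *measurement chain*, not
robustness to every real-world artifact; on real stacks the intensity
threshold and admission gates must be re-calibrated per batch, exactly
as the preliminary-experiment standards of a wet-lab protocol would be.

## The simulated replication study

`run_replication_study()` builds two cohorts of seeded phantoms
(default n = 6 per arm in three batches), scales the treated arm's
structure abundances by injected treated/control ratios, jitters
per-animal abundances with the variance model above, runs the full
pipeline on every volume, and compares the arms. Problem sizes were
chosen so a full study runs in ~10 s on one CPU: 50 × 144 × 88 voxel
volumes (350 × 720 × 440 µm at 7 × 5 × 5 µm), control abundances of 12
fascicles and 28/36/36 somata (SN-side/VTA/A11–13). With ratios 0.267
(fascicles), 1.831 (SN), 0.570 (VTA) and 0.617 (A11–13), estimated
percent changes land within ±10 points of the injected values with the
correct sign in ≥ 95% of master seeds, and the fascicle endpoint is
significant at the exhaustive-permutation floor. Residual spread is
dominated by the injected biological variance (a 6-animal mean of
lognormal abundances), not by measurement error — visible in that
ground-truth counts and measured counts track each other to ~2%.

## Known limitations

* Sub-10 µm objects are unreliable at a 7 µm z-step (above).
* Pathway units saturate on heavily overlapping tracts; between-group
  comparisons remain valid because both arms share the mapping.
* The area-equivalent diameter gate ignores cross-section shape; at
  these voxel sizes that is a feature, but at sub-voxel resolutions an
  inscribed-disc rule would discriminate better.
* Tube rasterization guarantees voxel hits only for diameters above
  the in-plane half-diagonal (≈ 8.6 µm at 5 µm pixels with 7 µm step):
  thinner structures can alias away, which mirrors real sampling.
* The permutation test conditions on batch sizes; with a single batch
  it degrades to an unstratified test.
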