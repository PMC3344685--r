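---
title: "Design-based stereology with phantom validation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology with phantom validation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostereo)
```

# The problem

Quantitative histology of a tubulo-glandular organ such as the rodent
ventral prostate asks for three-dimensional quantities — compartment
volumes, glandular tubule length, epithelial surface, stromal cell
numbers — from two-dimensional sections. Design-based stereology
answers with estimators that are unbiased by construction, provided the
sections are sampled by the right geometric design:

* **Volume density** `Vv` by the Delesse principle: the areal fraction
  of a compartment on a uniform random section equals its volume
  fraction. Absolute volumes follow as `V = Vv(%) * Vt / 100`, with the
  total organ volume `Vt` taken from fresh weight at unit specific
  gravity (1 mg corresponds to 1 mm^3).
* **Length density** of the glandular tubules from profile counts:
  `Lv = 2 * Q_A`, where `Q_A` is the number of tubule transections per
  unit sampled area, counted in an unbiased counting frame with
  forbidden lines. Total length is `L = Lv * Vt`.
* **Surface density** of the lumen-epithelium interface from cycloid
  test-line intercepts: `Sv = 2 * I / L_T`, with `I` intercepts over a
  test line of length `L_T` in the reference space.
* **Numerical density** of stromal mast cells and macrophages with the
  optical disector: particles whose counting point first comes into
  focus strictly below a look-up plane are counted in a probe of known
  volume (frame area times disector height), so `Nv = Q / (A * h)`.

`Lv` and `Sv` are only unbiased on isotropic uniform random (IUR)
sections. The bench protocol for cutting IUR sections is the orientator;
digitally we sample the plane normal uniformly on the hemisphere
(azimuth uniform, cosine of colatitude uniform) and the offset uniformly
over the block's support, which induces the same law and is exactly
testable.

Because the estimators are geometric, their correctness can be
established on synthetic tissue with analytically known truth. That is
the package's central design: a voxelized 3D phantom whose volume,
length, surface and particle densities are known exactly, a digital
microtome, the full estimator set, and a cohort simulator that
reproduces a six-group (three ages x control/treated) study of
carbamazepine exposure, including its statistics layer.

# The phantom

`build_phantom()` fills a rectangular block (default edge lengths set by
the spec, cubic voxels, voxel center = physical position, block =
half-open box) with three compartments: glandular lumen (label 1),
epithelium (2) and fibromuscular stroma (3).

**Tubules.** Real prostatic acini are long, branched, curved tubules
that essentially never end inside a tissue block. The phantom emulates
them with straight capped cylinders whose centerlines *wrap
periodically*: a centerline is a uniform random point plus a direction
drawn from the orientation law (isotropic by default), continued for the
requested length on the torus, so a tubule leaving one face re-enters
through the opposite face. The tube bodies are stamped from the periodic
images as well, which makes the construction exactly stationary:

* length density is uniform and satisfies `Lv = count * length / volume`
  identically;
* volume and surface densities are uniform in expectation, so no
  boundary depletion can bias spatially weighted sampling;
* no artificial gland end forms at a face — the re-entrant image's axis
  is the collinear continuation, and the nearest-centerline rule hands
  over seamlessly. Each tubule keeps exactly two true ends (epithelial
  caps, so tubules are closed), however long it is.

This construction was chosen over two alternatives that failed
validation: requiring whole straight centerlines inside the block
depletes tubule length near the faces (interior sampling then
overestimates `Lv` by tens of percent), and chopping the length budget
into many short rods produces a high density of end caps whose oblique
grazes inflate profile counts by roughly `pi * r_lu * (ends per length)`.
Long wrapped tubules keep the end density — the one geometric bias of
profile counting — as low as desired.

**Overlaps.** Where tubules overlap, a voxel takes the label implied by
the nearest centerline, which keeps the three compartments well defined
and the partition exact (`sum(Vv) = 1` to machine precision). At
gland-dense packing this overlap is substantial and is corrected for
when the cohort simulator derives radii from target volume fractions
(below).

**Ground truth.** `true_quantities()` computes `Vv` by exact voxel
counting, `Lv` from the summed generator centerline lengths, `Nv` as
particle count over stroma volume, and `Sv` by counting voxel faces
between lumen and epithelium. Face counting overestimates a smooth
surface by the direction-averaged factor `E(|nx| + |ny| + |nz|) = 3/2`;
the stored calibration factor 1.5 is re-measured on digital spheres by
`scripts/calibrate_surface_factor.R` and agrees with closed-form sphere
surfaces to well under 1% at the resolutions used.

**Particles.** `seed_particles()` places each class independently with a
Poisson total (mean = intensity times stroma volume) at positions
uniform over stroma voxels, jittered within the voxel, so every center
lies inside stroma.

**Ball suspensions.** `ball_phantom()` builds non-overlapping spheres
(lumen core, epithelial shell) — the canonical surface-calibration
object, since `sv / vv = 3 / r` holds exactly and spheres are immune to
orientation effects.

# Sectioning and sampling

`extract_section()` is the digital microtome: each pixel takes the label
of the voxel containing the pixel center's 3D position; particles within
half a section thickness of the plane are projected in with class and
depth. Planes that graze a block corner may contain no pixel center;
samplers redraw such planes (their tissue area is ~0, so area-weighted
pooling is unaffected). The in-plane "vertical" axis for cycloid
orientation is the normalized projection of the global z-axis (x-axis
when degenerate) — any fixed convention is valid under IUR sampling, and
a fixed one is reproducible.

`systematic_fields()` implements systematic uniform random field
sampling: a square grid with one uniform random start, tissue-free tiles
discarded, and a systematic subsample (constant stride, random phase) of
the remaining tiles, so the default 22 fields spread over the whole
section instead of clustering at one edge. The returned attributes
`n_available`/`n_taken` carry the inverse inclusion probability: when a
fixed field count is taken from sections of different sizes, small
(corner) sections are oversampled, and pooled pixel sums must be
weighted by `n_available / n_taken` (Horvitz-Thompson) for every tissue
pixel to carry equal weight. With that weighting the pooled Delesse
estimate is unbiased against the phantom's exact voxel truth (validated
to within 3 Monte-Carlo standard errors over 500 replicate runs).

# Numerical conventions

Several discretization conventions matter and are fixed package-wide:

* **Profile recognition.** A glandular tubule profile is recognized by
  its lumen: one 8-connected lumen component with its epithelial ring is
  one transection. Counting lumen components is what keeps the rule
  valid in gland-dense tissue, where neighboring epithelium fuses into a
  single connected mass, and it rejects lumen-free epithelial shavings
  (end-cap grazes, tangential cuts, digitization fragments), which
  otherwise inflate counts by tens of percent. In sparse tissue a
  recognition threshold of half the minimal transversal lumen area
  (`0.5 * pi * r_lu^2`) removes sub-pixel fragments; in gland-dense
  simulated tissue, where neighboring glands erode lumen patches, the
  pipeline uses a lenient 4-pixel speckle floor instead.
* **Forbidden-line rule, discretized.** A profile is counted in a frame
  when it has a pixel inside the frame and none on the forbidden set:
  the pixel column left of the frame with its upward extension, the
  row below the frame, and the downward extension at the right edge.
  This counts every profile exactly once under a contiguous tiling
  (verified exhaustively against an independent component-labeling
  oracle). `Q_A` is measured with a complete tiling of frames over the
  section and the delineated tissue area within the frames as
  denominator; restricting to frames wholly inside tissue loses long
  grazing-stripe profiles whose owner frame is skipped and was measured
  to bias `Lv` by -8%.
* **Cycloid intercepts.** Arcs are resampled at equal arc-length steps
  of 3/4 pixel and label runs shorter than one pixel of arc length are
  discarded before transitions are counted (crossing-parity rule). A
  digitized boundary is a staircase; raw transition counting at finer
  steps picks up spurious crossing pairs where the test line grazes the
  staircase (+5% on spheres), while aggressive run filtering discards
  genuine grazing chords (-7% at two pixels). The 3/4-pixel/1-pixel
  convention was calibrated once against closed-form sphere surfaces
  (`scripts/calibrate_surface_factor.R`) and reproduces them to within
  1% across ball radii and voxel sizes.
* **Disector rule.** The counting point of a (point) particle is scored
  when its height above the reference plane lies in `[0, h)` — look-up
  plane exclusive, reference plane inclusive — and its position falls in
  the half-open frame (inclusion right/upper). Stacked probes therefore
  count every particle exactly once (verified as exact integer equality
  under a full tiling). The look-up plane is a focal plane and may lie
  beyond the block surface. `Nv` uses the reference section's stroma
  area inside the frame times `h` as the sampled volume.
* **Surface oracle factor 1.5** as above.

# The simulated cohort

`study_config()` encodes the study design: six groups (C43, C63, C93,
CBZ43, CBZ63, CBZ93 — three control and three carbamazepine-treated
groups named for age in days), five animals each. Generative parameters
come from the embedded reference summaries (`reference_tables()`):
per-group prostate weight mean and SD, tubule length density, and the
93-day volume-density triples. Choices where the reference study is
silent, stated once and not revisited:

* Volume densities for the 43- and 63-day ages were not published ("data
  not shown", no significant alterations reported); they reuse the
  93-day control triple.
* Stromal cell intensities (per mm^3 of stroma) are synthetic round
  numbers chosen to give usable Poisson counting statistics and to
  mirror the reported directions — mast cells raised in the treated
  pubertal and adult groups (150/180/150/300/200/350), macrophages
  raised at puberty and depressed in the treated adults
  (100/120/100/220/200/90). The published figures report these densities
  only graphically, so no printed values exist to match.
* Nuclear transmittance is 0.35 everywhere except the treated adult
  group (0.70): those nuclei transmit twice the light, mirroring the
  reported weaker androgen-receptor staining. The densitometry model is
  standard Beer-Lambert with a white reference, `OD = log10(I0 / I)`
  capped at 3; synthetic nuclei are ellipses with Gaussian absorbance
  profiles on a bright single-channel background (chromogen color
  deconvolution is out of scope).
* Hormone levels enter as annotation columns only (they are measured by
  immunoassay in the reference study, outside computational scope).
* Body weights are derived from the printed absolute and relative weight
  columns (`relative weight = mg per 100 g body weight`).

Each animal gets a phantom block (0.8 mm edge, 8 um voxels — a sampled
tissue fragment, not the whole organ). Tubule radii are solved from the
animal's drawn targets with an overlap correction: for Poisson tubule
axes the nearest-axis distance satisfies
`P(D <= d) = 1 - exp(-Lv pi d^2)`, inverted at the lumen and outer
radii. Tubule count and length are set so `count * length / volume`
equals the drawn `Lv` exactly. Two caveats are documented rather than
hidden: with a handful of tubules per block the realized volume
fractions scatter around their targets (the finite realization is
lumpy — comparable in magnitude to the published between-animal SDs),
and at prostate-like packing (~82% gland) the total coverage is capped
at 85% with a radius cap so stroma never vanishes; the per-animal
estimates always measure the realized phantom, whose exact truth is
recorded.

`run_study()` walks the full protocol per animal — IUR sections,
22 systematic fields for the Delesse estimate, a complete counting-frame
tiling for `Q_A`, cycloid grids for `Sv`, dedicated IUR disector stacks
for `Nv`, rendered nuclei for the IOD arm — assembles per-animal
estimate records whose derived fields reproduce exactly from their raw
counts, and runs the statistics layer. Sections that sample no tissue
for a probe are extended (up to four times the planned number), as at
the bench. Reports print "mean ± SD" to two decimals, n = 5, mirroring
the reference tables.

# The statistics layer

The tests the reference study names are implemented from first
principles so they are oracle-testable, with base R's implementations
serving as independent cross-checks in the test suite:

* **Balanced two-way ANOVA** (treatment x age) from cell and marginal
  means; the decomposition `SS_total = SS_A + SS_B + SS_AB + SS_err`
  holds identically (asserted to 1e-9) and F/p values match `aov` to
  1e-9. Unbalanced designs are rejected — the study design is balanced
  and the orthogonal decomposition would not apply.
* **Pooled-variance Student t**, two-sided; zero pooled variance with
  equal means returns t = 0, p = 1, with unequal means it is a
  degenerate input and errors.
* **Mann-Whitney U** with midranks; exact two-sided p by complete
  enumeration of rank assignments when `n_a + n_b <= 12` without ties
  (using the symmetry of the null U distribution), otherwise the
  tie-corrected normal approximation with continuity correction. The
  exact mode agrees with `wilcox.test` on every untied 3-vs-3 input.
* **Group summaries** use the sample SD (n - 1; animals are sampled
  units); singleton groups are reported as SD 0 with a degenerate flag.
* Significance is declared at p <= 0.05 throughout; no multiple-testing
  correction is applied, faithful to the reference analysis.
* The animal is the statistical unit everywhere (one pooled estimate per
  animal, ratio of sums across its fields); the reference study is not
  fully explicit for the cell-count endpoints, and this choice is logged
  in every report.

# Problem sizes and what validation does (and does not) show

The validation suite establishes, on phantoms: Delesse unbiasedness
(500 replicate runs of 5 sections x 22 fields, grand estimate within 3
Monte-Carlo SE of exact truth per compartment); `Lv = 2 Q_A` recovery
within 5% (pooled over thin-tubule phantom realizations — three of 150
sections each in the test suite, eight of 80 sections in the reproduction
script — because the orientation coupling a finite set of tubule
directions induces scatters per-realization errors by ±2-3% and
realization averaging dominates the error budget); cycloid `Sv` within 5% on sphere
suspensions plus the `sv/vv = 3/r` identity; exact disector conservation
and pooled `Nv` within 3 SE of the seeded intensity; the statistics
oracles at scale (10^4 null simulations hold the t test's level at
5% ± 1%); IOD scale equivariance, monotonicity and group ordering in
100/100 seeded replicates; and >= 80% detection power for the adult
weight decrease over 200 simulated studies. These sizes keep the whole
suite within a few minutes on one core while leaving the Monte-Carlo
margins comfortably inside the tolerances.

What passing these tests does *not* show: the phantom has no staining
artifacts, deformation, shrinkage or lost caps; tubules are unbranched
and of a single radius per animal; particles are points, not extended
cells; nuclei images are single-channel with idealized backgrounds; and
at gland-dense packing the overlap construction is an approximation of
real space-filling acini, so the simulated `Lv` and `Vv` tables
reproduce the reference study's values only approximately (directions
and orders of magnitude, not cell-by-cell equality). The estimator
layer, by contrast, is validated exactly in the sense stated above.

# Known limitations

* Finite-tubule phantoms couple the realized orientation set to any
  fixed test-line convention: per-realization `Lv`/`Sv` deviations of
  ±2-3% are expected and average out over realizations.
* The Poisson-line overlap inversion degrades when a block holds very
  few, very fat tubules; the simulator caps coverage and radius and
  records the realized truth per animal.
* The forbidden-line frame undercounts objects comparable in size to the
  frame when the tiling is partial; the package therefore always tiles
  completely.
* IOD is a semi-quantitative readout: the package fixes a white
  reference (background subtraction is configurable at the calibration
  argument) and makes no claim of chromogen stoichiometry.
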