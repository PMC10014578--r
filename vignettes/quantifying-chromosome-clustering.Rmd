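---
title: "Quantifying chromosome clustering in oocytes: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosome clustering in oocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ooclust)
```

## The measurement problem

In the germinal vesicle (GV) of a large mammalian oocyte, chromosomes are
dispersed through a nucleus tens of micrometres wide. After nuclear
envelope breakdown (NEBD) they converge centripetally into a single
compact cluster, moved first by an inward-migrating network of actin
cables and later by microtubules, before the spindle assembles.
`ooclust` provides the quantitative read-outs of that process: how fast
the chromosomes converge, when NEBD happened, how directional the actin
flow is, how often kinetochores contact actin, and how fragment size and
kinetochore content affect clustering. This vignette explains each model,
its assumptions and tunable parameters, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
design was open.

## Clustering kinetics

The central statistic is the **largest pairwise distance** L(t): the
maximum Euclidean distance over all pairs of points of the segmented
chromatin at a time point. By default the point set is the *surface
voxels* of every labelled focus (the analogue of isosurface vertices); a
centroid-based fallback (`mode = "centroid"`) exists for coarse data and
is flagged by an attribute on the kinetics table. L(t) is insensitive to
how many foci the segmentation finds as long as the extreme chromatin is
captured, which is what makes it robust for speed estimation: merging or
splitting of interior foci leaves the extremes untouched.

**Clustering speed** over a window [a, b) minutes from NEBD is the mean
of −ΔL/Δt over consecutive frame pairs whose midpoints fall in the
window; decreasing distance is reported as a positive speed. Whether the
field's "average speed" is a per-frame mean or a regression slope is a
genuine ambiguity; both agree exactly for linear decay, the per-frame
mean is the default, and `method = "slope"` provides the alternative.
Reporting windows follow the biology: 0–30 min post-NEBD (the
actin-driven phase) and 30–50 min (the microtubule-driven phase). Windows
are half-open [start, end).

The **convex hull volume** of all chromatin points tracks cluster
compaction. The 3D hull is computed by an incremental algorithm written
for this package (no qhull binding is among the dependencies); the test
suite checks it against an independent brute-force facet-enumeration
oracle and against closed forms (unit tetrahedron 1/6; cube side 2 µm,
8 µm³). Point sets with fewer than four points in general position get
volume 0 with a `degenerate` flag.

**Time to complete clustering** is the time from NEBD to the first frame
with exactly one chromatin focus. If the count later rises again the
first qualifying frame is still reported, flagged `non_monotone`; a
series that never reaches one focus is `not_clustered`. **Fragment
classes** cross a strict 30 µm³ size gate (volumes below 30 are "small",
30 and above "large") with kinetochore presence. The threshold is applied
to measured volumes, as it is in practice.

## Segmentation

Chromatin foci: optional Gaussian pre-smoothing (defaults 1 voxel in
x/y, 0.5 in z; the field's pipelines rarely state theirs, so these are
exposed), a global Otsu threshold on the full intensity distribution,
26-connected component labelling (8-connectivity in 2D), a minimum-volume
gate (default 0.5 µm³) against shot-noise specks, and intensity-weighted
centroids in µm. Label maps conserve voxels (the per-object volumes sum
to the foreground count times the voxel volume) and are calibration-
equivariant: scaling the voxel size by s scales volumes by s³ and
centroids by s.

Surfaces (actin, membrane): the same threshold-and-label pipeline with an
inclusive volume gate at both bounds; the actin-surface default gate is
30–1000 µm³. Spots (kinetochores, Formin-2): band-pass
difference-of-Gaussians filtering and strict 26-neighbourhood local
maxima, with scan-order tie-breaking so a peak centred between voxels is
counted once. With a `target_count` the brightest that-many maxima are
returned (the practice of creating ~100 spots per cell for
comparability); an underfull set is returned whole with a flag.

A focus `has_kinetochore` when any spot lies within its label region
dilated by one voxel. The corresponding manual classification in practice
is by eye on the CENP-C signal; one voxel of tolerance absorbs the
sub-voxel offset between a spot centre and the label boundary.

Nuclear lamina: the 2D lamina frame is contrast-enhanced (coarse
background subtraction, normalisation by a coarse local amplitude with a
global floor so flat noise is not amplified), edges are taken from the
Otsu-thresholded gradient magnitude, edge pixels are transferred to polar
coordinates about their centre of mass, radial outliers are removed
(more than 3 MAD from the running median within a ±10° window — the
outlier rule itself is a package choice, as the upstream descriptions say
only that outliers were removed), and a cyclic smoothing spline ρ(θ)
(mgcv, `bs = "cc"`, smoothness by GCV) closes the contour, which is then
expanded outward by a margin (1.5 µm default, 2.5 µm variant). Fewer
edge pixels than a periodic fit needs is reported as "lamina not found".

## NEBD detection

A 40 kDa fluorescent dextran is excluded from the intact GV and floods
the nuclear region at NEBD. Detection mimics an acquisition-switching
trigger: per frame, the chromosome centre of mass is recomputed from the
chromatin channel above its Otsu threshold; the mean dextran intensity
inside a 10 µm-diameter probe sphere at that centre is recorded; and the
frame triggers when that mean exceeds `median + k·sd` of all previous
measurements (sample sd; a rolling-window option exists). The stringency
k and the minimum history length are not prescribed anywhere upstream;
the defaults k = 5 and `min_history` = 4 keep the false-trigger rate on
stationary noise at the few-percent level while detecting any influx an
order of magnitude above the read noise at the influx frame or one frame
later. Note the threshold's own floor: an influx of exactly k·sd is
missed about half the time by construction, so the validated regime in
the tests uses a 20·sd influx — small against a real dextran signal,
which in the rendered series is ~60 times the read noise. No trigger
within a series is a valid no-event result, not an error.

## Actin-flow directionality

High-temporal-resolution 2D actin imaging after NEBD is stabilized by a
per-frame translation against the first frame, estimated by Hann-windowed
FFT cross-correlation on the lamina channel with three-point subpixel
interpolation, and applied to all channels by bilinear resampling.

PIV is a three-pass window-refined cross-correlation: interrogation
windows of 64, 32 and 24 px at 50 % overlap, each pass offsetting its
windows by the nearest vector of the previous pass (window offsetting is
first-order window deformation; full image deformation is out of scope at
this problem size). Pre-processing is an adaptive local noise filter and
a low-pass, both of 5 px support. Each window pair is mean-subtracted,
Hann-tapered (suppressing the circular wrap-around bias that otherwise
displaces the correlation peak on smooth textures), correlated by FFT,
peak-searched within ±w/3, and refined by a three-point Gaussian fit
(parabolic fallback for non-positive neighbours). Post-filtering is
deliberately weak, matching practice: a vector is invalidated only when
the first-to-second correlation peak ratio falls below 1.05 (the floor is
a package choice; "weak filtering" is not quantified upstream).

Direction classification: for each valid vector inside the expanded
lamina contour with speed ≥ 1.8 µm/min (the px/frame equivalent depends
on calibration and is computed, never assumed), the signed angle between
the vector and the unit vector toward the nuclear centre is binned into
**inward [−60°, 60°), sideways [60°, 120°), outward [120°, 240°),
sideways [240°, 300°)**. The published category description (four
categories of 120° each) cannot tile 360°; this package tiles the circle
with a 120° inward sector, a 120° outward sector and two 60° sideways
sectors, which preserves the inward/outward symmetry that the biological
claim (inward excess) rests on. Circular statistics use the resultant
vector: mean direction, mean resultant length, and a 95 % CI from the
circular-dispersion approximation, falling back to a seeded bootstrap
when the approximation's validity condition (adequate resultant length
and sample size) fails. An isotropic field occupies the inward sector at
its width share (1/3); an inward-motion fraction p yields an expected
inward-vector fraction p + (1 − p)/3.

## Colocalization

Spot-to-surface distances are exact nearest-surface-voxel distances in
calibrated µm space (zero inside the surface), computed against the
boundary voxels of the mask; the unit tests pin them to an exhaustive
min-over-all-voxels search within half a voxel diagonal. The
**interaction fraction** is the share of spots within a cutoff; the
default cutoff 0.25 µm is approximately the lateral resolution of the
high-resolution imaging regime and is a package choice (the upstream
classification was visual), echoed in all outputs. The **mirrored
control** reflects spot x-coordinates about the volume's x mid-plane:
mirroring twice restores the input exactly, and mirroring spots and
surface together leaves every statistic unchanged. **Expected random
overlap** of two independent interaction types is the product of their
fractions. ROI crops (default 10 µm cube) are placed either explicitly
or automatically at the grid position farthest from both the nucleus mask
and the volume border; local actin intensity is a background-subtracted
ROI mean, clamped at zero with a flag.

## The synthetic-data generator

The generator's defaults are the study conditions, not tuning knobs: a
12.5 µm-radius GV nucleus in a 60 µm-radius oocyte, 12 chromatin bodies
of 1.5 µm radius, NEBD at 30 min (enough pre-NEBD baseline for the
adaptive trigger), convergence at 0.43 µm/min, 5-min frames at
0.5 × 0.5 × 3 µm voxels (the live regime; 0.19 µm isotropic is the
fixed/high-resolution regime), inward-flow fraction 0.7, and
Poisson-plus-Gaussian camera noise quantized to integer counts.

Chromatin bodies are rendered as **solid spheres with a
diffraction-blurred edge**: flat amplitude inside a core, Gaussian
fall-off (σ = 0.3 µm) outside, with the half-maximum isosurface exactly
at the nominal radius, so thresholding near half-max recovers
(4/3)πr³ — the property the volume tests rely on. A pure Gaussian
profile was rejected because its long skirt makes threshold-derived
volumes strongly histogram-dependent, which is neither realistic for
filled chromatin bodies nor checkable. Overlapping bodies combine by
maximum, not sum — chromosomes are mutually exclusive bodies, and
summing would brighten the forming cluster and drag the global threshold
upward over time, biasing apparent sizes. Kinetochores are additive
point sources. Initial positions keep centres at least 3.5 radii apart
(dispersed GV chromatins are individually resolvable); two bodies are
anchored antipodally at 0.85 of the nuclear radius so the initial
largest pairwise distance is reproducible across seeds and leaves the
linear-decay regime room before the cluster floor.

Post-NEBD motion contracts all positions about their centroid with the
scale factor chosen so that the true largest pairwise distance decreases
*linearly* at the programmed rate, stopping at the floor where all
pairwise distances reach twice the chromosome radius (a formed cluster).
This makes the truth slope exactly the programmed speed, which is what
parameter-recovery is measured against. Dextran is zero in the nucleus
before NEBD, at 60 % of cytoplasmic level on the NEBD frame and at full
level from the next frame; the lamina shell persists and compacts mildly
after NEBD.

Flow frames move a population of Gaussian cable particles inside a
lamina disc: per frame pair, with probability `actin_inward_fraction`
every particle steps toward the disc centre (particles reaching the
centre re-appear at the periphery, like cables nucleating there), and
otherwise the population translates rigidly in a uniform random
direction. Truth records the imposed displacement per sampling region
per pair. Cable density and width are free parameters (600 particles of
2 px σ by default); nothing upstream prescribes them. An imposed fixed
translation (`flow_translation`) turns the generator into a displacement
oracle.

The fragmentation generator renders prescribed volumes and kinetochore
flags, with kinetochore-free fragments under 30 µm³ converging at
`slow_factor` (default 0.3) of the full rate. The kinetochore–actin
volume renders a few actin cables (beads along random axes, ~1 µm
radius, within the 30–1000 µm³ surface gate after thresholding) and 40
kinetochore spots of which a stratified count — marginal per-spot
probability exactly equal to the programmed 18 % — sit on a cable axis
(distance 0) while the rest stay at least 1.5 µm clear; stratification
minimises across-cell variance in the recovered mean without changing
any spot's marginal contact probability, and a 1.5 µm minimum spot
separation keeps all 40 spots individually detectable.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: photobleaching and phototoxicity;
non-rigid cell and nucleus drift (stabilization is validated on pure
translations); chromatin that is nucleolus-associated (the optional
exclusion mask in the kinetics API exists for exactly that case on real
data, where no automatic rule is defensible); anisotropic and depth-
dependent point-spread functions; and 3D flow truth (flow ground truth
is 2D, as is the PIV).

## Numerical choices and degenerate inputs

Distances, centroids and volumes are computed in µm with voxel-centre
coordinates ((i − 0.5)·voxel); anisotropic voxels are handled by working
in calibrated space throughout. Frames are 1-based at the R level and
0-based in CSV outputs; times in minutes from NEBD. Zero or one focus
gives L = 0; an all-zero volume segments to an empty focus set (not an
error); a probe sphere smaller than one voxel degenerates to its
containing voxel; an empty surface or spot set in a distance computation
is an error. The hull's visibility tolerance scales with the cube of the
point-cloud extent. Ties in the largest-pairwise-distance pair are broken
by scan order (the value, not the pair, is the statistic). Problem sizes
in the validation suite — 20 synthetic oocytes per recovery experiment,
10 frames each, 64×64×10 live-regime volumes, 96×96×48 high-resolution
volumes, 192 px flow frames — were chosen so the full suite represents
each claim at the scale a workstation handles comfortably.

## Known limitations

The incremental hull is quadratic in the worst case and intended for the
point counts segmentation produces (hundreds to a few thousand); the
largest-pairwise-distance path reduces larger clouds to hull vertices
first. PIV window offsetting (rather than full deformation) limits
accuracy under strong shear within a window; the rotation-field test
quantifies this (window-integrated estimates against point values). The
Otsu threshold is global per volume; strongly non-stationary backgrounds
would need the pre-smoothing and gates adjusted. The NEBD trigger's
detection floor is set by k·sd, as discussed above. The mirrored control
assumes the structural channel is not itself mirror-symmetric about the
x mid-plane.
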