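---
title: "Context-aware template matching for crowded tomograms: models and design"
author: "catmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware template matching for crowded tomograms: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(catmtools)
```

## The problem

Nucleosomes inside chromatin condensates are flattened discs, roughly
11 nm across and 5.5 nm high, packed densely enough that their densities
overlap in a cryo-electron tomogram.  Two imaging artifacts make their
identification ambiguous: the *missing wedge* (the stage only tilts to
about ±60°, so a wedge of Fourier space is never sampled and every
particle is smeared along the beam axis z) and *contrast transfer
function* (CTF) modulation.  Exhaustive template matching treats every
voxel independently and resolves conflicts with a single
centre-to-centre distance cutoff; in a crowded field this merges,
duplicates, or misorients particles, and biases the apparent orientation
distribution.

Context-aware template matching (CATM) splits the task: an upstream
localization step supplies approximate particle centroids, local
template matching around each centroid retains a *list* of candidate
poses rather than a single best, and particles are mapped back into the
volume in descending order of their best cross-correlation coefficient
(CCC), resolving steric clashes first from a particle's own
alternatives, then by joint pairwise optimization with its nearest
placed neighbour; when no sterically compatible combination exists only
the stronger particle survives.

## Forward model of the simulator

`generate_benchmark()` composes the degradation chain

1. `sample_particle_configuration()` — positions uniform in the box,
   orientations uniform on SO(3), rejection sampling against voxelized
   steric-mask overlap (the ground truth is clash-free by construction);
2. `render_volume()` — sum of rotated, translated templates (trilinear
   resampling, linear in amplitude);
3. `apply_ctf()` — radially symmetric phase-contrast transfer function
   `-(sqrt(1-A^2) sin chi + A cos chi)`,
   `chi = pi lambda df k^2 - (pi/2) Cs lambda^3 k^4`
   (300 kV, Cs 2.7 mm, 4 µm underfocus, amplitude contrast 0.07 by
   default); the value at k = 0 is `-A`, so low-frequency contrast is
   inverted;
4. `add_noise()` — white Gaussian noise with variance `var(signal)/snr`;
5. `apply_missing_wedge()` — Fourier coefficients whose (kx, kz)
   direction lies outside the ±60° tilt fan are zeroed (tilt axis y).
   The wedge acts *after* the noise, as in a reconstruction from a
   limited tilt fan, so the noise field carries the same anisotropy as
   the signal.

The templates are parametric: a soft-edged cylinder (1-voxel cosine
taper centred on the nominal boundary, so the half-maximum isosurface
recovers the stated dimensions) for the nucleosome, and a 2 nm rod for
free DNA.  A Gaussian-per-atom rasterizer (`rasterize_atoms()`) is
available for structure-derived templates but nothing in the package
requires one.  What the simulator deliberately omits: internal
nucleosome structure (DNA gyres), linker DNA connecting nucleosomes into
arrays, conformational variability, detector and dose effects, and
reconstruction artifacts beyond the ideal wedge.  Passing benchmarks
here therefore demonstrates the correctness and the relative merits of
the assignment algorithms under a controlled forward model, not
performance on real micrographs.

## Matching

All scoring uses masked, locally normalized cross-correlation: the
template is rotated, degraded with the *same* wedge and CTF as the data
(matched filtering against the forward model — with the CTF's inverted
low-frequency contrast, correlating an unfiltered template against
CTF-modulated data would anti-correlate), restricted to its rotated
steric mask, standardized to zero mean and unit variance under that
mask, and correlated with the data; the local mean and variance under
the mask normalize every voxel's score into [−1, 1].  Zero-variance
neighbourhoods score 0.  The FFT engine packs two real volumes per
complex transform and splits the Hermitian halves in compiled code, so a
full-volume score map costs three FFTs per orientation.

Orientation grids exploit the disc's symmetry: the parametric cylinder
is symmetric in-plane and top-bottom, so a grid samples only disc-normal
directions on the hemisphere (antipodal directions identified), with a
Fibonacci layout sized so that no direction is farther than the angular
step from a grid point; `mode = "so3"` adds in-plane sampling for
asymmetric templates.  The default step is 15°.

Baseline TM (`tm_search()`): each voxel retains its best orientation,
local maxima above a floor (0.1) become candidates, and greedy
non-maximum suppression removes candidates within 4 nm of a
better-scoring one — slightly less than the disc height, the same rule
the condensate literature uses.  A CCC threshold sweep
(`ccc_threshold_sweep()`) then reports precision/recall/F1 per cutoff.

CATM (`run_catm()`): the tomogram is Gaussian low-passed to ~2 nm, the
candidate list for each seed centroid holds the per-orientation best
position within a 5 nm search radius with CCC at or above 0.3, and
`greedy_place()` maps particles back under the steric-clash rule
(overlap of more than 5% of the smaller rotated mask counts as a clash;
the published procedure gives no numeric tolerance, so this is a
package choice, configurable).  Ties in CCC are broken by particle id
for determinism.  Clash resolution is strictly two-body, matching the
published procedure; multibody optimization is out of scope.

`merge_assignments()` reconciles a CATM set with an externally refined
set: refined particles whose positions collapsed onto an earlier
particle within 2 nm are dropped (a known refinement artifact when
nearby particles are processed independently), then CATM particles
without a refined counterpart within 5.5 nm are restored if they create
no clash.

## Evaluation

`match_particles()` computes an optimal one-to-one assignment
(maximum-cardinality, minimum total distance, via maximum-weight
bipartite matching with a cardinality-dominant offset) between
predictions and ground truth within a 5.5 nm distance tolerance — half
the disc diameter — and, for the "position + orientation" scores, a 30°
tolerance on the antipodal-reduced disc-normal angle.  The reference
procedure does not print its tolerances; both are configuration values
and are reported alongside every F1.  The orientation diagnostic
compares the angle between disc normals and the beam axis to the
sin(θ) density of uniformly random orientations (CDF 1 − cos θ) with a
Kolmogorov–Smirnov test.

## Benchmark conditions

The shipped benchmark simulates three cubic tomograms of 96 nm
(96³ voxels at 1 nm/voxel) holding 75 nucleosomes and 38 free-DNA rods
each — the same number density as 600 particles in a 192³ volume, the
upper end of the condensate-mimicking density range — imaged at ±60°
tilt with the default CTF and SNR 0.05.  The SNR was calibrated once
against the matching operating point: the CCC of the true pose at the
true position spans roughly 0.35–0.45, bracketing the 0.3 candidate
retention threshold, and the resulting F1 scores sit at the values the
method is known to achieve (TM maximum F1 near 0.78–0.85 depending on
density; CATM near 0.98 for positions and 0.97 with orientations).
These problem sizes keep a full benchmark run at roughly 80 s per
tomogram on one CPU.  CATM is seeded with ground-truth centroids
jittered by 1.5 nm Gaussian noise, emulating the high-recall learned
segmentation used upstream in the reference pipeline; the classical
matched-filter localizer is provided (`matched_filter_localize()`) and
is exercised separately.

## Numerical choices and degenerate inputs

* Template standardization uses the population SD so the squared
  template sums to the mask size; the FFT score then equals the
  brute-force masked Pearson correlation to 8 decimals (tested).
* The zero-variance guard compares the local SD against 10⁻⁶ of the
  global SD; constant volumes score 0 everywhere.
* Steric tests use the half-sample convention: a voxel belongs to a
  particle if its centre lies inside the rotated mask.  Two discs
  touching edge-to-edge at exactly one diameter share no voxel.
* The wedge keeps the DC column and treats (kx, kz) and −(kx, kz) as
  the same sampled line; a ±90° range is the identity.
* MeanShift rejects saddle points (where seeds on a symmetry plane
  converge) by probing the kernel density one bandwidth away in six
  axis directions; a true mode dominates all probes.
* The matched filter thresholds its pooled orientation-max map at
  `median + 5 MAD`, floored at 0.25: on pure noise this admits
  essentially nothing, at the benchmark SNR it recovers roughly 80% of
  particles.  At that SNR the pooled score of the weakest true
  particles overlaps the null maxima, so no threshold reaches 95%
  recall with a silent null — the reason the benchmark seeds CATM from
  jittered centroids rather than from this detector.

## Spatial analysis of condensates

The interface of a droplet is fitted as a sphere (`fit_sphere()`:
algebraic fit, then Gauss–Newton on the geometric residuals) from
perimeter annotations; signed distance is positive inside.  A plane
variant covers flat interfaces such as the air–water interface of
blotted samples.  Contact graphs connect particles whose steric-mask
surfaces approach within 1 nm (default; a 12 nm centre-distance
criterion is the recorded alternative) — a shape-aware rule, in keeping
with the steric emphasis of the assignment step.  Heterogeneity is
summarized by the normalized Shannon entropy of the valence (degree)
distribution, with the category count K spanning the contiguous support
0..max observed valence (configurable to observed-only); entropy is
base-invariant after normalization.  Attribute assortativity uses the
standard categorical coefficient.  DBSCAN (eps 12 nm, minPts 3 by
default) labels clusters with an explicit noise class, and
`cluster_fraction_vs_depth()` profiles cluster membership against depth
from the interface, flagging bins with fewer than five particles rather
than reporting unstable ratios.

`generate_condensate()` plants known structure — face-to-face stacks of
a chosen size deep in the droplet (interior valence 2, stack ends 1) and
isolated nucleosomes near the interface (valence 0), groups separated
far enough that no accidental contacts arise — so the entire analysis
stack can be validated by parameter recovery: the entropy of the
planted valence distribution, the planted cluster-size mode, and the
cluster-poor interface shell.  The published statistics measured on
real condensate and nuclear tomograms (valence entropy near 0.74–0.77,
assortativity near 0.03, cluster-size peak at 4) require the deposited
experimental data and are not reproduced here; the planted-structure
checks show the estimators recover known values of the same statistics.

## Known limitations

* The benchmark volume and particle count are a desk-scale version of
  the published simulation; F1 values carry correspondingly more
  sampling noise (about ±0.02 across seeds).
* The baseline TM reproduces the face-on undercounting caused by the
  missing wedge, but its compensating excess appears at intermediate
  angles rather than at the side-on extreme; with the smooth parametric
  disc the face-on template retains more in-mask power after
  degradation than the side-on one, which thins weak side-on detections
  at the F1-optimal threshold.  A structured (atomic-model) template
  and denser crowding are the likely missing ingredients.
* Orientations are reported on the search grid; no continuous angular
  refinement is performed (the reference pipeline delegates that to
  subtomogram refinement, which is out of scope here).
* Two-body clash resolution can in principle be beaten by a global
  optimizer on pathological candidate sets; on generated 2–4 particle
  micro-instances it attains the enumeration optimum in every shipped
  case (tested).
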