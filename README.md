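# catmtools

Identify the positions and orientations of nucleosome-like particles in
crowded cryo-electron tomograms, and quantify how they organize inside
biomolecular condensates.

Nucleosomes are flattened discs (~11 nm diameter, ~5.5 nm height) that
pack densely inside chromatin condensates.  In a tomogram their
densities overlap, and the missing wedge of a limited tilt range
(typically ±60°) smears every particle along the beam axis while the
contrast transfer function (CTF) modulates contrast with spatial
frequency.  Conventional exhaustive template matching — score every
voxel against every rotated template, keep the best orientation per
voxel, suppress candidates within a centre-to-centre cutoff — merges,
duplicates or misorients particles under these conditions and biases
the recovered orientation distribution.

`catmtools` implements **context-aware template matching (CATM)**:

1. seed centroids come from an upstream localization step (a learned
   segmentation, a MeanShift of an external segmentation volume, or the
   built-in classical matched filter);
2. local template matching around each centroid retains a **list** of
   candidate poses (per-orientation best position within a search
   radius, CCC ≥ 0.3) instead of a single winner;
3. particles are mapped back into the volume in descending order of
   best CCC; a steric clash with already-placed particles is resolved
   first from the particle's own alternatives, then by jointly
   optimizing the candidate pair with the nearest placed neighbour
   (maximizing summed CCC over sterically compatible combinations), and
   if no compatible combination exists only the stronger particle
   survives.

The matching score everywhere is masked, locally normalized
cross-correlation: the template is rotated, degraded with the same
missing wedge and CTF as the data, standardized under its rotated
steric mask, and correlated by FFT (`CCC in [-1, 1]`).

The package also provides the synthetic-tomogram benchmark used to
validate the method (parametric nucleosome/DNA templates, uniform
non-overlapping configurations, CTF + noise + wedge forward model) and
the downstream spatial statistics of condensate organization: sphere or
plane fits of annotated interfaces, angle-to-interface distributions,
steric contact graphs with valence distributions, normalized valence
entropy, attribute assortativity, DBSCAN clustering and
cluster-fraction-versus-depth profiles.

## Worked example

Simulate a condensate-like tomogram with known ground truth, run both
matchers, and score them:

```r
library(catmtools)

cfg   <- catm_config()                    # all defaults in one list
sim   <- generate_benchmark(cfg, seed = 1)
tmpl  <- sim$templates$nucleosome
gt    <- sim$gt[sim$gt$kind == "nucleosome", ]

## baseline exhaustive TM + threshold sweep
cands <- tm_search(sim$tomogram, tmpl, rotation_grid(15), sim$model,
                   score_floor = cfg$tm$score_floor)
pred  <- nms_distance_cutoff(cands, cfg$tm$nms_cutoff)
sweep <- ccc_threshold_sweep(pred, gt, cfg$tm$sweep_thresholds,
                             dist_tol = 5.5, ang_tol = 30)
attr(sweep, "best")
#>   threshold n_pred precision    recall        f1 precision_ang recall_ang
#> 9       0.3     58 0.8965517 0.6933333 0.7819549     0.8793103       0.68
#>      f1_ang
#> 9 0.7669173

## CATM, seeded with jittered centroids emulating a segmentation step
cen  <- perturb_centroids(sim$gt, sigma_nm = 1.5, seed = 42)
catm <- run_catm(sim$tomogram, tmpl, cen, sim$model, cfg)
precision_recall_f1(match_particles(gt, catm, dist_tol = 5.5))
#> precision    recall        f1
#>         1         1         1
```

On this tomogram the best TM threshold reaches F1 ≈ 0.78 for positions
(0.77 when orientation agreement within 30° is also required), while
CATM places all 75 nucleosomes correctly with no steric clash in the
output.  The orientation diagnostic
(`orientation_distribution()`) compares assigned disc-normal angles to
the sin(θ) law of uniformly random orientations: CATM's histogram is
statistically indistinguishable from it, while TM underrepresents
face-on views (first bin).

Spatial statistics run on any particle table (STAR or CSV):

```r
ps   <- generate_condensate(seed = 1)          # planted-structure demo
mask <- build_steric_mask(build_nucleosome_template())
an   <- analyze_condensate(ps, mask, surface = attr(ps, "surface"))
an$entropy                 # normalized valence entropy in [0, 1]
an$cluster_sizes           # DBSCAN cluster-size distribution
an$depth_profile           # cluster fraction vs depth from interface
```

## Command line

A thin wrapper over the same functions ships in `exec/catmtools`:

```sh
catmtools simulate  --seed 1 --out sim/
catmtools tm        --tomogram sim/tomogram.mrc --out tm.star
catmtools catm      --tomogram sim/tomogram.mrc --centroids cen.csv --out catm.star
catmtools evaluate  --gt sim/ground_truth.star --pred catm.star --ang-tol 30
catmtools analyze   --particles catm.star --perimeter perimeter.csv --out analysis/
catmtools benchmark --seed 1 --out report/
```

All I/O uses MRC2014 volumes (mode-2 float, nm voxel sizes), STAR
particle tables (coordinates in voxels, ZYZ Euler angles in degrees) or
CSV (nm), GraphML for contact graphs, and YAML for configuration
overrides.

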