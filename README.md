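# ooclust

Quantitative image analysis of chromosome clustering in mammalian oocytes.

After nuclear envelope breakdown (NEBD), oocytes of large mammals gather
their dispersed chromosomes into a single compact cluster before the
acentrosomal spindle assembles; failures of this step leave chromosomes
uncaptured. `ooclust` implements the image-quantification pipeline for
studying that process in multi-channel 3D time-lapse fluorescence
microscopy:

- **Clustering kinetics** — segmentation of chromatin foci (Otsu
  threshold, 26-connected components, volume gate), then the *largest
  pairwise distance* L(t) = max over point pairs of the focus surfaces,
  the volume of the 3D convex hull enclosing all foci, focus counts, and
  the clustering speed `-ΔL/Δt` averaged over reporting windows
  (0–30 and 30–50 min post-NEBD).
- **Automatic NEBD detection** — the mean intensity of a cytoplasmic
  dextran marker inside a 10 µm probe sphere at the chromosome centre of
  mass, triggered when it exceeds `median + k·sd` of its own history
  (adaptive per-oocyte threshold, default k = 5).
- **Actin-flow directionality** — translational stabilization on the
  nuclear lamina, lamina segmentation via a cyclic smoothing spline in
  polar coordinates, three-pass cross-correlation PIV (64/32/24 px
  windows, 50 % overlap), classification of velocity vectors relative to
  the nuclear centre (inward / outward / sideways sectors), and circular
  statistics (mean direction, 95 % CI, Rayleigh test).
- **Colocalization** — per-spot shortest distance to a volume-gated
  surface (30–1000 µm³ actin surfaces), interaction fractions at a
  distance cutoff, a mirrored-signal null control, and the independence
  expectation for random overlap.
- **Fragmentation analysis** — classification of chromatin fragments by
  the 30 µm³ size gate and kinetochore content, and time-to-complete-
  clustering read-outs.
- **Synthetic data** — a ground-truthed generator for 3D+t oocyte
  volumes (chromatin, kinetochores, actin, lamina, dextran, membrane),
  2D+t actin-flow frames with programmed inward bias, and fixed-cell
  kinetochore/actin volumes with programmed contact probability, so that
  every stage is testable with no external data.

## Worked example

Simulate one porcine-like oocyte (20 µm nucleus, 12 chromatin bodies
converging at 0.43 µm/min after NEBD at t = 30 min, 5-min frames), detect
NEBD from the dextran channel, and measure its clustering kinetics:

```r
library(ooclust)

sc  <- oocyte_scenario(seed = 1, nucleus_radius = 10, n_frames = 14)
sim <- generate_oocyte_series(sc)

ev <- detect_nebd(sim$series)
#> NEBD trigger at frame 7 (t = 30.00 min), threshold 1.04

foci <- lapply(seq_len(14), function(i)
  segment_chromatin_foci(get_channel(sim$series, i, "chromatin"),
                         sim$series$voxel_size))
kin <- cluster_kinetics(foci, sim$series$times,
                        nebd_time = ev$trigger_time_min)
kin[, c("frame", "time_from_nebd_min", "lpd_um", "hull_um3", "n_foci")]
#>    frame time_from_nebd_min lpd_um hull_um3 n_foci
#> 1      1                -30  19.12   1299.1     12
#> 7      7                  0  19.12   1281.7     12
#> 8      8                  5  17.53    820.8      9
#> 9      9                 10  15.80    657.9      6
#> 10    10                 15  12.09    419.5      3
#> 11    11                 20   9.97    237.9      1
#> 13    13                 30   6.78     55.6      1

clustering_speed(kin, c(0, 30))
#> [1] 0.411
```

The trigger lands on the true NEBD frame; the largest pairwise distance
is flat before NEBD and then falls linearly; the focus count drops from
12 to 1 as the cluster forms; and the measured 0–30 min clustering speed
(0.411 µm/min) recovers the generative rate (0.43 µm/min) within the
segmentation noise of a single cell.

The same stages are scriptable: `run_pipeline(list(seed = 1))` executes
simulate → segment → nebd → kinetics and writes CSV tables, a YAML
manifest and a log; `inst/cli/ooclust` wraps it as a subcommand CLI
(`simulate`, `segment`, `nebd`, `kinetics`, `flow`, `coloc`, `run-all`)
whose exit code distinguishes NEBD event (0) from no-event (2) for
acquisition-style chaining.

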