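# surfmvpa

Surface-space searchlight multivariate pattern analysis (sf-MVPA) for fMRI,
for researchers who decode cognitive states from cortical surface data and
want the whole chain — mesh handling, parcellation, decoding, inference,
response modelling, connectivity — in one tested R package.

## What it does

Vertex-level surface templates are far finer (≈ 0.54 mm nearest-vertex
spacing on the standard 163,842-vertex average surface) than functional
voxels, so decoding per vertex wastes orders of magnitude of computation.
`surfmvpa` implements the **double-radius dividing** algorithm: sweeping
vertices in index order, an unpainted vertex seeds a label and captures every
unpainted vertex within radius *r* (painted green), while vertices between
*r* and *R* = 2*r* are painted yellow and later join the nearest green
centroid. The result is a partition into compact labels (~14–16 vertices,
~2.1 mm apart for *r* = 0.9 mm) whose resolution matches the functional data.

On the label space the package provides:

- **Searchlight decoding** — for each label, the labels with centres within
  10 mm form its searchlight; trials are decoded frame by frame (21 frames at
  TR = 1 s) with leave-one-run-out cross-validation, fold-internal z-scoring,
  and one-vs-one linear SVMs (C = 1, majority vote). Task-vs-control decoding
  (chance 50%) balances classes by downsampling each memory load to a quarter
  of the control count; load decoding (chance 25%) uses the four loads.
- **Group inference** — one-sided t-tests of accuracy vs chance across
  subjects, thresholded at p < 10⁻⁴ with Benjamini–Hochberg FDR q = 0.01, and
  recursive extraction of connected clusters (> 10 labels, adjacency =
  closest vertex pair < 1.1 mm) with areas in mm².
- **Response strength** — double-gamma HRF, 21-s boxcar designs, label-wise
  OLS, adjacent-condition paired contrasts (element p < 0.01, cluster-wise
  p < 0.05 by sign-flip permutation), baseline-zeroed control-subtracted
  response curves, and regression of mean curve amplitude on memory load
  (p < 0.05, cluster > 10).
- **Seed connectivity** — per-trial Pearson correlation of 21-frame windows
  between an ROI (seed label + adjacent labels) and every label, averaged per
  load, regressed on load across subjects.
- **Synthetic data** — a generator reproducing the reference paradigm (100
  trials, 20 per condition incl. control, runs of 33/33/34, 1-s frames) on a
  template-density sphere, with AR(1)+white noise and three injectable
  effects: condition patterns, load-proportional amplitude, load-proportional
  seed–target coupling.
- **I/O** — FreeSurfer binary surfaces, curv overlays and annot
  parcellations; GIFTI surfaces and scalar arrays; TSV exports throughout.

## Worked example

```r
library(surfmvpa)

mesh <- make_icosphere(subdivisions = 4, radius = 8.25)  # template-density sphere
mean_nearest_vertex_distance(mesh)        # 0.595 mm
parc <- double_radius_divide(mesh, r = 0.9, R = 1.8)
parc                                      # 2562 vertices -> 162 labels
mean_nearest_label_distance(parc)         # 2.29 mm
sl <- build_searchlights(parc$centers, radius = 5)
range(lengths(sl))                        # 15 18

cfg <- sim_config(n_subjects = 2, seed = 42)   # pattern + coupling injected
study <- simulate_study(cfg)
fr <- pattern_active_frames(cfg)               # frames 9..15 post-onset
map <- searchlight_decode_map(study$subjects[[1]], study$trials,
                              study$searchlights, scheme = "task", seed = 1,
                              frames = fr[4],
                              labels = c(study$regions$pattern[1],
                                         study$regions$amplitude[1]))
map[study$regions$pattern[1], 1]    # 0.900  -- decodable inside the pattern region
map[study$regions$amplitude[1], 1]  # 0.555  -- near chance elsewhere

average_condition_accuracy(c(77.6, 84.1, 75.4, 65.7))   # 75.7
```

The parcellation statistics mirror the full-size template's published
behaviour (≈ 0.54 mm vertex spacing in, ~2 mm label spacing and ~16
vertices/label out); the per-subject accuracy is high where a spatial pattern
was injected and at chance where none was, and the final line is the
behavioural summary: the equal-weighted mean of the four per-condition
response accuracies in percent.

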