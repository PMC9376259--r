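---
title: "Surface-space searchlight MVPA: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-space searchlight MVPA: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfmvpa)
```

## The problem

Searchlight multivariate pattern analysis asks, for every location on the
cortex, whether the local pattern of fMRI activity distinguishes experimental
conditions. Volumetric searchlights have two well-known defects: they mix
gray matter with other tissue, and — because the cortex is folded — a sphere
in volume space can span patches that are centimetres apart along the sheet.
Working directly on a surface mesh avoids both, but a registration template
such as FreeSurfer's average subject has 163,842 vertices per hemisphere with
a mean nearest-vertex spacing of about 0.54 mm, an order of magnitude finer
than functional voxels. Running one cross-validated classifier per vertex and
frame is wasteful at that resolution.

`surfmvpa` implements the remedy this package is organised around: the
**double-radius dividing** of the vertex space into small, approximately
uniform patches ("labels"), followed by label-space searchlight decoding,
group inference, response-strength modelling and seed connectivity.

## Double-radius dividing

Vertices are swept in ascending index order. An unpainted vertex becomes a
seed; every still-unpainted vertex strictly closer than `r` (including the
seed at distance 0) is painted green and joins the seed's label, and every
still-unpainted vertex at distance in `[r, R)` is painted yellow. Painted
vertices never seed, and the double radius `R = 2r` keeps neighbouring green
cores from overlapping. After the sweep, each yellow vertex joins the label
with the nearest green centroid (ties to the lowest label id). All distances
are 3-D Euclidean and all comparisons strict.

Two readings of "nearest label" are possible — nearest seed vertex or nearest
centroid of the green members. The centroid reading is the plain sense of
"centre position" and is the default; both are exposed through the
`membership` argument of `label_centers()`. The sweep contains no randomness:
a mesh and parameters determine the parcellation exactly, and the optimised
implementation (a uniform-grid spatial index with exact distance checks) is
tested for bit-identical agreement with a literal transcription of the rules.

With `r = 0.9` mm on a surface of ~0.54 mm vertex spacing, labels contain
roughly 14-16 vertices and neighbouring label centres sit ~2.1 mm apart —
comparable to a 2.5 mm functional voxel, which is the point of the
construction: the label space matches the information content of the data.

```{r chain}
chain <- surface_mesh(cbind(0:9, 0, 0))
parc <- double_radius_divide(chain, r = 0.95, R = 1.9)
parc$assignment
mean_nearest_label_distance(parc)
```

## Searchlight decoding

A searchlight of a label is every label whose centre lies strictly within
`searchlight_radius` of its centre (10 mm on a full-size cortex; the central
label is always a member). Decoding is frame-by-frame: for frame offset
`k` in 0..20 after stimulus onset, the feature vector of a trial is the
label-space BOLD at `onset + k` — no temporal window, no hemodynamic
deconvolution. Instances are split by run (leave-one-run-out, threefold for
the reference 3-run design), z-scored per feature with training-fold
statistics only (no test-set leakage; this also makes maps invariant to any
per-feature affine rescaling), and classified by one-vs-one linear SVMs
(C = 1) with majority voting. Fold accuracies are averaged into the map.

Two schemes exist. `"task"` collapses the four memory loads against control
(chance 0.5); because task trials outnumber control 4:1, each load is
downsampled to `floor(n_control / 4)` instances, drawn once per subject and
reused for every label and frame so the map is comparable across the surface.
`"load"` decodes the four loads (chance 0.25), excludes control, and needs no
balancing.

## Group inference

Per label (and frame), subjects' accuracies are compared to chance with a
one-sided one-sample t-test; significance requires jointly `p < 1e-4`
uncorrected **and** Benjamini–Hochberg FDR rejection at `q = 0.01` (family =
the labels of one frame; an across-frames family is available — the reference
criteria report per-frame maps, so per-frame is the default), and membership
in a connected cluster of strictly more than 10 labels under the label
adjacency (two labels are adjacent when their closest vertex pair is under
1.1 mm). Cluster extraction is the recursive grouping of masked labels into
connected components, implemented with an explicit stack and cross-checked
against an independent graph library. Degenerate zero-variance cells use
conservative conventions: exactly at chance gives p = 0.5; above chance with
zero variance gives p = 0 but is flagged `degenerate`.

## Response strength and load regression

The response model convolves 21 s condition boxcars with the canonical
double-gamma HRF (peak 6 s, undershoot 16 s, unit dispersions, ratio 6 —
"standard" parameters, since no others are printed) and fits ordinary least
squares per label; adjacent-condition contrasts are paired t-tests across
subjects, thresholded element-wise at p < 0.01 with cluster-wise p < 0.05
calibrated by sign-flip permutation of the subject difference maps (the
reference analysis names no cluster-calibration method; sign-flipping is the
standard nonparametric choice for one-sample designs). The GLM runs in label
space here; the reference ran it at vertex level — one code path was
preferred, and `downsample_series()` makes the vertex route available.

Response curves are computed per condition as the trial-averaged window from
one frame before onset to 20 after, minus the control average, shifted so the
pre-onset sample is zero; their **mean amplitude** (the average of the 21
samples; a peak option exists) enters a per-subject OLS slope on load, tested
against zero across subjects (two-sided, p < 0.05, cluster > 10, no FDR —
matching the printed criterion for this analysis). A pooled-OLS variant is
available; the random-effects (per-subject slope) form is the default because
the second-level analyses elsewhere in the pipeline are random-effects.

## Seed connectivity

An ROI's curve is the unweighted mean of its seed label and the labels
adjacent to it. Per trial, the Pearson correlation of the 21 post-onset
frames between the ROI curve and every label is computed; windows of zero
variance yield undefined correlations, which are dropped (not zero-filled)
when averaging within each load. The per-subject load-by-label tensors enter
the same slope test as amplitudes. Correlations can optionally be
Fisher-z transformed before regression; the default is raw r, as nothing in
the reference indicates a transform. The 21-frame window starts at onset
(whether the baseline frame was included is not documented; starting at onset
matches the decoding window).

## The synthetic study

`sim_config()` defines the validation world; its defaults are the reference
study's conditions wherever those are stated:

| parameter | default | basis |
|---|---|---|
| subjects | 23 | participant count |
| trials | 5 conditions x 20, runs 33/33/34 | paradigm |
| frame period | 1 s | acquisition TR |
| trial spacing | 32 s | 1 s silence + tones + 20 s delay + probe/answer |
| mesh | icosphere subdiv 4, radius 8.25 mm | ~0.54 mm vertex spacing, matching the template density so r = 0.9 / R = 1.8 / 1.1 mm act at the intended scale |
| searchlight radius | 5 mm | scaled to the toy sphere; 10 mm would cover most of it |
| noise | AR(1) phi 0.4, innovation sd 1, white sd 0.5 | plausible 1-s-TR BOLD autocorrelation; chosen once |
| pattern sd | 2 (shared across loads) | ~0.7-0.85 within-subject decodability, a realistic strong effect |
| amplitude slope | 0 | the reference found no load-amplitude effect |
| coupling | c0 0.5, c1 0.3, latent sd 1 | load-dependent connectivity, the reference's positive finding |

Three effects are injectable, one per analysis. The **pattern** effect adds a
fixed per-subject random spatial vector over a 12-label patch, modulated by
the HRF-convolved indicator of its active window. By default the vector is
*shared* across loads 1-4: the task is decodable against control while the
loads are mutually indistinguishable — precisely the dissociation the method
reported on real data (`pattern_mode = "per-condition"` gives each load its
own vector instead). The **amplitude** effect adds an HRF-convolved 21 s
boxcar scaled by `slope x load`. The **coupling** effect draws a fresh latent
series per non-control trial and adds it to the seed region with weight 1 and
to the target region with weight `c0 + c1 x load`, so seed-target correlation
rises with load. Everything is deterministic given the master seed;
per-subject and per-stage streams are derived from it.

What the generator does **not** emulate: physiological noise structure,
motion, spatial noise correlations beyond the label graph, hemodynamic
variability across regions, behavioural errors. Passing the validation suite
therefore demonstrates the *analysis machinery* — calibration under the null
and recovery of known effects — not performance on real data.

## Evaluation choices

Recovery of the pattern region is judged at searchlight resolution: a
searchlight map attributes information to every centre whose searchlight
overlaps the source, so the ground-truth set for the Jaccard overlap is all
labels whose searchlight intersects the injected patch. The group test runs
on the accuracy map averaged over the frames where the effect envelope is at
least 90% of peak — the effect is sustained there, so averaging is the
efficient statistic. Problem sizes in the validation suite (a 2,562-vertex
sphere, 162 labels, 23 subjects, full trial counts) were chosen so the whole
suite runs on a laptop in minutes.

The amplitude estimand needs one care: the injected slope multiplies a
peak-normalised HRF envelope, while the analysis reports the mean of the 21
curve samples, so the recoverable truth is `slope x mean(envelope)` — the
recovery test compares against that, not the raw slope.

## Known limitations

- Distances are 3-D Euclidean throughout, as in the reference method; no
  geodesic computation is performed, so labels and searchlights near deep
  folds of a *real* cortex can span the fold. On the synthetic sphere this is
  immaterial.
- The template statistics (11,895 labels, 0.542 mm, 2.08 mm, 36-91
  searchlight members) depend on which fsaverage geometry (white, pial,
  inflated) carries the coordinates; the reference does not say. The toolkit
  accepts any geometry file; exact reproduction is expected only on the
  matching surface.
- FDR family (per frame vs across frames) and balancing-redraw policy
  (once per subject vs per frame) are documented defaults with switches, as
  the reference leaves both unstated.
- No nuisance regressors, prewhitening, or HRF basis sets in the GLM; no
  partial correlations or graph metrics in connectivity.
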