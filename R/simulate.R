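#' Simulation configuration
#'
#' Defines a complete synthetic study: a spherical cortical sheet with the
#' vertex density of the standard high-resolution template (~0.54 mm nearest-
#' vertex spacing), the reference working-memory paradigm (5 conditions
#' including control, 20 trials each, split 33/33/34 over three 1-s-frame
#' runs), AR(1)-plus-white label-space noise, and three independently
#' injectable effects mirroring the three analyses: condition-specific spatial
#' patterns (what a decoder can exploit), load-proportional response
#' amplitude, and load-proportional seed-target coupling. Defaults encode the
#' reference study's outcome: patterns present (task decodable), amplitude
#' slope zero (no load effect on response strength), coupling slope positive
#' (load-dependent connectivity).
#'
#' @param mesh_subdivisions icosphere subdivision level.
#' @param mesh_radius sphere radius in mm (8.25 mm at subdivision 4 gives
#'   ~0.54 mm vertex spacing).
#' @param r,R double-radius dividing parameters (mm).
#' @param adjacency_threshold label adjacency threshold (mm).
#' @param searchlight_radius searchlight radius (mm); 5 mm on the small
#'   synthetic sphere plays the role the 10 mm radius plays on a full-size
#'   cortex.
#' @param n_subjects number of simulated subjects.
#' @param trials_per_condition trials per condition (5 conditions).
#' @param run_trials trial counts per run; must sum to 5 * trials_per_condition.
#' @param frame_period_s frame period in seconds.
#' @param trial_spacing_s inter-onset spacing in frames/seconds.
#' @param baseline constant signal baseline (a.u.).
#' @param ar_phi AR(1) coefficient of the slow noise component, in \[0, 1).
#' @param ar_sd innovation standard deviation of the AR(1) component.
#' @param white_sd standard deviation of the white noise component.
#' @param pattern_sd per-label standard deviation of the injected spatial
#'   patterns (0 disables the effect).
#' @param pattern_mode `"shared"` (default): one fixed spatial vector common
#'   to all pattern conditions, so the task is decodable against control but
#'   load levels are not decodable from each other -- the reference study's
#'   dissociation. `"per-condition"`: an independent vector per condition,
#'   making load levels mutually decodable as well.
#' @param pattern_conditions conditions that carry a pattern (default 1:4).
#' @param pattern_window frames after onset during which the pattern is active
#'   (before HRF convolution), default `c(0, 12)`.
#' @param pattern_n_labels size of the pattern region.
#' @param amplitude_slope per-load response amplitude increment (a.u.; 0
#'   disables, mirroring the reference null result).
#' @param amplitude_n_labels size of the amplitude region.
#' @param coupling_c0 baseline seed-target coupling weight.
#' @param coupling_c1 per-load coupling increment (0 disables).
#' @param coupling_latent_sd standard deviation of the shared latent signal.
#' @param coupling_seed_n_labels,coupling_target_n_labels region sizes.
#' @param seed master RNG seed; every stochastic step derives its own stream
#'   from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(mesh_subdivisions = 4, mesh_radius = 8.25,
                       r = 0.9, R = 2 * r, adjacency_threshold = 1.1,
                       searchlight_radius = 5,
                       n_subjects = 23, trials_per_condition = 20,
                       run_trials = c(33, 33, 34), frame_period_s = 1,
                       trial_spacing_s = 32, baseline = 100,
                       ar_phi = 0.4, ar_sd = 1, white_sd = 0.5,
                       pattern_sd = 2, pattern_mode = c("shared", "per-condition"),
                       pattern_conditions = 1:4,
                       pattern_window = c(0, 12), pattern_n_labels = 12,
                       amplitude_slope = 0, amplitude_n_labels = 12,
                       coupling_c0 = 0.5, coupling_c1 = 0.3,
                       coupling_latent_sd = 1, coupling_seed_n_labels = 6,
                       coupling_target_n_labels = 12, seed = 1L) {
  cfg <- as.list(environment())
  cfg$pattern_mode <- match.arg(pattern_mode)
  if (sum(run_trials) != 5 * trials_per_condition)
    stop_arg("run_trials must sum to 5 * trials_per_condition (%d)",
             5 * trials_per_condition)
  if (ar_phi < 0 || ar_phi >= 1) stop_arg("ar_phi must be in [0, 1)")
  if (any(c(ar_sd, white_sd, pattern_sd, coupling_latent_sd) < 0))
    stop_arg("noise and effect standard deviations must be non-negative")
  if (trial_spacing_s < 22)
    stop_arg("trial_spacing_s must be >= 22 so each 21-frame window plus the baseline frame fits")
  structure(cfg, class = "sim_config")
}

#' Random trial paradigm
#'
#' Shuffles the 5 x trials_per_condition conditions uniformly, splits them
#' across runs per `run_trials`, and lays out onsets at the configured spacing
#' so every trial has one pre-onset baseline frame and a full 21-frame window.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to a stream derived from `config$seed`).
#' @return trial table: data frame with `onset`, `condition`, `run`.
#' @export
make_paradigm <- function(config, seed = derive_seed(config$seed, 101)) {
  conds <- rep(0:4, each = config$trials_per_condition)
  conds <- with_seed(seed, sample(conds))
  run <- rep(seq_along(config$run_trials), config$run_trials)
  onset <- unlist(lapply(config$run_trials, function(n)
    2L + (seq_len(n) - 1L) * as.integer(config$trial_spacing_s)))
  data.frame(onset = onset, condition = conds, run = run)
}

run_length <- function(config, n_trials) {
  2L + (n_trials - 1L) * as.integer(config$trial_spacing_s) + 21L + 2L
}

#' Contiguous label region around a point
#'
#' The `n` labels whose centres are nearest to `point` -- on a parcellated
#' sphere this is a compact cap, used to place simulated effects.
#'
#' @param centers label centres matrix.
#' @param point length-3 coordinate (mm).
#' @param n region size in labels.
#' @return integer vector of label ids.
#' @export
region_around <- function(centers, point, n) {
  d2 <- cross_dist2(matrix(point, 1, 3), centers)
  order(d2[1, ])[seq_len(n)]
}

# resolve the three default effect regions on well-separated parts of the
# sphere: pattern at +z, amplitude at -x, coupling seed at -z / target at +x
resolve_regions <- function(config, centers) {
  rad <- config$mesh_radius
  list(
    pattern = region_around(centers, c(0, 0, rad), config$pattern_n_labels),
    amplitude = region_around(centers, c(-rad, 0, 0), config$amplitude_n_labels),
    coupling_seed = region_around(centers, c(0, 0, -rad),
                                  config$coupling_seed_n_labels),
    coupling_target = region_around(centers, c(rad, 0, 0),
                                    config$coupling_target_n_labels))
}

# peak-normalised HRF-convolved indicator of a window, as a within-trial
# envelope of length 21 (frames 0..20 after onset)
trial_envelope <- function(window, hrf = canonical_hrf()) {
  ind <- numeric(21)
  ind[(window[1]:window[2]) + 1L] <- 1
  env <- stats::convolve(ind, rev(hrf), type = "open")[1:21]
  env / max(env)
}

#' Frames where an injected effect is near its peak
#'
#' The within-trial envelope of an injected effect is its window indicator
#' convolved with the HRF; this returns the frame offsets (0-based) where the
#' envelope is at least `frac` of its maximum -- the frames at which the
#' corresponding analysis has full sensitivity.
#'
#' @param config a [sim_config()].
#' @param frac envelope fraction defining "active" (default 0.9).
#' @return integer vector of frame offsets in 0..20.
#' @export
pattern_active_frames <- function(config, frac = 0.9) {
  env <- trial_envelope(config$pattern_window,
                        canonical_hrf(frame_period_s = config$frame_period_s))
  which(env >= frac * max(env)) - 1L
}

#' Simulate label-space BOLD runs for one subject
#'
#' Signal model per label and frame:
#' baseline + AR(1) noise + white noise + injected effects. The pattern effect
#' adds, for every trial of an active condition, a fixed (per subject x
#' condition) random spatial vector over the pattern region, modulated by the
#' HRF-convolved indicator of the active window. The amplitude effect adds an
#' HRF-convolved 21-s boxcar scaled by `amplitude_slope * load` over its
#' region. The coupling effect draws a shared latent series in each non-control
#' trial window and adds it with weight 1 to the seed region and weight
#' `c0 + c1 * load` to the target region.
#'
#' @param config a [sim_config()].
#' @param trials trial table from [make_paradigm()].
#' @param regions list with elements `pattern`, `amplitude`, `coupling_seed`,
#'   `coupling_target` (label id vectors), e.g. from the parcellation via
#'   [region_around()].
#' @param n_labels number of labels in the parcellation.
#' @param subject subject index (selects the derived RNG stream).
#' @return list of labels x frames matrices, one per run, named by run id.
#' @export
simulate_bold <- function(config, trials, regions, n_labels, subject = 1L) {
  if (max(unlist(regions)) > n_labels)
    stop_arg("effect region outside the parcellation (%d labels)", n_labels)
  hrf <- canonical_hrf(frame_period_s = config$frame_period_s)
  pat_env <- trial_envelope(config$pattern_window, hrf)
  amp_env <- trial_envelope(c(0, 20), hrf)
  runs <- sort(unique(trials$run))
  out <- vector("list", length(runs))
  names(out) <- as.character(runs)
  with_seed(derive_seed(config$seed, 7, subject), {
    # fixed spatial pattern(s) for this subject: one shared vector, or one
    # independent vector per active condition
    shared <- stats::rnorm(length(regions$pattern), 0, config$pattern_sd)
    patterns <- lapply(config$pattern_conditions, function(cc)
      if (identical(config$pattern_mode, "per-condition"))
        stats::rnorm(length(regions$pattern), 0, config$pattern_sd)
      else shared)
    names(patterns) <- as.character(config$pattern_conditions)
    for (ri in seq_along(runs)) {
      tr <- trials[trials$run == runs[ri], , drop = FALSE]
      nf <- run_length(config, nrow(tr))
      innov <- matrix(stats::rnorm(nf * n_labels, 0, config$ar_sd), nf, n_labels)
      ar <- stats::filter(innov, config$ar_phi, method = "recursive")
      noise <- t(ar) + matrix(stats::rnorm(nf * n_labels, 0, config$white_sd),
                              n_labels, nf, byrow = FALSE)
      m <- matrix(config$baseline, n_labels, nf) + noise
      for (i in seq_len(nrow(tr))) {
        o <- tr$onset[i]; cond <- tr$condition[i]
        win <- o:(o + 20L)
        if (cond > 0 && !is.null(patterns[[as.character(cond)]]) &&
            config$pattern_sd > 0)
          m[regions$pattern, win] <- m[regions$pattern, win] +
            outer(patterns[[as.character(cond)]], pat_env)
        if (cond > 0 && config$amplitude_slope != 0)
          m[regions$amplitude, win] <- m[regions$amplitude, win] +
            rep(config$amplitude_slope * cond * amp_env,
                each = length(regions$amplitude))
        if (cond > 0 && (config$coupling_c0 != 0 || config$coupling_c1 != 0) &&
            config$coupling_latent_sd > 0) {
          z <- stats::rnorm(21, 0, config$coupling_latent_sd)
          g <- config$coupling_c0 + config$coupling_c1 * cond
          m[regions$coupling_seed, win] <- m[regions$coupling_seed, win] +
            rep(z, each = length(regions$coupling_seed))
          m[regions$coupling_target, win] <- m[regions$coupling_target, win] +
            g * rep(z, each = length(regions$coupling_target))
        }
      }
      out[[ri]] <- m
    }
  })
  out
}

#' Simulate a complete study
#'
#' Builds the synthetic sphere, parcellates it, derives adjacency, areas,
#' centres and searchlights, draws one paradigm, resolves the effect regions,
#' and simulates every subject. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study` with `config`, `mesh`, `parcellation`,
#'   `centers`, `adjacency`, `areas` (per label, mm^2), `searchlights`,
#'   `trials`, `regions`, `subjects` (list of per-run series lists).
#' @export
simulate_study <- function(config) {
  mesh <- make_icosphere(config$mesh_subdivisions, config$mesh_radius)
  parc <- double_radius_divide(mesh, config$r, config$R)
  adjacency <- build_adjacency(parc, mesh, config$adjacency_threshold)
  areas <- label_areas(parc, mesh)
  searchlights <- build_searchlights(parc$centers, config$searchlight_radius)
  trials <- make_paradigm(config)
  regions <- resolve_regions(config, parc$centers)
  subjects <- lapply(seq_len(config$n_subjects), function(s)
    simulate_bold(config, trials, regions, n_labels(parc), subject = s))
  structure(list(config = config, mesh = mesh, parcellation = parc,
                 centers = parc$centers, adjacency = adjacency, areas = areas,
                 searchlights = searchlights, trials = trials,
                 regions = regions, subjects = subjects),
            class = "sim_study")
}

#' Null dataset: same machinery, all effects disabled
#'
#' @param config a [sim_config()]; its effect sizes are forced to zero.
#' @return a `sim_study` with `pattern_sd`, `amplitude_slope`, `coupling_c0`
#'   and `coupling_c1` all zero.
#' @export
make_null_dataset <- function(config) {
  config$pattern_sd <- 0
  config$amplitude_slope <- 0
  config$coupling_c0 <- 0
  config$coupling_c1 <- 0
  simulate_study(config)
}

#' Per-label surface area
#'
#' Sum of member-vertex areas (vertex area = one third of incident triangle
#' areas), so label areas sum to the total mesh area.
#'
#' @param parcellation a `parcellation`.
#' @param mesh the mesh it was computed on.
#' @return numeric vector of label areas in mm^2.
#' @export
label_areas <- function(parcellation, mesh) {
  va <- vertex_areas(mesh)
  as.numeric(rowsum(va, factor(parcellation$assignment,
                               levels = seq_len(n_labels(parcellation)))))
}
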