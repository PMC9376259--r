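test_that("the default paradigm reproduces the reference trial structure", {
  cfg <- sim_config()
  trials <- make_paradigm(cfg)
  expect_equal(nrow(trials), 100)
  expect_equal(unname(table(trials$condition)), rep(20L, 5),
               ignore_attr = TRUE)
  expect_equal(unname(table(trials$run)), c(33L, 33L, 34L),
               ignore_attr = TRUE)
  # fixed seed reproduces the identical table
  expect_identical(trials, make_paradigm(cfg))
  # minimum spacing honoured within runs
  for (r in 1:3) {
    o <- sort(trials$onset[trials$run == r])
    if (length(o) > 1) expect_true(all(diff(o) >= cfg$trial_spacing_s))
  }
  # every window plus baseline frame fits its run
  nf <- surfmvpa:::run_length(cfg, 34)
  expect_true(all(trials$onset >= 2 & trials$onset + 20 <= nf))
  expect_error(sim_config(run_trials = c(10, 10, 10)), "sum")
  expect_error(sim_config(ar_phi = 1), "ar_phi")
  expect_error(sim_config(trial_spacing_s = 10), "spacing")
})

test_that("simulation is deterministic and effects land in their regions", {
  cfg <- tiny_sim_config()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$trials, s2$trials)
  # different seed changes the data
  s3 <- simulate_study(tiny_sim_config(seed = 12))
  expect_false(identical(s1$subjects[[1]][[1]], s3$subjects[[1]][[1]]))
  # effect regions are disjoint by construction on this geometry
  expect_length(intersect(s1$regions$pattern, s1$regions$amplitude), 0)
  expect_length(intersect(s1$regions$coupling_seed, s1$regions$coupling_target), 0)
})

test_that("all-zero noise and effects give a flat baseline", {
  cfg <- tiny_sim_config(ar_sd = 0, white_sd = 0, pattern_sd = 0,
                         amplitude_slope = 0, coupling_c0 = 0,
                         coupling_c1 = 0)
  study <- simulate_study(cfg)
  for (run in study$subjects[[1]])
    expect_true(all(run == cfg$baseline))
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
  cfg <- tiny_sim_config(trials_per_condition = 20,
                         run_trials = c(33, 33, 34), ar_phi = 0.4,
                         white_sd = 0)
  study <- simulate_study(cfg)
  m <- study$subjects[[1]][[1]]
  # off-effect labels carry pure AR(1) noise
  off <- setdiff(seq_len(nrow(m)), unlist(study$regions))
  ac <- apply(m[off[1:10], ], 1, function(x) cor(x[-1], x[-length(x)]))
  expect_lt(abs(mean(ac) - 0.4), 0.05)
})

test_that("injected amplitude slope is recovered by the GLM pipeline", {
  cfg <- tiny_sim_config(n_subjects = 12, amplitude_slope = 0.8,
                         pattern_sd = 0, coupling_c0 = 0, coupling_c1 = 0,
                         seed = 31)
  study <- simulate_study(cfg)
  L <- n_labels(study$parcellation)
  amp <- array(NA_real_, c(cfg$n_subjects, 4, L))
  for (s in seq_len(cfg$n_subjects))
    for (cond in 1:4)
      amp[s, cond, ] <- curve_amplitude(
        response_curves(study$subjects[[s]], study$trials, cond))
  res <- amplitude_load_map(amp, study$adjacency, study$areas,
                            min_cluster_labels = 3)
  rec <- sort(unique(unlist(lapply(res$clusters, `[[`, "labels"))))
  expect_true(all(study$regions$amplitude %in% rec))
  # mean recovered slope in the region is proportional to the injected slope;
  # the curve amplitude averages the HRF-shaped response over 21 frames, so
  # compare against slope * mean(envelope)
  env <- surfmvpa:::trial_envelope(c(0, 20))
  target <- 0.8 * mean(env)
  est <- mean(res$stat$mean[study$regions$amplitude])
  expect_lt(abs(est - target) / target, 0.2)
})

test_that("injected coupling makes seed-target correlation increase in load", {
  # the reference trial counts (20 per load) give this property its power;
  # run it on the small mesh to keep the test fast
  ok <- vapply(1:5, function(k) {
    cfg <- tiny_sim_config(trials_per_condition = 20,
                           run_trials = c(33, 33, 34),
                           coupling_c0 = 0.5, coupling_c1 = 0.3,
                           pattern_sd = 0, amplitude_slope = 0, seed = 40 + k)
    study <- simulate_study(cfg)
    roi <- roi_spec("seed", seed_label = study$regions$coupling_seed[1])
    # average the per-subject tensors to estimate the group profile
    tensors <- lapply(study$subjects, condition_connectivity,
                      trials = study$trials, roi = roi,
                      adjacency = study$adjacency)
    tensor <- Reduce(`+`, tensors) / length(tensors)
    tgt <- rowMeans(tensor[, study$regions$coupling_target])
    cor(tgt, 1:4, method = "spearman") == 1
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("null datasets are effect-free for all three analyses", {
  cfg <- tiny_sim_config()
  study <- make_null_dataset(cfg)
  expect_equal(study$config$pattern_sd, 0)
  expect_equal(study$config$amplitude_slope, 0)
  expect_equal(study$config$coupling_c1, 0)
  # decoding a handful of labels at the pattern peak stays near chance
  pk <- max(pattern_active_frames(cfg))
  labels <- c(study$regions$pattern[1:2], study$regions$amplitude[1])
  accs <- unlist(lapply(1:4, function(s)
    searchlight_decode_map(study$subjects[[s]], study$trials,
                           study$searchlights, scheme = "task",
                           seed = s, frames = pk,
                           labels = labels)[labels, 1]))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
  # amplitude regression finds nothing
  L <- n_labels(study$parcellation)
  amp <- array(NA_real_, c(4, 4, L))
  for (s in 1:4) for (cond in 1:4)
    amp[s, cond, ] <- curve_amplitude(
      response_curves(study$subjects[[s]], study$trials, cond))
  res <- amplitude_load_map(amp, study$adjacency, study$areas)
  expect_length(res$clusters, 0)
})

test_that("cross-talk: each effect is invisible to the other analyses", {
  # default config: pattern + coupling injected, amplitude slope zero
  cfg <- tiny_sim_config(n_subjects = 6)
  study <- simulate_study(cfg)
  L <- n_labels(study$parcellation)
  amp <- array(NA_real_, c(6, 4, L))
  for (s in 1:6) for (cond in 1:4)
    amp[s, cond, ] <- curve_amplitude(
      response_curves(study$subjects[[s]], study$trials, cond))
  res <- amplitude_load_map(amp, study$adjacency, study$areas)
  rec <- unlist(lapply(res$clusters, `[[`, "labels"))
  # no amplitude-load cluster should cover the pattern region
  expect_length(intersect(rec, study$regions$pattern), 0)
})
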