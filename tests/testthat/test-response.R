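test_that("canonical HRF starts at zero, peaks at 1 within 4-7 s", {
  h <- canonical_hrf()
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # dense-grid argmax oracle for the continuous double-gamma
  tg <- seq(0, 30, by = 0.001)
  hg <- dgamma(tg, 6, 1) - dgamma(tg, 16, 1) / 6
  expect_equal(which.max(h) - 1, round(tg[which.max(hg)]))
  expect_gte(tg[which.max(hg)], 4); expect_lte(tg[which.max(hg)], 7)
  expect_error(canonical_hrf(length_s = 10), ">= 21")
  expect_error(canonical_hrf(peak_s = -1), "positive")
})

test_that("design regressors are shifted convolutions and superpose", {
  h <- canonical_hrf()
  tr1 <- data.frame(onset = 10, condition = 1, run = 1)
  X1 <- build_design(tr1, 120, h)
  expect_equal(colnames(X1), c("intercept", paste0("cond", 0:4)))
  expect_true(all(X1[, "cond0"] == 0))             # no control trials
  # direct discrete convolution oracle
  box <- numeric(120); box[10:30] <- 1
  conv <- numeric(120)
  for (t in 1:120) for (k in 1:t)
    if (t - k + 1 <= length(h)) conv[t] <- conv[t] + box[k] * h[t - k + 1]
  expect_equal(unname(X1[, "cond1"]), conv, tolerance = 1e-9)
  # linearity: two distant trials = sum of shifted copies
  tr2 <- data.frame(onset = c(10, 70), condition = 1, run = 1)
  X2 <- build_design(tr2, 150, h)
  Xa <- build_design(data.frame(onset = 10, condition = 1, run = 1), 150, h)
  Xb <- build_design(data.frame(onset = 70, condition = 1, run = 1), 150, h)
  expect_equal(X2[, "cond1"], Xa[, "cond1"] + Xb[, "cond1"], tolerance = 1e-9)
})

test_that("GLM fit equals the normal equations and flags rank deficiency", {
  h <- canonical_hrf()
  tr <- data.frame(onset = c(5, 40, 80), condition = c(1, 2, 1), run = 1)
  X <- build_design(tr, 110, h, conditions = 1:2)
  y <- 2 * X[, "cond1"] + 0.5 * X[, "cond2"] + 3
  b <- fit_glm(matrix(y, 1), X)
  expect_equal(unname(b[1, ]), c(3, 2, 0.5), tolerance = 1e-9)
  # series orthogonal to the task regressors
  b0 <- fit_glm(matrix(1, 1, 110), X)
  expect_equal(unname(b0[1, ]), c(1, 0, 0), tolerance = 1e-9)
  # 3-frame toy system against hand-solved normal equations
  Xt <- cbind(intercept = 1, x = c(0, 1, 2))
  yt <- c(1, 3, 4)
  # betas = (X'X)^-1 X'y
  bt <- solve(t(Xt) %*% Xt, t(Xt) %*% yt)
  expect_equal(unname(fit_glm(matrix(yt, 1), Xt)[1, ]), as.numeric(bt))
  # duplicated column: rank deficiency names the culprit
  Xd <- cbind(Xt, x2 = Xt[, "x"])
  expect_error(fit_glm(matrix(yt, 1), Xd), "x2")
})

test_that("adjacent contrasts are null on identical betas and calibrated on noise", {
  L <- 30
  adj <- matrix(FALSE, L, L)
  for (i in seq_len(L - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  # identical betas across conditions: all t = 0
  b <- array(rep(rnorm(8 * L), 5), c(8, 5, L))
  for (cc in 2:5) b[, cc, ] <- b[, 1, ]
  res <- adjacent_contrasts(b, adj, n_perm = 50, seed = 1)
  expect_length(res, 4)
  for (cc in 1:4) {
    expect_true(all(res[[cc]]$stat$t == 0))
    expect_length(res[[cc]]$clusters, 0)
  }
  # betas equal to load for every subject: differences constant 1, degenerate
  bl <- array(0, c(6, 5, L))
  for (cc in 1:5) bl[, cc, ] <- cc - 1
  resl <- adjacent_contrasts(bl, adj, n_perm = 20, seed = 1)
  expect_true(all(resl[[1]]$stat$degenerate))
  # null calibration: cluster-wise false positives at most ~5%
  set.seed(18)
  fp <- replicate(40, {
    bn <- array(rnorm(8 * 5 * L), c(8, 5, L))
    rn <- adjacent_contrasts(bn, adj, n_perm = 60, seed = sample.int(1e6, 1))
    any(vapply(rn, function(r) length(r$clusters) > 0, logical(1)))
  })
  # 4 contrasts x 5% each, so a small familywise rate is expected; bound it
  expect_lte(mean(fp), 0.35)
})

test_that("response curves subtract control and zero the baseline", {
  cfg <- tiny_sim_config()
  trials <- make_paradigm(cfg)
  L <- 5
  nf <- surfmvpa:::run_length(cfg, max(table(trials$run)))
  # constant series: condition equals control, curve identically zero
  runs <- lapply(1:3, function(r) matrix(7, L, nf))
  names(runs) <- 1:3
  rc <- response_curves(runs, trials, condition = 2)
  expect_equal(dim(rc), c(L, 21))
  expect_true(all(rc == 0))
  # condition adds a constant 3 from onset onward: flat curve at 3
  runs3 <- lapply(1:3, function(r) {
    m <- matrix(0, L, nf)
    tr <- trials[trials$run == r & trials$condition == 2, ]
    for (o in tr$onset) m[, o:(o + 20)] <- m[, o:(o + 20)] + 3
    m
  })
  names(runs3) <- 1:3
  rc3 <- response_curves(runs3, trials, condition = 2)
  expect_equal(unname(rc3), matrix(3, L, 21))
  # oracle: literal mean/subtract/shift transcription on random data
  set.seed(19)
  runsr <- lapply(1:3, function(r) matrix(rnorm(L * nf), L, nf))
  names(runsr) <- 1:3
  rcr <- response_curves(runsr, trials, condition = 1)
  win <- function(cond) {
    rows <- which(trials$condition == cond)
    acc <- 0
    for (i in rows) {
      m <- runsr[[as.character(trials$run[i])]]
      acc <- acc + m[, (trials$onset[i] - 1):(trials$onset[i] + 20)]
    }
    acc / length(rows)
  }
  d <- win(1) - win(0)
  expect_equal(unname(rcr), unname((d - d[, 1])[, -1]))
  # invariance to adding a constant to the whole series
  runsc <- lapply(runsr, function(m) m + 42)
  names(runsc) <- 1:3
  expect_equal(response_curves(runsc, trials, 1), rcr)
  expect_error(response_curves(runsr, trials[trials$condition != 0, ], 1),
               "control")
})

test_that("curve amplitude is the sample mean (or the signed peak)", {
  expect_equal(curve_amplitude(rep(0, 21)), 0)
  expect_equal(curve_amplitude(rep(3, 21)), 3)
  expect_equal(curve_amplitude(0:20), 10)
  expect_equal(curve_amplitude(c(rep(0, 20), -5), type = "peak"), -5)
  m <- rbind(0:20, rep(2, 21))
  expect_equal(unname(curve_amplitude(m)), c(10, 2))
})

test_that("amplitude load map is null-calibrated and recovers injected slopes", {
  L <- 40
  adj <- matrix(FALSE, L, L)
  for (i in seq_len(L - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  # constant amplitudes: empty result
  res0 <- amplitude_load_map(array(5, c(6, 4, L)), adj)
  expect_length(res0$clusters, 0)
  # null: rarely any surviving cluster
  set.seed(20)
  fp <- replicate(50, {
    a <- array(rnorm(12 * 4 * L), c(12, 4, L))
    length(amplitude_load_map(a, adj)$clusters) > 0
  })
  expect_gte(mean(!fp), 0.9)
  # injected slope 0.5 in a 15-label block: recovered with small bias
  region <- 10:24
  reps <- replicate(10, {
    a <- array(rnorm(20 * 4 * L, 0, 0.3), c(20, 4, L))
    for (s in 1:20) for (cond in 1:4)
      a[s, cond, region] <- a[s, cond, region] + 0.5 * cond
    r <- amplitude_load_map(a, adj)
    rec <- sort(unique(unlist(lapply(r$clusters, `[[`, "labels"))))
    c(jac = length(intersect(rec, region)) / length(union(rec, region)),
      slope = mean(r$stat$mean[region]))
  })
  expect_gte(median(reps["jac", ]), 0.8)
  expect_lt(abs(median(reps["slope", ]) - 0.5), 0.1)
})
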