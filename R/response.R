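#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF: a positive gamma density peaking around 5-6 s
#' minus a later, smaller gamma undershoot, sampled at the frame period and
#' normalized so the peak equals 1. Defaults are the widely used parameters
#' (response peak 6 s, undershoot peak 16 s, unit dispersions, peak:undershoot
#' ratio 6).
#'
#' @param length_s duration to sample, in seconds (>= 21).
#' @param frame_period_s sampling interval in seconds (1 s for the reference
#'   acquisition).
#' @param peak_s time-to-peak of the response gamma (shape = peak / dispersion).
#' @param undershoot_s time-to-peak of the undershoot gamma.
#' @param dispersion_s dispersion (scale) of the response gamma.
#' @param u_dispersion_s dispersion of the undershoot gamma.
#' @param ratio peak-to-undershoot amplitude ratio (undershoot weight 1/ratio).
#' @return numeric vector sampled at t = 0, frame_period, ..., peak value 1.
#' @export
canonical_hrf <- function(length_s = 32, frame_period_s = 1, peak_s = 6,
                          undershoot_s = 16, dispersion_s = 1,
                          u_dispersion_s = 1, ratio = 6) {
  if (length_s < 21) stop_arg("length_s must be >= 21")
  if (peak_s <= 0 || undershoot_s <= 0 || dispersion_s <= 0 ||
      u_dispersion_s <= 0 || ratio <= 0)
    stop_arg("HRF parameters must be positive")
  t <- seq(0, length_s, by = frame_period_s)
  h <- stats::dgamma(t, shape = peak_s / dispersion_s, scale = dispersion_s) -
    stats::dgamma(t, shape = undershoot_s / u_dispersion_s,
                  scale = u_dispersion_s) / ratio
  h / max(h)
}

#' Build a GLM design matrix from a trial table
#'
#' For each condition, the regressor is a boxcar starting at each trial onset
#' with the given duration (21 s in the reference analysis), convolved with
#' the HRF and truncated to the run length. Overlapping boxcars of the same
#' condition sum. An intercept column is always included.
#'
#' @param trials trial table (columns onset, condition, run) for one run.
#' @param n_frames run length in frames.
#' @param hrf sampled HRF (e.g. [canonical_hrf()]).
#' @param duration boxcar duration in frames (seconds at 1-s frames).
#' @param conditions conditions to model (default 0:4; conditions absent from
#'   the run get an all-zero column).
#' @return numeric matrix n_frames x (1 + length(conditions)), columns
#'   `intercept`, `cond<k>`.
#' @export
build_design <- function(trials, n_frames, hrf = canonical_hrf(),
                         duration = 21, conditions = 0:4) {
  trials <- check_trials(trials)
  if (any(trials$onset < 1 | trials$onset > n_frames))
    stop_arg("trial onsets outside run (1..%d)", n_frames)
  X <- matrix(0, n_frames, length(conditions),
              dimnames = list(NULL, paste0("cond", conditions)))
  for (j in seq_along(conditions)) {
    onsets <- trials$onset[trials$condition == conditions[j]]
    if (!length(onsets)) next
    box <- numeric(n_frames)
    for (o in onsets) {
      to <- min(o + duration - 1L, n_frames)
      box[o:to] <- box[o:to] + 1
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_frames)]
    X[, j] <- conv
  }
  cbind(intercept = 1, X)
}

#' Ordinary least squares GLM fit, label-wise
#'
#' Solves the normal equations once per run and returns the per-label
#' regression coefficients. The design must be full rank; an informative error
#' names the collinear columns otherwise.
#'
#' @param series labels x frames matrix.
#' @param design frames x regressors matrix (see [build_design()]).
#' @return coefficients matrix, labels x regressors.
#' @export
fit_glm <- function(series, design) {
  series <- as.matrix(series)
  design <- as.matrix(design)
  if (ncol(series) != nrow(design))
    stop_arg("series has %d frames but design has %d rows", ncol(series),
             nrow(design))
  qr_ <- qr(design)
  if (qr_$rank < ncol(design)) {
    bad <- colnames(design)[qr_$pivot[(qr_$rank + 1):ncol(design)]]
    stop_arg("design is rank deficient; collinear column(s): %s",
             paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_, t(series))
  out <- t(beta)
  colnames(out) <- colnames(design)
  out
}

#' Condition betas across runs for one subject
#'
#' Fits the GLM per run and averages the condition coefficients over runs.
#'
#' @param series_runs list of labels x frames matrices.
#' @param trials full trial table (column `run` selects rows per run).
#' @param hrf sampled HRF.
#' @param duration boxcar duration in frames.
#' @param conditions conditions to model.
#' @return matrix labels x conditions of mean betas.
#' @export
condition_betas <- function(series_runs, trials, hrf = canonical_hrf(),
                            duration = 21, conditions = 0:4) {
  if (is.null(names(series_runs)))
    names(series_runs) <- as.character(seq_along(series_runs))
  trials <- check_trials(trials, series_runs)
  acc <- 0
  for (r in names(series_runs)) {
    tr <- trials[as.character(trials$run) == r, , drop = FALSE]
    X <- build_design(tr, ncol(series_runs[[r]]), hrf, duration, conditions)
    # a condition absent from this run yields a zero column; drop it from the
    # fit and impute a zero beta so runs stay comparable
    zero <- apply(X, 2, function(c) all(c == 0))
    b <- fit_glm(series_runs[[r]], X[, !zero, drop = FALSE])
    full <- matrix(0, nrow(b), ncol(X), dimnames = list(NULL, colnames(X)))
    full[, !zero] <- b
    acc <- acc + full[, -1, drop = FALSE]
  }
  acc / length(series_runs)
}

#' Adjacent-condition contrasts of GLM betas
#'
#' For each pair of adjacent conditions (c, c+1) the per-subject beta
#' difference maps are tested against zero with a paired t-test across
#' subjects, thresholded element-wise at `p_elem`, clustered on the adjacency,
#' and cluster sizes are calibrated cluster-wise at `cluster_p` by sign-flip
#' permutation of the subject difference maps (max-cluster-size null).
#'
#' @param betas array subjects x conditions x labels (conditions ordered
#'   0,1,2,3,4).
#' @param adjacency label adjacency matrix.
#' @param areas per-label areas (mm^2).
#' @param p_elem element-wise threshold (0.01).
#' @param cluster_p cluster-wise threshold (0.05).
#' @param n_perm number of sign-flip permutations.
#' @param seed RNG seed for the permutations.
#' @return list per contrast: `stat` (a `stat_map`), `clusters` (surviving
#'   `cluster_set`), `cluster_size_threshold`.
#' @export
adjacent_contrasts <- function(betas, adjacency, areas = NULL, p_elem = 0.01,
                               cluster_p = 0.05, n_perm = 500, seed = NULL) {
  d <- dim(betas)
  if (length(d) != 3) stop_arg("betas must be subjects x conditions x labels")
  if (d[1] < 2) stop_arg("need at least 2 subjects")
  out <- vector("list", d[2] - 1)
  with_seed(seed, {
    for (cc in seq_len(d[2] - 1)) {
      diffs <- matrix(betas[, cc + 1, ] - betas[, cc, ], d[1], d[3])
      st <- paired_t(diffs)
      mask <- st$p < p_elem
      mask[is.na(mask)] <- FALSE
      cl <- extract_clusters(mask, adjacency, stat = st$t, areas = areas)
      # sign-flip null of the maximum cluster size
      maxsz <- integer(n_perm)
      for (k in seq_len(n_perm)) {
        flip <- sample(c(-1, 1), d[1], replace = TRUE)
        stp <- paired_t(diffs * flip)
        mk <- stp$p < p_elem
        mk[is.na(mk)] <- FALSE
        clp <- extract_clusters(mk, adjacency)
        maxsz[k] <- if (length(clp))
          max(vapply(clp, `[[`, integer(1), "size")) else 0L
      }
      thr <- stats::quantile(maxsz, 1 - cluster_p, type = 1)
      keep <- vapply(cl, function(c) c$size > thr, logical(1))
      out[[cc]] <- list(stat = st,
                        clusters = structure(unclass(cl)[keep],
                                             class = "cluster_set"),
                        cluster_size_threshold = as.numeric(thr))
    }
  })
  names(out) <- paste0("c", seq_len(d[2] - 1) - 1, "_vs_c", seq_len(d[2] - 1))
  out
}

# two-sided one-sample t of difference maps (subjects x labels)
paired_t <- function(diffs) {
  n <- nrow(diffs)
  mu <- colMeans(diffs)
  sd <- apply(diffs, 2, stats::sd)
  t <- mu / (sd / sqrt(n))
  p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  degen <- sd == 0
  t[degen & mu == 0] <- 0
  p[degen & mu == 0] <- 1
  p[degen & mu != 0] <- 0
  t[degen & mu != 0] <- sign(mu[degen & mu != 0]) * Inf
  structure(list(t = t, p = p, mean = mu, degenerate = degen & mu != 0),
            class = "stat_map")
}

#' Control-subtracted, baseline-zeroed response curves
#'
#' For one subject: averages the raw BOLD over all trials of a condition in a
#' window from one frame before onset to 20 frames after (22 samples), does
#' the same for the control condition, subtracts the control average, then
#' shifts the difference so the pre-onset (baseline) sample is zero. The 21
#' post-onset samples (seconds 0..20) are returned.
#'
#' @param series_runs list of labels x frames matrices.
#' @param trials trial table; onsets must leave one pre-onset frame.
#' @param condition condition whose curve is wanted (1-4).
#' @param control control condition id (default 0).
#' @return matrix labels x 21.
#' @export
response_curves <- function(series_runs, trials, condition, control = 0L) {
  if (is.null(names(series_runs)))
    names(series_runs) <- as.character(seq_along(series_runs))
  trials <- check_trials(trials, series_runs)
  if (!any(trials$condition == condition))
    stop_arg("no trials of condition %d", condition)
  if (!any(trials$condition == control))
    stop_arg("no trials of the control condition (%d)", control)
  avg_window <- function(cond) {
    rows <- which(trials$condition == cond)
    acc <- 0
    for (i in rows) {
      m <- series_runs[[as.character(trials$run[i])]]
      o <- trials$onset[i]
      if (o < 2 || o + 20 > ncol(m))
        stop_arg("trial window [onset-1, onset+20] outside run for onset %d", o)
      acc <- acc + m[, (o - 1):(o + 20), drop = FALSE]
    }
    acc / length(rows)
  }
  diffm <- avg_window(condition) - avg_window(control)
  curve <- diffm - diffm[, 1]          # baseline sample (onset - 1 s) to zero
  curve[, -1, drop = FALSE]            # 21 post-onset samples
}

#' Mean amplitude of a response curve
#'
#' The arithmetic mean of the 21 samples; `"peak"` returns the maximum
#' absolute value instead.
#'
#' @param curve numeric vector of 21 samples, or a labels x 21 matrix (then a
#'   vector of per-label amplitudes is returned).
#' @param type `"mean"` or `"peak"`.
#' @return amplitude(s), a.u.
#' @export
curve_amplitude <- function(curve, type = c("mean", "peak")) {
  type <- match.arg(type)
  f <- if (type == "mean") mean else function(x) x[which.max(abs(x))]
  if (is.matrix(curve)) apply(curve, 1, f) else f(curve)
}

#' Load regression of response amplitudes
#'
#' Per-subject, per-label mean response amplitudes under loads 1-4 are
#' regressed on load ([group_slope_test()]); labels with two-sided p below
#' `p_thresh` are clustered and clusters with strictly more than
#' `min_cluster_labels` labels survive. No FDR step, matching the reference
#' criterion for this analysis.
#'
#' @param amplitudes array subjects x loads (4) x labels.
#' @param adjacency label adjacency matrix.
#' @param areas per-label areas (mm^2).
#' @param loads load levels (default 1:4).
#' @param p_thresh significance level (0.05).
#' @param min_cluster_labels cluster-size threshold, strict (10).
#' @return list with `stat` (a `stat_map` of slopes) and `clusters`
#'   (a `cluster_set`).
#' @export
amplitude_load_map <- function(amplitudes, adjacency, areas = NULL,
                               loads = 1:4, p_thresh = 0.05,
                               min_cluster_labels = 10) {
  st <- group_slope_test(amplitudes, loads = loads)
  cl <- significant_map(list(p = matrix(st$p, ncol = 1),
                             t = matrix(st$t, ncol = 1)),
                        adjacency, areas, p_thresh = p_thresh, fdr_q = NULL,
                        min_cluster_labels = min_cluster_labels)[[1]]
  list(stat = st, clusters = cl)
}
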