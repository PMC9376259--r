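#' Build surface searchlights
#'
#' For each label, the searchlight is the set of labels whose centre lies
#' strictly inside a sphere of the given radius around that label's centre.
#' The central label itself (distance 0) is always a member, and membership is
#' symmetric because a single radius is used.
#'
#' @param centers numeric matrix labels x 3 of final label centres (mm).
#' @param radius searchlight radius in mm (10 mm in the reference analysis).
#' @return list of integer vectors (member label ids per central label), class
#'   `searchlight_map`, with the radius in attribute `"radius"`.
#' @export
build_searchlights <- function(centers, radius = 10) {
  if (radius <= 0) stop_arg("radius must be > 0")
  centers <- as_coord_matrix(centers, "centers")
  L <- nrow(centers)
  out <- vector("list", L)
  chunk <- 1024L
  for (s in seq(1L, L, by = chunk)) {
    e <- min(s + chunk - 1L, L)
    d <- sqrt(cross_dist2(centers[s:e, , drop = FALSE], centers))
    for (i in s:e) out[[i]] <- which(d[i - s + 1L, ] < radius)
  }
  structure(out, radius = radius, class = "searchlight_map")
}

#' Frame-wise decoding instances from a label series
#'
#' One instance per trial; the feature vector is the label-space BOLD at frame
#' `onset + frame_offset`. Two labelling schemes are supported: `"task"`
#' collapses conditions 1-4 into a single task class against the control class
#' (condition 0), `"load"` keeps conditions 1-4 as four classes and drops
#' control trials.
#'
#' @param series_runs list of labels x frames matrices, one per run (run ids
#'   must match `trials$run`).
#' @param trials data frame with columns `onset` (1-based frame of stimulus
#'   onset), `condition` (0-4, 0 = control) and `run`.
#' @param frame_offset integer in 0..20.
#' @param scheme `"task"` or `"load"`.
#' @return list with `x` (instances x labels matrix), `y` (factor of class
#'   labels) and `run` (run id per instance).
#' @export
extract_frame_features <- function(series_runs, trials, frame_offset,
                                   scheme = c("task", "load")) {
  scheme <- match.arg(scheme)
  if (frame_offset < 0 || frame_offset > 20)
    stop_arg("frame_offset must be in 0..20")
  if (is.null(names(series_runs)))
    names(series_runs) <- as.character(seq_along(series_runs))
  trials <- check_trials(trials, series_runs)
  keep <- if (scheme == "load") trials$condition != 0L else rep(TRUE, nrow(trials))
  trials <- trials[keep, , drop = FALSE]
  run_ids <- names(series_runs)
  x <- t(vapply(seq_len(nrow(trials)), function(i) {
    m <- series_runs[[as.character(trials$run[i])]]
    fr <- trials$onset[i] + frame_offset
    if (fr > ncol(m)) stop_arg("frame %d beyond run end (%d frames)", fr, ncol(m))
    m[, fr]
  }, numeric(nrow(series_runs[[1]]))))
  y <- if (scheme == "task") factor(ifelse(trials$condition == 0L, "control", "task"))
       else factor(trials$condition)
  list(x = x, y = y, run = trials$run)
}

check_trials <- function(trials, series_runs = NULL) {
  need <- c("onset", "condition", "run")
  if (!all(need %in% names(trials)))
    stop_arg("trial table needs columns: %s", paste(need, collapse = ", "))
  trials$onset <- as.integer(trials$onset)
  trials$condition <- as.integer(trials$condition)
  if (any(trials$condition < 0L | trials$condition > 4L))
    stop_arg("conditions must be in 0..4")
  if (!is.null(series_runs)) {
    if (is.null(names(series_runs)))
      names(series_runs) <- as.character(seq_along(series_runs))
    miss <- setdiff(as.character(unique(trials$run)), names(series_runs))
    if (length(miss)) stop_arg("runs missing from series: %s",
                               paste(miss, collapse = ", "))
  }
  trials
}

#' Balance instances against the control class
#'
#' Task trials outnumber control trials four to one in the reference paradigm,
#' which biases classifiers towards the large class. To balance, all control
#' instances are retained and each load condition is randomly downsampled to
#' `floor(n_control / 4)` instances, so the two classes end up equal in size.
#'
#' @param conditions integer vector of per-instance conditions (0 = control).
#' @param seed RNG seed; identical seeds give identical subsets.
#' @return sorted integer vector of retained instance indices.
#' @export
balance_instances <- function(conditions, seed = NULL) {
  conditions <- as.integer(conditions)
  ctrl <- which(conditions == 0L)
  if (!length(ctrl)) stop_arg("no control instances to balance against")
  per_load <- length(ctrl) %/% 4L
  keep <- ctrl
  with_seed(seed, {
    for (cond in 1:4) {
      avail <- which(conditions == cond)
      if (length(avail) < per_load)
        stop_arg("condition %d has %d instances, %d required", cond,
                 length(avail), per_load)
      keep <- c(keep, if (per_load > 0) sample(avail, per_load) else integer(0))
    }
  })
  sort(keep)
}

# z-score columns of train by train statistics; apply to test. Constant
# features are mapped to 0 in both (no information, no NaN).
zscore_fold <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- Inf
  list(train = sweep(sweep(train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(test, 2, mu), 2, sd, "/"))
}

#' Leave-one-run-out cross-validated multiclass decoding
#'
#' Splits instances by run: each fold trains on all other runs and tests on
#' the held-out run (threefold with the reference 3-run paradigm). Features
#' are z-scored per feature using training-fold statistics only, then a
#' multiclass model of one-vs-one linear support vector machines (C = 1) with
#' majority-vote decoding classifies the held-out run. Fold accuracies are
#' averaged.
#'
#' @param x instances x features matrix.
#' @param y class labels (factor or coercible).
#' @param run run id per instance; at least 2 distinct runs.
#' @return mean test accuracy over usable folds, in \[0, 1\].
#' @export
train_classify_cv <- function(x, y, run) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop_arg("need at least 2 classes")
  runs <- unique(run)
  if (length(runs) < 2) stop_arg("need at least 2 distinct runs for cross-validation")
  accs <- numeric(0)
  for (r in runs) {
    te <- run == r
    ytr <- droplevels(y[!te])
    if (nlevels(ytr) < nlevels(y)) {
      warning(sprintf("fold %s skipped: training set missing a class", r))
      next
    }
    z <- zscore_fold(x[!te, , drop = FALSE], x[te, , drop = FALSE])
    fit <- e1071::svm(z$train, ytr, kernel = "linear", cost = 1, scale = FALSE)
    pred <- stats::predict(fit, z$test)
    accs <- c(accs, mean(as.character(pred) == as.character(y[te])))
  }
  if (!length(accs)) stop_arg("all folds skipped: no usable training split")
  mean(accs)
}

#' Frame-by-frame searchlight decoding map
#'
#' For every label and frame offset, the features are the current values of
#' the labels in that label's searchlight, and the score is the leave-one-run-
#' out cross-validated decoding accuracy. With `scheme = "task"` instances are
#' balanced once per call (one random subset, reused across all labels and
#' frames so the map is comparable over the surface); with `scheme = "load"`
#' control trials are excluded and no balancing is applied.
#'
#' @param series_runs list of labels x frames matrices, one per run.
#' @param trials trial table (see [extract_frame_features()]).
#' @param searchlights a `searchlight_map`.
#' @param scheme `"task"` (chance 0.5) or `"load"` (chance 0.25).
#' @param seed RNG seed for the balancing subset.
#' @param frames integer vector of frame offsets to decode (default 0..20).
#' @param labels integer vector of central labels to decode (default all).
#' @return matrix labels x frames of accuracies, with attributes `"chance"`
#'   and `"frames"`; undecoded cells are `NA`.
#' @export
searchlight_decode_map <- function(series_runs, trials, searchlights,
                                   scheme = c("task", "load"), seed = NULL,
                                   frames = 0:20, labels = NULL) {
  scheme <- match.arg(scheme)
  L <- length(searchlights)
  if (is.null(labels)) labels <- seq_len(L)
  out <- matrix(NA_real_, L, length(frames),
                dimnames = list(NULL, paste0("frame", frames)))
  # one balancing subset per call: instance order under scheme = "task" is the
  # trial-table order, so the subset is drawn from the raw conditions
  keep <- if (scheme == "task")
    balance_instances(check_trials(trials)$condition, seed = seed) else NULL
  for (j in seq_along(frames)) {
    inst <- extract_frame_features(series_runs, trials, frames[j], scheme)
    if (!is.null(keep)) {
      inst$x <- inst$x[keep, , drop = FALSE]
      inst$y <- droplevels(inst$y[keep])
      inst$run <- inst$run[keep]
    }
    for (l in labels) {
      feats <- inst$x[, searchlights[[l]], drop = FALSE]
      out[l, j] <- train_classify_cv(feats, inst$y, inst$run)
    }
  }
  structure(out, chance = if (scheme == "task") 0.5 else 0.25, frames = frames)
}
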