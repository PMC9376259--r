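#' Region-of-interest specification
#'
#' An ROI is anchored at a seed label; its time course is averaged over the
#' seed and (by default) the labels adjacent to it. A coordinate may be given
#' instead of a label id, in which case it is snapped to the nearest final
#' label centre in the supplied template space -- any stereotaxic conversion
#' to that space is the caller's responsibility.
#'
#' @param name ROI name (free text).
#' @param seed_label 1-based label id, or `NULL` when `coord` is given.
#' @param coord optional length-3 coordinate (mm) snapped to the nearest label
#'   centre.
#' @param centers label centres (needed with `coord`).
#' @param include_adjacent average the adjacent labels into the ROI curve.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, seed_label = NULL, coord = NULL, centers = NULL,
                     include_adjacent = TRUE) {
  if (is.null(seed_label)) {
    if (is.null(coord) || is.null(centers))
      stop_arg("give either seed_label or coord + centers")
    d2 <- cross_dist2(matrix(coord, 1, 3), centers)
    seed_label <- which.min(d2[1, ])
  }
  structure(list(name = name, seed_label = as.integer(seed_label),
                 include_adjacent = isTRUE(include_adjacent)),
            class = "roi_spec")
}

#' ROI time course
#'
#' Unweighted mean of the seed label's series and, when the ROI includes its
#' neighbourhood, the series of all labels adjacent to the seed.
#'
#' @param series labels x frames matrix for one run.
#' @param roi an [roi_spec()].
#' @param adjacency label adjacency matrix.
#' @return numeric vector of frames.
#' @export
roi_curve <- function(series, roi, adjacency) {
  if (roi$seed_label > nrow(series))
    stop_arg("seed label %d not in parcellation", roi$seed_label)
  members <- roi$seed_label
  if (roi$include_adjacent)
    members <- c(members, which(adjacency[roi$seed_label, ]))
  colMeans(series[members, , drop = FALSE])
}

#' Trial-wise connectivity of one ROI with every label
#'
#' Pearson correlation between the ROI curve and each label's curve over the
#' 21-frame window starting at the trial onset. Windows with zero variance on
#' either side yield `NA` (excluded from later averaging rather than
#' zero-filled).
#'
#' @param roi_series ROI time course for the trial's run.
#' @param series labels x frames matrix for the same run.
#' @param onset 1-based onset frame.
#' @param window window length in frames (21).
#' @return numeric vector of per-label correlations in \[-1, 1\] (or `NA`).
#' @export
trial_connectivity <- function(roi_series, series, onset, window = 21) {
  to <- onset + window - 1L
  if (onset < 1 || to > ncol(series))
    stop_arg("trial window [%d, %d] outside run (%d frames)", onset, to,
             ncol(series))
  x <- roi_series[onset:to]
  if (stats::sd(x) == 0) return(rep(NA_real_, nrow(series)))
  w <- t(series[, onset:to, drop = FALSE])
  r <- suppressWarnings(as.numeric(stats::cor(x, w)))
  r[!is.finite(r)] <- NA_real_
  r
}

#' Per-condition connectivity maps for one subject
#'
#' Averages the trial-wise ROI-to-label correlations within each memory load
#' (conditions 1-4; control trials never contribute). Undefined per-trial
#' correlations are dropped from the average.
#'
#' @param series_runs list of labels x frames matrices.
#' @param trials trial table.
#' @param roi an [roi_spec()].
#' @param adjacency label adjacency matrix.
#' @param window window length in frames (21).
#' @return matrix loads (4) x labels of mean correlations.
#' @export
condition_connectivity <- function(series_runs, trials, roi, adjacency,
                                   window = 21) {
  if (is.null(names(series_runs)))
    names(series_runs) <- as.character(seq_along(series_runs))
  trials <- check_trials(trials, series_runs)
  L <- nrow(series_runs[[1]])
  roi_by_run <- lapply(series_runs, roi_curve, roi = roi, adjacency = adjacency)
  out <- matrix(NA_real_, 4, L, dimnames = list(paste0("load", 1:4), NULL))
  for (load in 1:4) {
    rows <- which(trials$condition == load)
    if (!length(rows)) stop_arg("no trials of load %d", load)
    rs <- matrix(NA_real_, length(rows), L)
    for (i in seq_along(rows)) {
      run <- as.character(trials$run[rows[i]])
      rs[i, ] <- trial_connectivity(roi_by_run[[run]], series_runs[[run]],
                                    trials$onset[rows[i]], window)
    }
    if (all(is.na(rs)))
      stop_arg("load %d has no usable trials (all windows degenerate)", load)
    out[load, ] <- colMeans(rs, na.rm = TRUE)
  }
  out
}

#' Load regression of connectivity maps
#'
#' Per-subject mean ROI-to-label correlations under loads 1-4 are regressed on
#' load across subjects ([group_slope_test()]); labels significant at
#' `p_thresh` (two-sided, no FDR step) are clustered and clusters with
#' strictly more than `min_cluster_labels` labels survive.
#'
#' @param tensor array subjects x loads (4) x labels of mean correlations.
#' @param adjacency label adjacency matrix.
#' @param areas per-label areas (mm^2).
#' @param loads load levels (default 1:4).
#' @param p_thresh significance level (0.05).
#' @param min_cluster_labels cluster-size threshold, strict (10).
#' @param fisher_z apply the Fisher z transform (atanh) before regression.
#' @return list with `stat` (a `stat_map` of slopes) and `clusters`.
#' @export
connectivity_load_map <- function(tensor, adjacency, areas = NULL, loads = 1:4,
                                  p_thresh = 0.05, min_cluster_labels = 10,
                                  fisher_z = FALSE) {
  if (any(tensor < -1 - 1e-9 | tensor > 1 + 1e-9, na.rm = TRUE))
    stop_arg("correlations must lie in [-1, 1]")
  if (fisher_z) tensor <- atanh(pmin(pmax(tensor, -1 + 1e-12), 1 - 1e-12))
  st <- group_slope_test(tensor, loads = loads)
  cl <- significant_map(list(p = matrix(st$p, ncol = 1),
                             t = matrix(st$t, ncol = 1)),
                        adjacency, areas, p_thresh = p_thresh, fdr_q = NULL,
                        min_cluster_labels = min_cluster_labels)[[1]]
  list(stat = st, clusters = cl)
}
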