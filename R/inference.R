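#' One-sample t-test of accuracy maps against chance
#'
#' Second-level random-effects test: for each label (and frame) the subjects'
#' accuracies are compared to the chance level with a one-sided, one-sample
#' t-test (alternative: mean greater than chance). Degenerate zero-variance
#' cells use conservative conventions: all subjects exactly at chance gives
#' t = 0 and p = 0.5; zero variance strictly above chance gives p = 0 and is
#' flagged; zero variance below chance gives p = 1 and is flagged.
#'
#' @param maps numeric array subjects x labels (x frames).
#' @param chance chance level (0.5 two-class, 0.25 four-class).
#' @return A `stat_map`: list with matrices/vectors `t`, `p`, `mean` (labels x
#'   frames) and logical `degenerate`.
#' @export
ttest_vs_chance <- function(maps, chance) {
  if (length(dim(maps)) == 2L) dim(maps) <- c(dim(maps), 1L)
  n <- dim(maps)[1]
  if (n < 2) stop_arg("need at least 2 subjects")
  mu <- apply(maps, c(2, 3), mean)
  sd <- apply(maps, c(2, 3), stats::sd)
  t <- (mu - chance) / (sd / sqrt(n))
  p <- stats::pt(t, df = n - 1, lower.tail = FALSE)
  degen <- sd == 0
  t[degen & mu == chance] <- 0
  p[degen & mu == chance] <- 0.5
  p[degen & mu > chance] <- 0
  t[degen & mu > chance] <- Inf
  p[degen & mu < chance] <- 1
  t[degen & mu < chance] <- -Inf
  structure(list(t = t, p = p, mean = mu, degenerate = degen & mu != chance),
            class = "stat_map")
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure at level `q` over the supplied family of p values:
#' reject the k smallest p values where k is the largest index with
#' p_(k) <= k * q / m.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @param q FDR level.
#' @return logical vector, `TRUE` where rejected.
#' @export
fdr_mask <- function(p, q) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_arg("p values must be in [0, 1]")
  out <- rep(FALSE, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH") <= q
  out
}

#' Recursive cluster extraction on the label graph
#'
#' Groups the labels passing a statistical mask into connected clusters under
#' the label adjacency: starting from any unclustered masked label, its masked
#' adjacent labels are pulled in, then theirs, until closure -- i.e. the
#' connected components of the masked subgraph (implemented with an explicit
#' stack). Each cluster carries its member set, size in labels, surface area
#' in mm^2 and the peak label (largest |statistic|).
#'
#' @param mask logical vector over labels.
#' @param adjacency logical labels x labels adjacency matrix.
#' @param stat numeric statistic per label (for the peak); defaults to zeros.
#' @param areas label areas in mm^2; defaults to zeros.
#' @return A `cluster_set`: list of clusters, each with `labels`, `size`,
#'   `area_mm2`, `peak_label`, `peak_stat`.
#' @export
extract_clusters <- function(mask, adjacency, stat = NULL, areas = NULL) {
  L <- length(mask)
  if (nrow(adjacency) != L) stop_arg("mask and adjacency sizes differ")
  stat <- stat %||% numeric(L)
  areas <- areas %||% numeric(L)
  visited <- rep(FALSE, L)
  clusters <- list()
  for (start in which(mask)) {
    if (visited[start]) next
    members <- integer(0)
    stack <- start
    visited[start] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      nb <- which(adjacency[cur, ] & mask & !visited)
      visited[nb] <- TRUE
      stack <- c(stack, nb)
    }
    members <- sort(members)
    peak <- members[which.max(abs(stat[members]))]
    clusters[[length(clusters) + 1L]] <-
      list(labels = members, size = length(members),
           area_mm2 = sum(areas[members]), peak_label = peak,
           peak_stat = stat[peak])
  }
  structure(clusters, class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  #%d: %d labels, %.1f mm^2, peak label %d (stat %.3f)\n",
                i, x[[i]]$size, x[[i]]$area_mm2, x[[i]]$peak_label,
                x[[i]]$peak_stat))
  invisible(x)
}

#' Summarise a cluster set as a data frame
#'
#' Mirrors a typical cluster report: one row per cluster with the peak
#' statistic as -log10(p) when p values are supplied.
#'
#' @param clusters a `cluster_set`.
#' @param p optional per-label p values (for the -log10 peak column).
#' @param centers optional label centres for peak coordinates.
#' @return data frame with columns cluster, n_labels, area_mm2, peak_label,
#'   peak_stat, and optionally neg_log10_p, peak_x/y/z.
#' @export
cluster_report <- function(clusters, p = NULL, centers = NULL) {
  if (!length(clusters))
    return(data.frame(cluster = integer(0), n_labels = integer(0),
                      area_mm2 = numeric(0), peak_label = integer(0),
                      peak_stat = numeric(0)))
  df <- data.frame(
    cluster = seq_along(clusters),
    n_labels = vapply(clusters, `[[`, integer(1), "size"),
    area_mm2 = vapply(clusters, `[[`, numeric(1), "area_mm2"),
    peak_label = vapply(clusters, `[[`, integer(1), "peak_label"),
    peak_stat = vapply(clusters, `[[`, numeric(1), "peak_stat"))
  if (!is.null(p)) df$neg_log10_p <- -log10(pmax(p[df$peak_label], 1e-300))
  if (!is.null(centers)) {
    df$peak_x <- centers[df$peak_label, 1]
    df$peak_y <- centers[df$peak_label, 2]
    df$peak_z <- centers[df$peak_label, 3]
  }
  df
}

#' Thresholded significance clusters per frame
#'
#' Applies the full decoding-map criterion: a label survives when its
#' uncorrected p value is below `p_thresh` and it is rejected by the
#' Benjamini-Hochberg procedure at level `fdr_q` (family = the labels of one
#' frame), then surviving labels are clustered on the adjacency and only
#' clusters with strictly more than `min_cluster_labels` labels are kept.
#'
#' @param stat a `stat_map` from [ttest_vs_chance()] (labels x frames).
#' @param adjacency logical label adjacency matrix.
#' @param areas per-label areas (mm^2).
#' @param p_thresh uncorrected per-label threshold (1e-4 in the reference
#'   decoding analysis).
#' @param fdr_q FDR level (0.01). Set `NULL` to skip FDR (as in the load
#'   regression criteria).
#' @param min_cluster_labels minimum cluster size, strict (> 10).
#' @param fdr_family `"frame"` (default) or `"all"` (one family across every
#'   frame).
#' @return list of `cluster_set`, one per frame.
#' @export
significant_map <- function(stat, adjacency, areas = NULL, p_thresh = 1e-4,
                            fdr_q = 0.01, min_cluster_labels = 10,
                            fdr_family = c("frame", "all")) {
  fdr_family <- match.arg(fdr_family)
  p <- as.matrix(stat$p)
  t <- as.matrix(stat$t)
  fdr <- if (is.null(fdr_q)) {
    matrix(TRUE, nrow(p), ncol(p))
  } else if (fdr_family == "all") {
    matrix(fdr_mask(as.numeric(p), fdr_q), nrow(p), ncol(p))
  } else {
    matrix(apply(p, 2, fdr_mask, q = fdr_q), nrow(p), ncol(p))
  }
  out <- vector("list", ncol(p))
  for (f in seq_len(ncol(p))) {
    mask <- (p[, f] < p_thresh) & fdr[, f]
    mask[is.na(mask)] <- FALSE
    cl <- extract_clusters(mask, adjacency, stat = t[, f], areas = areas)
    keep <- vapply(cl, function(c) c$size > min_cluster_labels, logical(1))
    out[[f]] <- structure(unclass(cl)[keep], class = "cluster_set")
  }
  out
}

#' Group-level load-slope test
#'
#' Random-effects regression of a per-label quantity on memory load: each
#' subject contributes an ordinary-least-squares slope of the quantity on the
#' load levels, and the slopes are tested against zero across subjects with a
#' two-sided one-sample t-test. If every subject's slope is exactly zero the
#' cell is degenerate and reported with p = 1; zero variance around a nonzero
#' mean is flagged with p = 0.
#'
#' @param values numeric array subjects x conditions x labels.
#' @param loads numeric predictor per condition (default 1:4).
#' @param method `"per-subject"` (random effects, default) or `"pooled"`
#'   (single OLS over all subject-condition points per label).
#' @return A `stat_map` with per-label `t`, `p`, `mean` (mean slope) and
#'   `degenerate`.
#' @export
group_slope_test <- function(values, loads = seq_len(dim(values)[2]),
                             method = c("per-subject", "pooled")) {
  method <- match.arg(method)
  d <- dim(values)
  if (length(d) != 3) stop_arg("values must be subjects x conditions x labels")
  if (d[1] < 2) stop_arg("need at least 2 subjects")
  if (length(loads) != d[2]) stop_arg("loads length must match conditions")
  lc <- loads - mean(loads)
  ss <- sum(lc^2)
  if (ss == 0) stop_arg("need at least 2 distinct load levels")
  if (method == "pooled") {
    x <- rep(lc, each = d[1])
    t <- p <- mu <- numeric(d[3])
    for (l in seq_len(d[3])) {
      fit <- stats::lm(as.numeric(values[, , l]) ~ x)
      s <- summary(fit)$coefficients
      mu[l] <- s["x", "Estimate"]; t[l] <- s["x", "t value"]
      p[l] <- s["x", "Pr(>|t|)"]
    }
    return(structure(list(t = t, p = p, mean = mu,
                          degenerate = rep(FALSE, d[3])), class = "stat_map"))
  }
  # per-subject OLS slope, vectorised over labels: slope = sum(lc * y) / ss
  slopes <- matrix(0, d[1], d[3])
  for (s in seq_len(d[1]))
    slopes[s, ] <- colSums(matrix(values[s, , ], d[2], d[3]) * lc) / ss
  n <- d[1]
  mu <- colMeans(slopes)
  sd <- apply(slopes, 2, stats::sd)
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
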