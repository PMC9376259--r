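# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
as_coord_matrix <- function(x, what = "coordinates") {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop_arg("%s must have 3 columns, got %d", what, ncol(x))
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop_arg("%s contain non-finite values", what)
  x
}

# Uniform-grid spatial index over 3-D points; cells of side `cell`.
# Supports exact radius queries: candidates come from the 27 surrounding
# cells, then true Euclidean distances are checked, so results match brute
# force exactly.
grid_index <- function(points, cell) {
  stopifnot(cell > 0)
  key <- grid_key(points, cell)
  list(points = points, cell = cell,
       buckets = split(seq_len(nrow(points)), key))
}

grid_key <- function(points, cell, offset = c(0L, 0L, 0L)) {
  ijk <- floor(points / cell)
  paste(ijk[, 1] + offset[1], ijk[, 2] + offset[2], ijk[, 3] + offset[3],
        sep = ",")
}

# Indices of points with Euclidean distance < radius from `p` (strict).
grid_query <- function(index, p, radius) {
  stopifnot(radius <= index$cell + 1e-12)
  base <- floor(p / index$cell)
  cand <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    k <- paste(base[1] + dx, base[2] + dy, base[3] + dz, sep = ",")
    b <- index$buckets[[k]]
    if (!is.null(b)) cand <- c(cand, b)
  }
  if (!length(cand)) return(list(idx = integer(0), dist = numeric(0)))
  d <- sqrt((index$points[cand, 1] - p[1])^2 +
            (index$points[cand, 2] - p[2])^2 +
            (index$points[cand, 3] - p[3])^2)
  keep <- d < radius
  list(idx = cand[keep], dist = d[keep])
}

# Squared Euclidean cross-distances between row sets (n x 3, m x 3).
# Computed by direct coordinate subtraction: slightly slower than the expanded
# inner-product form but numerically exact, so strict threshold comparisons
# and nearest-centre tie-breaks match a literal per-pair computation bit for
# bit.
cross_dist2 <- function(a, b) {
  (outer(a[, 1], b[, 1], "-"))^2 + (outer(a[, 2], b[, 2], "-"))^2 +
    (outer(a[, 3], b[, 3], "-"))^2
}

# For each row of `a`, Euclidean distance to the nearest row of `b`,
# excluding self-matches when exclude_self (a and b identical). Chunked so
# memory stays bounded on large meshes.
nearest_dist <- function(a, b = a, exclude_self = identical(a, b),
                         chunk = 2048L) {
  n <- nrow(a)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- cross_dist2(a[s:e, , drop = FALSE], b)
    if (exclude_self) {
      d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf
    }
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Derive a deterministic sub-seed
#'
#' One user-facing master seed spawns independent, reproducible RNG streams
#' per stage / subject / unit: the master seed and any further integers are
#' hashed into a single 32-bit seed. Used throughout the pipeline so that one
#' configuration seed governs every stochastic step.
#'
#' @param seed master seed (integer).
#' @param ... further integers identifying the stream (stage id, subject
#'   index, ...).
#' @return a single integer seed below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) h <- (h * 1000003 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
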