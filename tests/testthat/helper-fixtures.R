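# Shared fixtures, built in code.

# 1-D chain of vertices at x = 0..(n-1) mm (no faces); with r = 0.95 and
# R = 1.9 the double-radius sweep gives pairwise labels {0,1}, {2,3}, ...
chain_mesh <- function(n = 10) surface_mesh(cbind(0:(n - 1), 0, 0))

chain_parcellation <- function(n = 10) {
  double_radius_divide(chain_mesh(n), r = 0.95, R = 1.9)
}

# small sphere reused across tests (memoised per session)
.fixture_cache <- new.env()
small_sphere <- function() {
  if (is.null(.fixture_cache$sphere))
    .fixture_cache$sphere <- make_icosphere(3, 4.2)  # 642 vertices, ~0.55 mm
  .fixture_cache$sphere
}

# a small end-to-end simulation configuration: same geometry density and
# paradigm structure as the defaults, scaled down for unit tests
tiny_sim_config <- function(...) {
  base <- list(mesh_subdivisions = 3, mesh_radius = 4.2,
               searchlight_radius = 3, n_subjects = 4,
               trials_per_condition = 4, run_trials = c(7, 7, 6),
               trial_spacing_s = 24, pattern_n_labels = 6,
               amplitude_n_labels = 6, coupling_seed_n_labels = 3,
               coupling_target_n_labels = 6, seed = 11)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# literal, unoptimised transcription of the double-radius painting/grouping
# rules, used as the oracle for the optimised implementation. Distances are
# per-coordinate double-precision Euclidean (x^2 + y^2 + z^2, left to right),
# the same arithmetic the contract specifies, so strict threshold comparisons
# agree bit for bit.
oracle_double_radius <- function(mesh, r, R = 2 * r) {
  v <- mesh$vertices
  n <- nrow(v)
  euclid <- function(points, q)
    sqrt((points[, 1] - q[1])^2 + (points[, 2] - q[2])^2 +
           (points[, 3] - q[3])^2)
  paint <- rep("none", n)
  assignment <- integer(n)
  seeds <- integer(0)
  for (i in seq_len(n)) {
    if (paint[i] != "none") next
    seeds <- c(seeds, i)
    lab <- length(seeds)
    d <- euclid(v, v[i, ])
    for (j in seq_len(n)) {
      if (paint[j] != "none") next
      if (d[j] < r) {
        paint[j] <- "green"; assignment[j] <- lab
      } else if (d[j] < R) {
        paint[j] <- "yellow"
      }
    }
  }
  centers <- t(vapply(seq_along(seeds), function(l)
    colMeans(v[assignment == l, , drop = FALSE]), numeric(3)))
  for (j in which(assignment == 0L)) {
    assignment[j] <- which.min(euclid(centers, v[j, ]))  # ties: lowest label
  }
  list(assignment = assignment, seeds = seeds)
}

# independent connected-components oracle (igraph)
oracle_components <- function(mask, adjacency) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  sub <- adjacency[idx, idx, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(k) sort(idx[comp$membership == k]))
}
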