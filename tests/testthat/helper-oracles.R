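# Independent oracles and small fixture builders shared across tests.

# 2-D convex hull area: base chull() vertex order + shoelace formula.
oracle_hull_area_2d <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 3) return(0)
  v <- grDevices::chull(pts)
  x <- pts[v, 1]
  y <- pts[v, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# 3-D convex hull volume by brute force: every point triple whose plane
# supports the set contributes a tetrahedron fan from the centroid.
# Assumes points in general position (no 4 coplanar hull points).
oracle_hull_volume_3d <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4) return(0)
  cen <- colMeans(pts)
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    nrm <- pracma_cross(pts[j, ] - pts[i, ], pts[k, ] - pts[i, ])
    if (sqrt(sum(nrm^2)) < 1e-12) next
    s <- as.numeric(pts %*% nrm) - sum(nrm * pts[i, ])
    tol <- 1e-9 * max(abs(s), 1)
    if (all(s <= tol) || all(s >= -tol))
      vol <- vol + abs(det(rbind(pts[i, ] - cen, pts[j, ] - cen,
                                 pts[k, ] - cen))) / 6
  }
  vol
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Hand-rolled Gower distance for two trait rows (categorical mismatch +
# range-scaled rank difference), used to cross-check gower_distance().
oracle_gower_pair <- function(traits, i, j) {
  cols <- setdiff(names(traits), "species_id")
  contrib <- vapply(cols, function(cl) {
    x <- traits[[cl]]
    if (is.ordered(x)) {
      r <- as.integer(x)
      rng <- max(r) - min(r)
      if (rng == 0) 0 else abs(r[i] - r[j]) / rng
    } else {
      as.numeric(as.character(x[i]) != as.character(x[j]))
    }
  }, 0)
  mean(contrib)
}

# A tiny deterministic dataset for pipeline-level tests.
small_dataset <- function(seed = 42, ...) {
  generate_landscape(landscape_config(
    grid_rows = 24, grid_cols = 24, n_species = 12, n_parks = 5,
    shift_cells = 4, response_width = 5, noise_sd = 0.03,
    threshold = 0.35, seed = seed, ...))
}

# Random but valid landscape configs for oracle-equivalence sweeps.
random_config <- function(seed) {
  set.seed(seed)
  landscape_config(
    grid_rows = sample(24:30, 1), grid_cols = sample(24:30, 1),
    n_species = sample(8:20, 1), n_parks = sample(3:6, 1),
    shift_cells = sample(0:6, 1), response_width = runif(1, 4, 8),
    noise_sd = runif(1, 0, 0.1), threshold = runif(1, 0.2, 0.5),
    seed = seed)
}

# Compare pipeline projections against the brute-force oracle record by
# record (same record set, same majority, same presence flags).
expect_matches_oracle <- function(dataset) {
  proj <- project_parks(dataset)
  truth <- oracle_assemblages(dataset)
  n_truth <- sum(vapply(dataset$seasons, function(se)
    sum(vapply(truth[[se]], function(p) length(p$majority), 0L)), 0L))
  expect_identical(nrow(proj), as.integer(n_truth))
  for (i in seq_len(nrow(proj))) {
    tp <- truth[[proj$season[i]]][[proj$park_id[i]]]
    expect_identical(unname(tp$majority[proj$species_id[i]]),
                     proj$majority[i])
    expect_identical(proj$species_id[i] %in% tp$current,
                     proj$present_current[i])
    expect_identical(proj$species_id[i] %in% tp$future,
                     proj$present_future[i])
  }
  invisible(proj)
}
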