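make_space <- function(points) {
  # wrap raw coordinates as a functional space for index-level tests
  structure(list(points = points, eig = rep(1, ncol(points)),
                 n_axes = ncol(points), correction = "none", msd = 0,
                 pool_hull_volume = hull_volume(points),
                 pool_max_distance = max(dist(points))),
            class = "functional_space")
}

test_that("Gower distance follows the per-trait contribution rules", {
  tr <- data.frame(
    species_id = c("a", "b", "c"),
    feeding_behavior = c("probing", "probing", "aerial_forager"),
    primary_food = c("seeds", "fruit", "fish"),
    habitat = c("forest", "forest", "tundra"),
    nesting = c("tree", "cavity", "cliff"),
    relative_size = factor(c("small", "small", "very_large"),
                           levels = size_levels(), ordered = TRUE),
    stringsAsFactors = FALSE)
  D <- gower_distance(tr)
  expect_identical(diag(D), c(a = 0, b = 0, c = 0))
  expect_equal(D, t(D))
  # a vs b: 2 of 4 categorical traits differ, identical size -> 2/5
  expect_equal(D["a", "b"], 0.4)
  # a vs c: everything maximally different -> 1
  expect_equal(D["a", "c"], 1)
  # identical rows -> 0
  tr2 <- tr
  tr2[2, -1] <- tr[1, -1]
  expect_equal(gower_distance(tr2)["a", "b"], 0)
  # single-level column contributes 0 but stays in the denominator
  tr3 <- tr
  tr3$habitat <- "forest"
  expect_warning(D3 <- gower_distance(tr3), "single level")
  expect_equal(D3["a", "c"], 4 / 5)
  expect_error(gower_distance(tr[1, ]), "at least 2")
  tr$primary_food[1] <- NA
  expect_error(gower_distance(tr), "missing values")
})

test_that("Gower distance matches cluster::daisy on random trait tables", {
  skip_if_not_installed("cluster")
  for (seed in c(501, 502, 503)) {
    tr <- generate_trait_table(25, seed = seed)
    D <- gower_distance(tr)
    df <- tr[setdiff(names(tr), "species_id")]
    for (cl in names(df)) if (!is.ordered(df[[cl]]))
      df[[cl]] <- factor(df[[cl]])
    Dd <- as.matrix(cluster::daisy(df, metric = "gower"))
    dimnames(Dd) <- dimnames(D)
    expect_equal(D, Dd, tolerance = 1e-10)
  }
})

test_that("PCoA reproduces Euclidean configurations and the collinear fixture", {
  set.seed(504)
  X <- matrix(rnorm(12 * 4), 12, 4)
  D <- as.matrix(dist(X))
  rownames(D) <- colnames(D) <- sprintf("s%d", 1:12)
  sp <- pcoa_embed(D, n_axes = 4, correction = "none")
  expect_lt(max(abs(as.matrix(dist(sp$points)) - D)), 1e-9)
  expect_equal(sp$msd, 0, tolerance = 1e-15)

  # 3 collinear points, distances 1, 1, 2: one positive axis
  D3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  sp3 <- pcoa_embed(D3, n_axes = 1, correction = "none")
  expect_equal(sp3$eig[1], 2)
  co <- sort(as.numeric(sp3$points))
  expect_equal(co, c(-1, 0, 1))
  expect_error(pcoa_embed(D3, n_axes = 2, correction = "none"),
               "positive eigenvalues")

  # two species span exactly one axis
  D2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_silent(pcoa_embed(D2, n_axes = 1, correction = "none"))
})

test_that("PCoA agrees with ape::pcoa on corrected Gower matrices", {
  skip_if_not_installed("ape")
  tr <- generate_trait_table(20, seed = 505)
  D <- gower_distance(tr)
  sp <- pcoa_embed(D, n_axes = 4, correction = "sqrt")
  ref <- ape::pcoa(as.dist(sqrt(D)))
  expect_equal(sp$eig[1:4], ref$values$Eigenvalues[1:4], tolerance = 1e-8)
  for (k in 1:4)  # axes match up to sign
    expect_equal(abs(sp$points[, k]), abs(ref$vectors[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("sqrt-corrected Gower matrices embed without negative eigenvalues", {
  for (seed in c(506, 507)) {
    tr <- generate_trait_table(18, seed = seed)
    sp <- pcoa_embed(gower_distance(tr), n_axes = 6, correction = "sqrt")
    expect_true(all(sp$eig > -1e-8 * max(sp$eig)))
    expect_true(all(diff(sp$eig[1:6]) <= 1e-12))
  }
})

test_that("embedding quality mSD shrinks as axes are added", {
  tr <- generate_trait_table(20, seed = 508)
  D <- gower_distance(tr)
  msd <- vapply(2:6, function(k)
    pcoa_embed(D, n_axes = k, correction = "sqrt")$msd, 0)
  expect_true(all(diff(msd) <= 1e-12))
  expect_true(all(msd >= 0))
  # degenerate: identical species give a zero-msd point space
  tr2 <- tr
  for (cl in setdiff(names(tr2), "species_id")) tr2[[cl]] <- tr2[[cl]][1]
  D2 <- suppressWarnings(gower_distance(tr2))
  expect_equal(pcoa_embed(D2, n_axes = 2)$msd, 0)
})

test_that("hull volumes are exact on known polytopes", {
  expect_equal(hull_volume(as.matrix(expand.grid(0:1, 0:1))), 1)
  # coplanar facets (cube faces) exercise the recursive facet path
  expect_equal(hull_volume(as.matrix(expand.grid(0:1, 0:1, 0:1))), 1)
  expect_equal(hull_volume(as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))), 1)
  expect_equal(hull_volume(rbind(c(0, 0, 0), diag(3))), 1 / 6)
  # interior points and duplicates change nothing
  sq <- rbind(as.matrix(expand.grid(0:1, 0:1)), c(0.5, 0.5), c(0, 0))
  expect_equal(hull_volume(sq), 1)
  # degenerate (flat) sets have zero volume
  expect_equal(hull_volume(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
})

test_that("hull volumes match independent 2-D and 3-D oracles", {
  set.seed(509)
  for (i in 1:20) {
    p2 <- matrix(runif(2 * sample(4:12, 1)), ncol = 2)
    expect_equal(hull_volume(p2), oracle_hull_area_2d(p2),
                 tolerance = 1e-9)
    p3 <- matrix(runif(3 * sample(5:10, 1)), ncol = 3)
    expect_equal(hull_volume(p3), oracle_hull_volume_3d(p3),
                 tolerance = 1e-9)
  }
})

test_that("functional richness is the hull fraction with degeneracy flags", {
  sq <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1)))
  rownames(sq) <- c("a", "b", "c", "d")
  space <- make_space(sq)
  expect_equal(space$pool_hull_volume, 1)
  # three corners cover half the unit square
  fr <- functional_richness(c("a", "b", "c"), space)
  expect_equal(fr$fric, 0.5)
  # whole pool is the unit fraction
  expect_equal(functional_richness(rownames(sq), space)$fric, 1)
  # n_axes points cannot span a hull
  fr2 <- functional_richness(c("a", "b"), space)
  expect_true(is.na(fr2$fric))
  expect_identical(fr2$undefined_reason, "insufficient_species")
  expect_error(functional_richness(c("a", "zz"), space), "not in")
})

test_that("functional richness never decreases when species are added", {
  set.seed(510)
  for (i in 1:100) {
    d <- sample(2:3, 1)
    pool <- matrix(runif(d * 12), ncol = d)
    rownames(pool) <- sprintf("s%02d", 1:12)
    space <- make_space(pool)
    members <- sample(rownames(pool), sample((d + 1):10, 1))
    extra <- sample(setdiff(rownames(pool), members), 1)
    f1 <- functional_richness(members, space)
    f2 <- functional_richness(c(members, extra), space)
    expect_gte(f2$fric + 1e-12, f1$fric)
    # against the brute-force oracle
    oracle <- if (d == 2) oracle_hull_area_2d(pool[members, , drop = FALSE])
              else oracle_hull_volume_3d(pool[members, , drop = FALSE])
    expect_equal(f1$hull_volume, oracle, tolerance = 1e-9)
  }
})

test_that("functional dispersion is centroid distance with pool scaling", {
  tri <- rbind(a = c(0, 0), b = c(1, 0), c = c(0.5, sqrt(3) / 2))
  space <- make_space(tri)  # equilateral, side 1 = pool max distance
  fd <- functional_dispersion(rownames(tri), space)
  expect_equal(fd$fdis_raw, 1 / sqrt(3))
  expect_equal(fd$fdis_scaled, 2 / sqrt(3))  # deliberately exceeds 1
  # the two most distant species score exactly 1
  fd2 <- functional_dispersion(c("a", "b"), space)
  expect_equal(fd2$fdis_scaled, 1, tolerance = 1e-12)
  # a singleton sits on its own centroid
  expect_equal(functional_dispersion("a", space)$fdis_raw, 0)
})

test_that("dispersion is zero iff all members coincide", {
  set.seed(511)
  pts <- matrix(runif(20), 10, 2)
  pts[4, ] <- pts[1, ]
  rownames(pts) <- sprintf("s%d", 1:10)
  space <- make_space(pts)
  expect_equal(functional_dispersion(c("s1", "s4"), space)$fdis_raw, 0)
  expect_gt(functional_dispersion(c("s1", "s2"), space)$fdis_raw, 0)
})

test_that("taxon restrictedness equals direct occupancy counting", {
  set.seed(512)
  for (i in 1:10) {
    n_sp <- sample(5:15, 1)
    n_pk <- sample(4:10, 1)
    cur <- matrix(runif(n_sp * n_pk) < 0.5, n_sp, n_pk,
                  dimnames = list(sprintf("s%d", 1:n_sp),
                                  sprintf("p%d", 1:n_pk)))
    fut <- matrix(runif(n_sp * n_pk) < 0.5, n_sp, n_pk,
                  dimnames = dimnames(cur))
    tr <- suppressWarnings(taxon_restrictedness(cur, fut))
    for (j in seq_len(nrow(tr))) {
      m <- if (tr$period[j] == "current") cur else fut
      # independent counting loop
      hits <- 0L
      for (pk in colnames(m)) if (m[tr$species_id[j], pk]) hits <- hits + 1L
      expect_equal(tr$tres[j], hits / n_pk)
    }
    # only species present in both periods are kept
    expect_setequal(unique(tr$species_id),
                    rownames(cur)[rowSums(cur) > 0 & rowSums(fut) > 0])
  }
})

test_that("restrictedness hits its boundary values", {
  cur <- rbind(everywhere = rep(TRUE, 10), half = rep(c(TRUE, FALSE), 5),
               nowhere = rep(FALSE, 10))
  colnames(cur) <- sprintf("p%d", 1:10)
  fut <- cur
  fut["nowhere", 1] <- TRUE
  expect_warning(tr <- taxon_restrictedness(cur, fut), "dropped")
  expect_equal(tr$tres[tr$species_id == "everywhere" &
                         tr$period == "current"], 1)
  expect_equal(tr$tres[tr$species_id == "half" & tr$period == "current"],
               0.5)
  expect_false("nowhere" %in% tr$species_id)
})

test_that("per-season functional indices run end to end", {
  d <- small_dataset(seed = 31)
  proj <- apply_review_filters(project_parks(d), d$review)$projections
  fi <- suppressWarnings(
    functional_indices(proj, d$traits, n_axes = 4,
                       exclude_parks = "park01"))
  expect_false("park01" %in% fi$indices$park_id)
  ok <- !is.na(fi$indices$fric)
  expect_true(all(fi$indices$fric[ok] >= 0 & fi$indices$fric[ok] <= 1))
  expect_true(all(fi$indices$fdis_raw >= 0))
  expect_true(all(c("summer", "winter") %in% names(fi$spaces)))
  expect_equal(fi$indices$fdis_scaled,
               fi$indices$fdis_raw /
                 vapply(fi$indices$season, function(se)
                   fi$spaces[[se]]$pool_max_distance / 2, 0),
               ignore_attr = TRUE)
})
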