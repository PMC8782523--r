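test_that("percent change is plain relative change with guarded domain", {
  expect_equal(percent_change(0.50, 0.25), -50)
  expect_equal(percent_change(0.40, 0.40), 0)
  expect_equal(percent_change(0.20, 0.27), 35)
  expect_error(percent_change(0.05, 0.2, threshold = 0.1), "threshold")
  expect_error(percent_change(0, 0.2), "zero baseline")
  expect_error(percent_change(NA_real_, 0.2), "finite")
})

test_that("cell classification covers the worked examples and boundaries", {
  expect_identical(classify_cell(0.50, 0.30, 0.1), "worsening")
  expect_identical(classify_cell(0.05, 0.20, 0.1), "potential_colonisation")
  expect_identical(classify_cell(0.50, 0.55, 0.1), "stable")
  expect_identical(classify_cell(0.02, 0.05, 0.1), "absent")
  expect_identical(classify_cell(0.50, 0.05, 0.1), "potential_extirpation")
  # interval endpoints resolve to stable on both sides (dyadic values make
  # the +/-25% deltas exact in floating point)
  expect_identical(classify_cell(0.5, 0.375, 0.1), "stable")   # exactly -25
  expect_identical(classify_cell(0.5, 0.625, 0.1), "stable")   # exactly +25
  expect_identical(classify_cell(0.5, 0.3749, 0.1), "worsening")
  expect_identical(classify_cell(0.5, 0.6251, 0.1), "improving")
  expect_error(classify_cell(0.5, NaN, 0.1), "finite")
  expect_error(classify_cell(0.5, 1.2, 0.1), "\\[0, 1\\]")
})

test_that("classification always returns exactly one valid category", {
  set.seed(301)
  n <- 5000
  # include the interval endpoints (-100%, -25%, +25%) and threshold edges
  b <- c(runif(n), 0, 1, 0.25, 0.1, 0.5, 0.5, 0.5)
  s <- c(runif(n + 2), 0.25, 0.1, 0.375, 0.625, 0)
  thr <- c(runif(n + 2, 0.05, 0.95), 0.25, 0.1, 0.2, 0.2, 0.2)
  out <- mapply(classify_cell, b, s, thr)
  expect_length(out, n + 7)
  expect_true(all(out %in% change_categories()))
})

test_that("park summaries follow the majority rule and tie priority", {
  cats <- matrix("absent", 4, 5)
  # 10 worsening, 5 stable, 3 improving in an 18-cell mask
  cats[1:18] <- rep(c("worsening", "stable", "improving"), c(10, 5, 3))
  mask <- 0:17  # 0-based row-major over the 4x5 grid
  s <- summarize_park(cats, mask)
  expect_identical(s$majority, "worsening")
  expect_identical(unname(s$counts["worsening"]), 10L)

  # tie: colonisation beats stable under the default priority
  cats2 <- matrix(rep(c("stable", "potential_colonisation"), each = 4),
                  2, 4)
  s2 <- summarize_park(cats2, 0:7)
  expect_identical(s2$majority, "potential_colonisation")
  # and the priority order is configurable
  s3 <- summarize_park(cats2, 0:7,
                       tie_order = c("stable", "improving", "worsening",
                                     "potential_colonisation",
                                     "potential_extirpation"))
  expect_identical(s3$majority, "stable")

  # all-absent masks yield no projection
  s4 <- summarize_park(matrix("absent", 3, 3), 0:8)
  expect_true(is.na(s4$majority))
  expect_false(s4$present_current || s4$present_future)

  expect_error(summarize_park(cats, integer(0)), "empty")
  expect_error(summarize_park(cats, c(0L, 100L)), "outside the grid")
})

test_that("category counts are conserved over the occupied mask", {
  set.seed(302)
  for (rep in 1:20) {
    nr <- sample(5:10, 1)
    nc <- sample(5:10, 1)
    thr <- runif(1, 0.2, 0.6)
    b <- matrix(runif(nr * nc), nr, nc)
    s <- matrix(runif(nr * nc), nr, nc)
    cats <- classify_cell(b, s, thr)
    cells <- sort(sample(0:(nr * nc - 1), sample(3:(nr * nc), 1)))
    ps <- summarize_park(cats, cells)
    # independent occupancy count straight from the surfaces
    ri <- cells %/% nc + 1
    ci <- cells %% nc + 1
    occupied <- sum(b[cbind(ri, ci)] >= thr | s[cbind(ri, ci)] >= thr)
    expect_identical(sum(ps$counts[setdiff(change_categories(), "absent")]),
                     as.integer(occupied))
    expect_identical(sum(ps$counts), length(cells))
  }
})

test_that("presence derivation follows the period membership rule", {
  p <- derive_presence(c("stable", "potential_extirpation",
                         "potential_colonisation", "worsening",
                         "improving"))
  expect_identical(p$present_current, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_identical(p$present_future, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_error(derive_presence("nonsense"), "change categories")
})

test_that("pipeline projections equal the brute-force oracle", {
  expect_matches_oracle(small_dataset(seed = 17))
})

test_that("review filters drop exactly the flagged compatible records", {
  proj <- data.frame(
    park_id = "p1", species_id = sprintf("s%02d", 1:10), season = "summer",
    majority = c(rep("stable", 6), "potential_extirpation",
                 rep("potential_colonisation", 3)),
    present_current = c(rep(TRUE, 7), rep(FALSE, 3)),
    present_future = c(rep(TRUE, 6), FALSE, rep(TRUE, 3)),
    stringsAsFactors = FALSE)

  # empty review table: identity
  f0 <- apply_review_filters(proj, NULL)
  expect_identical(f0$projections, proj)
  expect_true(all(f0$removals$fraction_removed == 0))

  # one of ten flagged unconfirmed: 9 remain, removal fraction 0.10
  rv <- data.frame(species_id = "s01", park_id = "p1", season = "summer",
                   flag = "unconfirmed_baseline", stringsAsFactors = FALSE)
  f1 <- apply_review_filters(proj, rv)
  expect_identical(nrow(f1$projections), 9L)
  expect_equal(
    f1$removals$fraction_removed[f1$removals$flag == "unconfirmed_baseline"],
    0.10)

  # improbable colonisation removes a colonisation record
  rv2 <- data.frame(species_id = "s09", park_id = "p1", season = "summer",
                    flag = "improbable_colonisation",
                    stringsAsFactors = FALSE)
  f2 <- apply_review_filters(proj, rv2)
  expect_false("s09" %in% f2$projections$species_id)

  # incompatible flags warn and remove nothing
  rv3 <- data.frame(species_id = c("s02", "s10"), park_id = "p1",
                    season = "summer",
                    flag = c("improbable_colonisation",
                             "unconfirmed_baseline"),
                    stringsAsFactors = FALSE)
  w <- testthat::capture_warnings(f3 <- apply_review_filters(proj, rv3))
  expect_length(w, 2)
  expect_true(all(grepl("not removed", w)))
  expect_identical(nrow(f3$projections), nrow(proj))

  # flags never add records; fractions stay in [0, 1]
  expect_lte(nrow(f2$projections), nrow(proj))
  expect_true(all(f2$removals$fraction_removed >= 0 &
                    f2$removals$fraction_removed <= 1))
})
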