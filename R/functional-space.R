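#' Gower distance over a mixed-type trait table
#'
#' Per-trait contributions: unordered categorical traits contribute 0 (match)
#' or 1 (mismatch); ordered traits contribute the absolute rank difference
#' range-normalised to `[0, 1]` over the ranks observed in the data. The
#' distance is the unweighted mean of the per-trait contributions, so a trait
#' column with a single observed level contributes 0 for every pair but stays
#' in the denominator (with a warning).
#'
#' @param traits Data frame with a `species_id` column; every other column is
#'   a trait. Ordered factors are treated as ordinal, everything else as
#'   unordered categorical. No missing values allowed.
#' @return Symmetric numeric matrix in `[0, 1]` with zero diagonal and
#'   species ids as dimnames.
#' @export
gower_distance <- function(traits) {
  if (!"species_id" %in% names(traits))
    stop("traits must have a species_id column")
  ids <- traits$species_id
  n <- length(ids)
  if (n < 2) stop("need at least 2 species")
  if (anyDuplicated(ids)) stop("duplicate species_id in trait table")
  cols <- setdiff(names(traits), "species_id")
  if (length(cols) == 0) stop("trait table has no trait columns")
  if (anyNA(traits[cols])) stop("trait table has missing values")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (cl in cols) {
    x <- traits[[cl]]
    if (is.ordered(x)) {
      r <- as.integer(x)
      rng <- max(r) - min(r)
      if (rng == 0) {
        warning("trait '", cl, "' has a single level; it contributes 0 ",
                "to all pairwise distances")
        next
      }
      D <- D + abs(outer(r, r, "-")) / rng
    } else {
      x <- as.character(x)
      if (length(unique(x)) == 1) {
        warning("trait '", cl, "' has a single level; it contributes 0 ",
                "to all pairwise distances")
        next
      }
      D <- D + (outer(x, x, "!=") * 1)
    }
  }
  D / length(cols)
}

#' Principal coordinates embedding of a dissimilarity matrix
#'
#' Builds the functional space: optionally square-root transforms the
#' dissimilarities (the standard remedy that makes a Gower matrix
#' near-Euclidean), double-centers `-0.5 * D^2`, eigendecomposes, and keeps
#' the first `n_axes` axes scaled by the square roots of their eigenvalues.
#' Fails with an informative error when fewer than `n_axes` eigenvalues are
#' positive. The returned object also carries the embedding-quality mean
#' squared deviation ([space_quality_msd()]), the convex-hull volume of the
#' whole pool, and the largest pairwise distance in the pool, which
#' downstream indices are scaled by.
#'
#' @param distances Symmetric dissimilarity matrix (or `dist`).
#' @param n_axes Number of retained axes (>= 1; 6 in the default analysis).
#' @param correction `"sqrt"` (default) or `"none"`.
#' @return Object of class `functional_space`: list with `points` (species x
#'   `n_axes` coordinates), `eig` (all eigenvalues, decreasing), `n_axes`,
#'   `correction`, `msd`, `pool_hull_volume`, `pool_max_distance`.
#' @export
pcoa_embed <- function(distances, n_axes = 6L,
                       correction = c("sqrt", "none")) {
  correction <- match.arg(correction)
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 points")
  if (!isSymmetric(unname(D), tol = 1e-8) || any(diag(D) != 0) || any(D < 0))
    stop("distances must be a symmetric non-negative matrix with zero ",
         "diagonal")
  if (n_axes < 1) stop("n_axes must be at least 1")
  if (n_axes > n - 1) stop("n_axes cannot exceed n - 1 = ", n - 1)
  Dc <- if (correction == "sqrt") sqrt(D) else D
  if (max(Dc) == 0) {
    # all points identical: a legitimate degenerate space
    pts <- matrix(0, n, n_axes, dimnames = list(rownames(D), NULL))
    sp <- structure(list(points = pts, eig = rep(0, n), n_axes = n_axes,
                         correction = correction, msd = 0,
                         pool_hull_volume = 0, pool_max_distance = 0),
                    class = "functional_space")
    return(sp)
  }
  cm <- suppressWarnings(stats::cmdscale(Dc, k = n_axes, eig = TRUE))
  npos <- sum(cm$eig > max(cm$eig) * 1e-9)
  if (npos < n_axes)
    stop("only ", npos, " positive eigenvalues: choose n_axes <= ", npos)
  pts <- cm$points
  rownames(pts) <- rownames(D)
  sp <- structure(list(points = pts, eig = cm$eig, n_axes = n_axes,
                       correction = correction, msd = NA_real_,
                       pool_hull_volume = NA_real_,
                       pool_max_distance = max(stats::dist(pts))),
                  class = "functional_space")
  sp$msd <- space_quality_msd(D, sp)
  sp$pool_hull_volume <- hull_volume(pts)
  sp
}

#' Build a functional space from a trait table
#'
#' Convenience wrapper: [gower_distance()] followed by [pcoa_embed()].
#'
#' @inheritParams gower_distance
#' @inheritParams pcoa_embed
#' @return A `functional_space` object (see [pcoa_embed()]).
#' @export
functional_space <- function(traits, n_axes = 6L,
                             correction = c("sqrt", "none")) {
  pcoa_embed(gower_distance(traits), n_axes = n_axes,
             correction = match.arg(correction))
}

#' @export
print.functional_space <- function(x, ...) {
  cat("Functional space:", nrow(x$points), "species on", x$n_axes,
      "axes\n")
  cat("  dissimilarity correction:", x$correction, "\n")
  cat("  embedding quality (mSD):", format(x$msd, digits = 4), "\n")
  cat("  pool hull volume:", format(x$pool_hull_volume, digits = 4),
      "| max pairwise distance:",
      format(x$pool_max_distance, digits = 4), "\n")
  invisible(x)
}

#' Embedding quality: mean squared deviation
#'
#' Mean over unordered pairs of the squared deviation between the input
#' dissimilarity and the Euclidean distance in the retained space, after
#' rescaling the space distances so their maximum matches the maximum input
#' dissimilarity (the standard quality measure for reduced functional
#' spaces). 0 means a perfect embedding.
#'
#' @param distances The original (pre-correction) dissimilarity matrix.
#' @param space A `functional_space` built from those distances.
#' @return Non-negative scalar.
#' @export
space_quality_msd <- function(distances, space) {
  Din <- as.matrix(distances)
  De <- as.matrix(stats::dist(space$points))
  ut <- upper.tri(Din)
  if (max(De) == 0) return(mean(Din[ut]^2))
  sc <- max(Din) / max(De)
  mean((Din[ut] - De[ut] * sc)^2)
}

#' Convex hull volume of a point set
#'
#' Exact d-dimensional hull volume by supporting-hyperplane facet
#' enumeration (compiled code); exponential in the number of axes, intended
#' for the small spaces used here. Degenerate sets (affine rank below the
#' space dimension) have zero volume.
#'
#' @param points Numeric matrix, one row per point.
#' @return Non-negative scalar volume.
#' @export
hull_volume <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || !all(is.finite(points)))
    stop("points must be a finite numeric matrix")
  .hull_volume_cpp(points)
}

resolve_members <- function(members, space) {
  if (is.character(members)) {
    missing <- setdiff(members, rownames(space$points))
    if (length(missing) > 0)
      stop("species not in the functional space: ",
           paste(missing, collapse = ", "))
    space$points[members, , drop = FALSE]
  } else {
    m <- as.matrix(members)
    if (ncol(m) != ncol(space$points))
      stop("member coordinates must have ", ncol(space$points), " columns")
    m
  }
}

affine_rank <- function(coords) {
  if (nrow(coords) < 2) return(0L)
  qr(sweep(coords, 2, colMeans(coords)))$rank
}

#' Functional richness of an assemblage
#'
#' Convex-hull volume of the assemblage's species in the functional space as
#' a fraction of the global pool's hull volume. Undefined (NA, with
#' `undefined_reason = "insufficient_species"`) when the assemblage has fewer
#' than `n_axes + 1` affinely independent members.
#'
#' @param members Character vector of species ids (rows of `space$points`)
#'   or a coordinate matrix.
#' @param space A `functional_space`.
#' @return List with `fric` (in `[0, 1]`, or `NA`), `hull_volume`, and
#'   `undefined_reason` (`NA` when defined).
#' @export
functional_richness <- function(members, space) {
  coords <- resolve_members(members, space)
  d <- ncol(coords)
  if (is.na(space$pool_hull_volume) || space$pool_hull_volume <= 0)
    stop("the pool hull volume is zero or unknown; the pool needs at ",
         "least n_axes + 1 affinely independent species")
  coords <- unique(coords)
  if (nrow(coords) < d + 1 || affine_rank(coords) < d)
    return(list(fric = NA_real_, hull_volume = NA_real_,
                undefined_reason = "insufficient_species"))
  v <- hull_volume(coords)
  list(fric = v / space$pool_hull_volume, hull_volume = v,
       undefined_reason = NA_character_)
}

#' Functional dispersion of an assemblage
#'
#' Mean Euclidean distance of the assemblage's species to their unweighted
#' centroid in the functional space. The scaled value divides by half the
#' largest pairwise distance in the pool (the dispersion of an assemblage
#' holding only the two most distant species), so a two-most-distant-species
#' assemblage scores exactly 1; other configurations can exceed 1 and the
#' value is deliberately not clamped.
#'
#' @inheritParams functional_richness
#' @return List with `fdis_raw` and `fdis_scaled` (a singleton scores 0 on
#'   both).
#' @export
functional_dispersion <- function(members, space) {
  coords <- resolve_members(members, space)
  if (nrow(coords) == 0) stop("assemblage is empty")
  cen <- colMeans(coords)
  raw <- mean(sqrt(rowSums(sweep(coords, 2, cen)^2)))
  scl <- if (space$pool_max_distance > 0)
    raw / (space$pool_max_distance / 2) else 0
  list(fdis_raw = raw, fdis_scaled = scl)
}

#' Occurrence matrix from park projections
#'
#' @param projections Data frame from [project_parks()] (normally filtered).
#' @param season Season to extract.
#' @param period `"current"` or `"future"`.
#' @param parks Optional character vector fixing the park set (columns);
#'   defaults to the parks appearing in `projections` for that season.
#' @return Logical species x park matrix.
#' @export
occurrence_matrix <- function(projections, season,
                              period = c("current", "future"),
                              parks = NULL) {
  period <- match.arg(period)
  p <- projections[projections$season == season, , drop = FALSE]
  if (is.null(parks)) parks <- sort(unique(p$park_id))
  species <- sort(unique(p$species_id))
  m <- matrix(FALSE, length(species), length(parks),
              dimnames = list(species, parks))
  pres <- if (period == "current") p$present_current else p$present_future
  p <- p[pres & p$park_id %in% parks, , drop = FALSE]
  m[cbind(p$species_id, p$park_id)] <- TRUE
  m
}

#' Taxon restrictedness of species across parks
#'
#' The fraction of parks a species occupies, per period: 0 means absent from
#' every park (completely restricted), 1 means present at every park (no
#' restriction). Computed only for species occupying at least one park in
#' both the current and the future community; others are dropped with a
#' warning.
#'
#' @param current,future Logical species x park occurrence matrices with
#'   identical dimnames (see [occurrence_matrix()]).
#' @return Data frame with `species_id`, `period`, `tres`.
#' @export
taxon_restrictedness <- function(current, future) {
  if (!identical(dim(current), dim(future)) ||
      !identical(dimnames(current), dimnames(future)))
    stop("current and future occurrence matrices must have identical ",
         "dimnames")
  keep <- rowSums(current) > 0 & rowSums(future) > 0
  if (any(!keep))
    warning(sum(!keep), " species absent from all parks in one period ",
            "dropped from restrictedness")
  sp <- rownames(current)[keep]
  data.frame(
    species_id = rep(sp, 2),
    period = rep(c("current", "future"), each = length(sp)),
    tres = c(rowMeans(current[keep, , drop = FALSE]),
             rowMeans(future[keep, , drop = FALSE])),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Functional indices for every park, season and period
#'
#' Computes species richness, functional richness and (scaled) functional
#' dispersion for the current and future assemblage of each park, in a
#' functional space built per season from the pooled species of both
#' periods. Species without trait data and parks on the exclusion list are
#' left out.
#'
#' @param projections Filtered projections ([apply_review_filters()]).
#' @param traits Trait table covering the projected species.
#' @param n_axes Number of functional axes.
#' @param exclude_parks Parks left out of the functional analyses.
#' @param correction Dissimilarity correction for [pcoa_embed()].
#' @return List with `indices` (data frame: `park_id`, `season`, `period`,
#'   `sp_rich`, `fric`, `fdis_raw`, `fdis_scaled`, `undefined_reason`) and
#'   `spaces` (named list of per-season `functional_space` objects).
#' @export
functional_indices <- function(projections, traits, n_axes = 6L,
                               exclude_parks = character(),
                               correction = "sqrt") {
  p <- projections[!projections$park_id %in% exclude_parks, , drop = FALSE]
  rows <- list()
  spaces <- list()
  k <- 0L
  for (season in sort(unique(p$season))) {
    ps <- p[p$season == season, , drop = FALSE]
    pool <- sort(unique(ps$species_id[ps$present_current |
                                        ps$present_future]))
    pool <- intersect(pool, traits$species_id)
    if (length(pool) < n_axes + 1) {
      warning("season ", season, ": pool of ", length(pool),
              " species too small for a ", n_axes, "-axis space; skipped")
      next
    }
    space <- functional_space(traits[match(pool, traits$species_id), ,
                                     drop = FALSE],
                              n_axes = n_axes, correction = correction)
    spaces[[season]] <- space
    for (pk in sort(unique(ps$park_id))) {
      g <- ps[ps$park_id == pk, , drop = FALSE]
      for (period in c("current", "future")) {
        pres <- if (period == "current") g$present_current else
          g$present_future
        members <- intersect(g$species_id[pres], pool)
        if (length(members) == 0) next
        fr <- functional_richness(members, space)
        fd <- functional_dispersion(members, space)
        k <- k + 1L
        rows[[k]] <- data.frame(
          park_id = pk, season = season, period = period,
          sp_rich = length(members), fric = fr$fric,
          fdis_raw = fd$fdis_raw, fdis_scaled = fd$fdis_scaled,
          undefined_reason = fr$undefined_reason, stringsAsFactors = FALSE)
      }
    }
  }
  indices <- if (k > 0) do.call(rbind, rows) else
    data.frame(park_id = character(), season = character(),
               period = character())
  rownames(indices) <- NULL
  list(indices = indices, spaces = spaces)
}
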