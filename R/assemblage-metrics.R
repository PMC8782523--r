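#' Sorensen and Jaccard turnover between two presence sets
#'
#' Sorensen similarity is `2|A n B| / (|A| + |B|)`; Jaccard similarity is
#' `|A n B| / |A u B|`; turnover is one minus similarity. Both are undefined
#' (returned as `NA` with a warning) when both sets are empty, as happens for
#' parks with no winter species.
#'
#' @param current,future Character vectors of species ids (duplicates are
#'   ignored).
#' @return A single turnover value in `[0, 1]`, or `NA`.
#' @examples
#' sorensen_turnover(c("a", "b", "c"), c("b", "c", "d"))  # 1 - 4/6
#' @export
sorensen_turnover <- function(current, future) {
  current <- unique(current)
  future <- unique(future)
  if (length(current) + length(future) == 0) {
    warning("turnover undefined: both assemblages empty")
    return(NA_real_)
  }
  a <- length(intersect(current, future))
  1 - 2 * a / (length(current) + length(future))
}

#' @rdname sorensen_turnover
#' @export
jaccard_turnover <- function(current, future) {
  current <- unique(current)
  future <- unique(future)
  if (length(current) + length(future) == 0) {
    warning("turnover undefined: both assemblages empty")
    return(NA_real_)
  }
  a <- length(intersect(current, future))
  1 - a / length(union(current, future))
}

#' Per-park assemblage comparison metrics
#'
#' Collapses (review-filtered) park projections into one row per park and
#' season: current and future species richness, counts of each majority
#' category, and Sorensen/Jaccard turnover between the current and future
#' presence sets.
#'
#' @param projections Data frame from [project_parks()], normally after
#'   [apply_review_filters()].
#' @return Data frame with columns `park_id`, `season`, `sp_rich_current`,
#'   `sp_rich_future`, `richness_change`, `n_colonisation`, `n_extirpation`,
#'   `n_worsening`, `n_improving`, `n_stable`, `sorensen_turnover`,
#'   `jaccard_turnover`.
#' @export
assemblage_pairs <- function(projections) {
  if (nrow(projections) == 0) {
    warning("no projection records: no assemblages to summarize")
    return(data.frame(park_id = character(), season = character()))
  }
  grp <- split(projections,
               list(park = projections$park_id,
                    season = projections$season), drop = TRUE)
  rows <- lapply(grp, function(g) {
    cur <- g$species_id[g$present_current]
    fut <- g$species_id[g$present_future]
    data.frame(
      park_id = g$park_id[1], season = g$season[1],
      sp_rich_current = length(cur), sp_rich_future = length(fut),
      richness_change = length(fut) - length(cur),
      n_colonisation = sum(g$majority == "potential_colonisation"),
      n_extirpation = sum(g$majority == "potential_extirpation"),
      n_worsening = sum(g$majority == "worsening"),
      n_improving = sum(g$majority == "improving"),
      n_stable = sum(g$majority == "stable"),
      sorensen_turnover = sorensen_turnover(cur, fut),
      jaccard_turnover = jaccard_turnover(cur, fut),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$season, out$park_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify parks into relative trend groups
#'
#' Plots (conceptually) the proportion of potential colonisations against the
#' proportion of potential extirpations across parks and cuts the plane into
#' five sectors from the per-axis median and upper quartile: `high_turnover`
#' (both proportions high), `high_potential_colonisation` /
#' `high_potential_extirpation` (exactly one high), `low_change` (both
#' strictly below the medians) and `intermediate_change` (the rest). A
#' proportion counts as "high" when it is at or above the upper quartile and
#' strictly above the median; with degenerate spreads (all parks identical)
#' every park is therefore `intermediate_change`.
#'
#' Colonisation proportions are scaled by future richness and extirpation
#' proportions by current richness (configurable via `denominators`).
#' Quartiles use the linear-interpolation convention (`type = 7`).
#'
#' @param pairs Data frame from [assemblage_pairs()].
#' @param denominators Length-2 character vector naming the richness column
#'   period used to scale colonisations and extirpations.
#' @return Data frame with `park_id`, `season`, `prop_colonisation`,
#'   `prop_extirpation`, `group`; per-season quartile cuts are attached as
#'   the `quartile_cuts` attribute.
#' @export
classify_trend_groups <- function(pairs,
                                  denominators = c(colonisation = "future",
                                                   extirpation = "current")) {
  res <- list()
  cuts <- list()
  for (season in unique(pairs$season)) {
    p <- pairs[pairs$season == season, , drop = FALSE]
    if (nrow(p) < 5)
      stop("trend groups need at least 5 parks per season (got ",
           nrow(p), " in ", season, ")")
    den_c <- if (denominators[["colonisation"]] == "future")
      p$sp_rich_future else p$sp_rich_current
    den_e <- if (denominators[["extirpation"]] == "current")
      p$sp_rich_current else p$sp_rich_future
    prop_c <- ifelse(den_c == 0, 0, p$n_colonisation / den_c)
    prop_e <- ifelse(den_e == 0, 0, p$n_extirpation / den_e)
    qc <- stats::quantile(prop_c, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    qe <- stats::quantile(prop_e, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    hi_c <- prop_c >= qc[3] & prop_c > qc[2]
    hi_e <- prop_e >= qe[3] & prop_e > qe[2]
    lo <- prop_c < qc[2] & prop_e < qe[2]
    group <- ifelse(hi_c & hi_e, "high_turnover",
             ifelse(hi_c, "high_potential_colonisation",
             ifelse(hi_e, "high_potential_extirpation",
             ifelse(lo, "low_change", "intermediate_change"))))
    res[[season]] <- data.frame(park_id = p$park_id, season = season,
                                prop_colonisation = prop_c,
                                prop_extirpation = prop_e, group = group,
                                stringsAsFactors = FALSE)
    cuts[[season]] <- list(colonisation = stats::setNames(qc, c("q1", "median", "q3")),
                           extirpation = stats::setNames(qe, c("q1", "median", "q3")))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "quartile_cuts") <- cuts
  out
}

mean_se_cols <- function(x) {
  n <- sum(!is.na(x))
  m <- mean(x, na.rm = TRUE)
  se <- if (n > 1) stats::sd(x, na.rm = TRUE) / sqrt(n) else NA_real_
  c(mean = m, se = se)
}

#' Regional and national summary of assemblage change
#'
#' Per region and season: number of parks and mean +/- SE of richness change,
#' potential colonisations, potential extirpations and Sorensen turnover per
#' park, plus a national row aggregating all parks. SE is the sample standard
#' deviation over sqrt(n parks); single-park regions report a bare mean
#' (SE `NA`).
#'
#' @param pairs Data frame from [assemblage_pairs()].
#' @param regions Named character vector mapping `park_id` to region label.
#' @return Data frame, one row per region x season plus `National` rows.
#' @export
summarize_regions <- function(pairs, regions) {
  unmapped <- setdiff(unique(pairs$park_id), names(regions))
  if (length(unmapped) > 0)
    stop("parks not mapped to a region: ", paste(unmapped, collapse = ", "))
  pairs$region <- unname(regions[pairs$park_id])
  rows <- list()
  k <- 0L
  for (season in unique(pairs$season)) {
    p <- pairs[pairs$season == season, , drop = FALSE]
    for (reg in c(sort(unique(p$region)), "National")) {
      g <- if (reg == "National") p else p[p$region == reg, , drop = FALSE]
      rc <- mean_se_cols(g$richness_change)
      co <- mean_se_cols(g$n_colonisation)
      ex <- mean_se_cols(g$n_extirpation)
      tu <- mean_se_cols(g$sorensen_turnover)
      k <- k + 1L
      rows[[k]] <- data.frame(
        region = reg, season = season, n_parks = nrow(g),
        richness_change_mean = rc[["mean"]], richness_change_se = rc[["se"]],
        colonisation_mean = co[["mean"]], colonisation_se = co[["se"]],
        extirpation_mean = ex[["mean"]], extirpation_se = ex[["se"]],
        turnover_mean = tu[["mean"]], turnover_se = tu[["se"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
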