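#' The five suitability-change categories (plus the structural `absent` class)
#'
#' Per-cell transitions between a baseline and a warming-scenario suitability
#' surface are classified as `potential_extirpation` (present only in the
#' baseline), `worsening` (present in both, suitability change in
#' \[-100\%, -25\%)), `stable` (change in \[-25\%, +25\%\]), `improving`
#' (change > +25\%) or `potential_colonisation` (present only under the
#' scenario). Cells below the occurrence threshold in both periods carry the
#' bookkeeping category `absent`; they are excluded from park majority votes.
#'
#' @return Character vector of category names, `absent` first.
#' @export
change_categories <- function() {
  c("absent", "potential_extirpation", "worsening", "stable", "improving",
    "potential_colonisation")
}

#' Default tie-break priority for park majority votes
#'
#' When two or more categories are tied for the largest cell count within a
#' park, the winner is the first tied category in this order. The default
#' favours flagging change over stasis: extirpation and colonisation first,
#' stability last.
#'
#' @return Character vector of the five non-absent categories in priority
#'   order.
#' @export
default_tie_order <- function() {
  c("potential_extirpation", "potential_colonisation", "worsening",
    "improving", "stable")
}

#' Percent change in suitability between baseline and scenario
#'
#' Computes `100 * (scenario - baseline) / baseline`. The quantity is only
#' meaningful where the species is present in the baseline; cells below the
#' occurrence threshold must instead be routed to the colonisation/absent
#' branches of [classify_cell()].
#'
#' @param baseline,scenario Numeric vectors of suitability values in `[0, 1]`.
#' @param threshold Optional occurrence threshold; if supplied, baseline
#'   values below it raise an error (the change is undefined there).
#' @return Numeric vector of percent changes.
#' @examples
#' percent_change(0.5, 0.25)  # -50
#' percent_change(0.2, 0.27)  # +35
#' @export
percent_change <- function(baseline, scenario, threshold = NULL) {
  if (!all(is.finite(baseline)) || !all(is.finite(scenario)))
    stop("suitability values must be finite")
  if (!is.null(threshold) && any(baseline < threshold))
    stop("percent change undefined: baseline suitability below the ",
         "occurrence threshold")
  if (any(baseline <= 0))
    stop("percent change undefined for zero baseline suitability")
  100 * (scenario - baseline) / baseline
}

#' Classify per-cell suitability change
#'
#' Vectorised over cells; matrix inputs yield a matrix of the same shape.
#' Presence in a period means suitability at or above `threshold`. Category
#' interval endpoints: `worsening` is \[-100, -25), `stable` the closed
#' interval \[-25, +25\], `improving` (+25, Inf); the +/-25 boundaries
#' resolve to `stable`.
#'
#' @param baseline,scenario Suitability values in `[0, 1]` (vectors or
#'   equal-shaped matrices).
#' @param threshold Occurrence threshold in (0, 1); scalar or per-cell.
#' @return Character vector/matrix of categories (see [change_categories()]).
#' @examples
#' classify_cell(0.50, 0.30, 0.1)  # worsening (-40%)
#' classify_cell(0.05, 0.20, 0.1)  # potential_colonisation
#' @export
classify_cell <- function(baseline, scenario, threshold) {
  if (length(scenario) != length(baseline))
    stop("baseline and scenario must have the same length")
  if (!all(is.finite(baseline)) || !all(is.finite(scenario)))
    stop("suitability values must be finite")
  if (any(baseline < 0 | baseline > 1) || any(scenario < 0 | scenario > 1))
    stop("suitability values must lie in [0, 1]")
  if (!all(is.finite(threshold)) || any(threshold <= 0 | threshold >= 1))
    stop("threshold must lie in (0, 1)")
  pb <- baseline >= threshold
  ps <- scenario >= threshold
  out <- character(length(baseline))
  out[!pb & !ps] <- "absent"
  out[pb & !ps] <- "potential_extirpation"
  out[!pb & ps] <- "potential_colonisation"
  both <- pb & ps
  if (any(both)) {
    delta <- percent_change(baseline[both], scenario[both])
    out[both] <- ifelse(delta < -25, "worsening",
                        ifelse(delta > 25, "improving", "stable"))
  }
  if (is.matrix(baseline)) dim(out) <- dim(baseline)
  out
}

# 0-based row-major cell index -> R linear (column-major, 1-based) index
cell_linear_index <- function(cells, nrow, ncol) {
  row <- cells %/% ncol
  col <- cells %% ncol
  col * nrow + row + 1L
}

#' Summarize suitability-change categories over a park mask
#'
#' Tallies cell categories over the park's cells, excluding cells `absent` in
#' both periods, and assigns the park the category with the largest count;
#' ties are broken by `tie_order`. If every cell is absent the species gets
#' no projection for the park (majority `NA`).
#'
#' @param cell_categories Character matrix from [classify_cell()].
#' @param mask Integer vector of 0-based row-major cell indices, or a list
#'   with a `cells` element.
#' @param tie_order Priority order for ties; see [default_tie_order()].
#' @return List with `counts` (named counts over all six categories),
#'   `majority` (category or `NA`), and `present_current` / `present_future`
#'   logicals per the presence rule (see [derive_presence()]).
#' @export
summarize_park <- function(cell_categories, mask,
                           tie_order = default_tie_order()) {
  cells <- if (is.list(mask)) mask$cells else mask
  if (length(cells) == 0) stop("park mask is empty")
  nr <- nrow(cell_categories)
  nc <- ncol(cell_categories)
  if (any(cells < 0 | cells >= nr * nc))
    stop("park mask references cells outside the grid")
  if (!setequal(tie_order, setdiff(change_categories(), "absent")))
    stop("tie_order must be a permutation of the five change categories")
  vals <- cell_categories[cell_linear_index(cells, nr, nc)]
  counts <- table(factor(vals, levels = change_categories()))
  counts <- stats::setNames(as.integer(counts), names(counts))
  voting <- counts[tie_order]
  if (sum(voting) == 0L)
    return(list(counts = counts, majority = NA_character_,
                present_current = FALSE, present_future = FALSE))
  majority <- tie_order[which.max(voting)]  # first max in priority order
  pres <- derive_presence(majority)
  list(counts = counts, majority = majority,
       present_current = pres$present_current,
       present_future = pres$present_future)
}

#' Presence in each period implied by a park's majority category
#'
#' A species is present in the baseline period when its park majority is
#' extirpation, worsening, stable or improving, and present under the
#' scenario when it is worsening, stable, improving or colonisation.
#'
#' @param majority Character vector of majority categories.
#' @return List with logical vectors `present_current` and `present_future`.
#' @export
derive_presence <- function(majority) {
  if (any(is.na(majority) | !majority %in% change_categories()))
    stop("majority must be one of the change categories")
  list(
    present_current = majority %in% c("potential_extirpation", "worsening",
                                      "stable", "improving"),
    present_future = majority %in% c("worsening", "stable", "improving",
                                     "potential_colonisation")
  )
}

#' Project all species onto all parks
#'
#' Runs [classify_cell()] per species/season surface pair and
#' [summarize_park()] per park, returning one record per species x park x
#' season where the species occupies at least one park cell in at least one
#' period.
#'
#' @param dataset A dataset as produced by [generate_landscape()] or
#'   [read_dataset()].
#' @param tie_order Majority tie-break order.
#' @return Data frame with columns `park_id`, `species_id`, `season`,
#'   per-category cell counts (`n_absent`, `n_potential_extirpation`, ...),
#'   `majority`, `present_current`, `present_future`.
#' @export
project_parks <- function(dataset, tie_order = default_tie_order()) {
  rows <- list()
  k <- 0L
  for (season in dataset$seasons) {
    for (sp in dataset$species) {
      surf <- dataset$surfaces[[season]][[sp]]
      cats <- classify_cell(surf$baseline, surf$scenario,
                            dataset$thresholds[[sp]])
      for (pk in names(dataset$parks)) {
        s <- summarize_park(cats, dataset$parks[[pk]], tie_order)
        if (is.na(s$majority)) next
        k <- k + 1L
        rows[[k]] <- data.frame(
          park_id = pk, species_id = sp, season = season,
          t(s$counts), majority = s$majority,
          present_current = s$present_current,
          present_future = s$present_future,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(park_id = character(), species_id = character(),
                      season = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  names(out)[match(change_categories(), names(out))] <-
    paste0("n_", change_categories())
  rownames(out) <- NULL
  out
}

#' Apply expert-review filters to park projections
#'
#' `unconfirmed_baseline` flags mark species x park x season records whose
#' baseline presence could not be confirmed against contemporary park lists
#' (transients, migrants, accidentals); such records are dropped entirely
#' unless their majority is `potential_colonisation` (no baseline presence to
#' remove), which triggers a warning instead. `improbable_colonisation` flags
#' remove records whose majority is `potential_colonisation`; on any other
#' majority the flag is incompatible and only warns.
#'
#' @param projections Data frame from [project_parks()].
#' @param review Data frame with columns `species_id`, `park_id`, `season`,
#'   `flag`; `NULL` or zero rows passes everything through.
#' @return List with `projections` (the filtered data frame) and `removals`,
#'   a data frame reporting per flag class the number flagged, number removed
#'   and fraction of input records removed.
#' @export
apply_review_filters <- function(projections, review) {
  flags <- c("unconfirmed_baseline", "improbable_colonisation")
  removals <- data.frame(flag = flags, n_flagged = 0L, n_removed = 0L,
                         fraction_removed = 0, stringsAsFactors = FALSE)
  if (is.null(review) || nrow(review) == 0)
    return(list(projections = projections, removals = removals))
  if (!all(review$flag %in% flags))
    stop("unknown review flag: ",
         paste(setdiff(review$flag, flags), collapse = ", "))
  rkey <- paste(review$species_id, review$park_id, review$season)
  if (anyDuplicated(rkey))
    warning("duplicate review-table keys; later rows are redundant")
  key <- paste(projections$species_id, projections$park_id,
               projections$season)
  keep <- rep(TRUE, nrow(projections))
  for (i in seq_len(nrow(review))) {
    j <- match(rkey[i], key)
    fl <- review$flag[i]
    removals$n_flagged[removals$flag == fl] <-
      removals$n_flagged[removals$flag == fl] + 1L
    if (is.na(j)) {
      warning("review flag references a record with no projection: ",
              rkey[i])
      next
    }
    is_col <- projections$majority[j] == "potential_colonisation"
    if (fl == "unconfirmed_baseline") {
      if (is_col) {
        warning("unconfirmed_baseline flag on a potential_colonisation ",
                "record (no baseline presence); not removed: ", rkey[i])
      } else {
        keep[j] <- FALSE
        removals$n_removed[1L] <- removals$n_removed[1L] + 1L
      }
    } else {
      if (!is_col) {
        warning("improbable_colonisation flag on a ",
                projections$majority[j], " record; not removed: ", rkey[i])
      } else {
        keep[j] <- FALSE
        removals$n_removed[2L] <- removals$n_removed[2L] + 1L
      }
    }
  }
  removals$fraction_removed <- removals$n_removed / nrow(projections)
  list(projections = projections[keep, , drop = FALSE], removals = removals)
}
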