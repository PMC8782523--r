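#' Pipeline configuration
#'
#' Collects every analysis convention in one place: input/output locations,
#' seasons, number of functional axes, parks excluded from functional
#' analyses, the majority tie order, trend-sector denominators, permutation
#' count and seed. Either build it programmatically or load a YAML file with
#' the same field names via `file =`.
#'
#' @param input Dataset directory (layout of [write_dataset()]). May be
#'   `NULL` when a dataset object is passed to [run_pipeline()] directly.
#' @param output Output directory for the report tables.
#' @param seasons Seasons to run.
#' @param n_axes Functional axes (>= 2 for the pipeline).
#' @param exclude_parks Parks left out of functional richness/dispersion.
#' @param tie_order Majority tie-break priority.
#' @param denominators Trend-proportion denominators
#'   (see [classify_trend_groups()]).
#' @param n_perm Permutations for the regression tests (>= 99).
#' @param correction Dissimilarity correction for the functional space.
#' @param seed Integer seed used for all pipeline randomness.
#' @param file Optional YAML file whose fields override the defaults.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, output = NULL,
                            seasons = c("summer", "winter"), n_axes = 6L,
                            exclude_parks = character(),
                            tie_order = default_tie_order(),
                            denominators = c(colonisation = "future",
                                             extirpation = "current"),
                            n_perm = 999L, correction = "sqrt", seed = 1L,
                            file = NULL) {
  cfg <- list(input = input, output = output, seasons = seasons,
              n_axes = as.integer(n_axes),
              exclude_parks = as.character(exclude_parks),
              tie_order = tie_order, denominators = denominators,
              n_perm = as.integer(n_perm), correction = correction,
              seed = as.integer(seed))
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    for (nm in intersect(names(y), names(cfg))) {
      v <- y[[nm]]
      cfg[[nm]] <- if (is.list(v)) unlist(v) else v
    }
    cfg$n_axes <- as.integer(cfg$n_axes)
    cfg$n_perm <- as.integer(cfg$n_perm)
    cfg$seed <- as.integer(cfg$seed)
  }
  if (cfg$n_axes < 2) stop("n_axes must be at least 2")
  if (cfg$n_perm < 99) stop("n_perm must be at least 99")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate pipeline inputs
#'
#' Non-mutating checks: shared grid shape and `[0, 1]` range across all
#' surfaces, thresholds in (0, 1), both periods present per species/season,
#' park masks non-empty and in bounds, every park mapped to a region, trait
#' rows for every species, review-table referential integrity. Issues are
#' reported, not thrown; `severity == "fatal"` rows abort [run_pipeline()].
#'
#' @param dataset An `assemblage_dataset`.
#' @return Data frame with columns `severity` (`"fatal"`/`"warning"`) and
#'   `message`; zero rows when fully consistent.
#' @export
validate_inputs <- function(dataset) {
  issues <- list()
  add <- function(severity, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, message = message, stringsAsFactors = FALSE)
  nr <- dataset$grid[["rows"]]
  nc <- dataset$grid[["cols"]]
  for (season in dataset$seasons) {
    for (sp in dataset$species) {
      surf <- dataset$surfaces[[season]][[sp]]
      for (period in c("baseline", "scenario")) {
        m <- surf[[period]]
        if (is.null(m)) {
          add("fatal", paste0("missing ", period, " surface for ", sp, "/",
                              season))
          next
        }
        if (!identical(dim(m), c(nr, nc)))
          add("fatal", paste0("surface ", sp, "/", season, "/", period,
                              " does not match the shared grid"))
        if (any(!is.finite(m)))
          add("fatal", paste0("non-finite suitability in ", sp, "/", season,
                              "/", period))
        else if (any(m < 0 | m > 1))
          add("fatal", paste0("suitability outside [0, 1] in ", sp, "/",
                              season, "/", period))
      }
    }
  }
  bad_thr <- dataset$thresholds <= 0 | dataset$thresholds >= 1
  if (any(bad_thr))
    add("fatal", paste0("thresholds outside (0, 1) for: ",
                        paste(names(dataset$thresholds)[bad_thr],
                              collapse = ", ")))
  for (pk in names(dataset$parks)) {
    cells <- dataset$parks[[pk]]$cells
    if (length(cells) == 0)
      add("fatal", paste0("park ", pk, " rasterizes to zero cells"))
    else if (any(cells < 0 | cells >= nr * nc))
      add("fatal", paste0("park ", pk, " has cells outside the grid"))
  }
  unmapped <- setdiff(names(dataset$parks), names(dataset$regions))
  if (length(unmapped) > 0)
    add("fatal", paste0("parks without a region: ",
                        paste(unmapped, collapse = ", ")))
  no_traits <- setdiff(dataset$species, dataset$traits$species_id)
  if (length(no_traits) > 0)
    add("fatal", paste0("species missing from the trait table: ",
                        paste(no_traits, collapse = ", ")))
  if (!is.null(dataset$review) && nrow(dataset$review) > 0) {
    bad_sp <- setdiff(dataset$review$species_id, dataset$species)
    if (length(bad_sp) > 0)
      add("warning", paste0("review table references unknown species: ",
                            paste(unique(bad_sp), collapse = ", ")))
    bad_pk <- setdiff(dataset$review$park_id, names(dataset$parks))
    if (length(bad_pk) > 0)
      add("warning", paste0("review table references unknown parks: ",
                            paste(unique(bad_pk), collapse = ", ")))
    key <- paste(dataset$review$species_id, dataset$review$park_id,
                 dataset$review$season)
    if (anyDuplicated(key))
      add("warning", "review table has duplicate keys")
  }
  if (length(issues) == 0)
    return(data.frame(severity = character(), message = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

#' Run the full projection pipeline
#'
#' Orchestrates, per season: cell classification and park majority
#' projection, expert-review filtering, assemblage metrics, trend groups,
#' regional summaries, functional spaces and indices, taxon restrictedness,
#' and the major-axis regression table comparing future against current
#' values of SpRich, FRic, FDis and TRes. Writes six CSV tables plus a JSON
#' run report (record counts, removal fractions, warnings, seed, config
#' hash, output manifest with checksums) into `config$output`.
#'
#' @param config A [pipeline_config()].
#' @param dataset Optional `assemblage_dataset`; when `NULL` it is read from
#'   `config$input`.
#' @return Object of class `run_report` (invisibly the same list written to
#'   `run_report.json`).
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dataset)) {
    if (is.null(config$input)) stop("no dataset and no input directory")
    dataset <- read_dataset(config$input)
  }
  if (is.null(config$output)) stop("config$output must be set")
  warnings_log <- character()
  run <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        warnings_log[[length(warnings_log) + 1L]] <<-
          paste0(stage, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  dataset$seasons <- intersect(dataset$seasons, config$seasons)
  validation <- run("validate", validate_inputs(dataset))
  if (any(validation$severity == "fatal"))
    stop("stage validate: fatal input issues:\n  ",
         paste(validation$message[validation$severity == "fatal"],
               collapse = "\n  "))
  for (msg in validation$message)
    warnings_log[[length(warnings_log) + 1L]] <- paste0("validate: ", msg)

  projections <- run("project", project_parks(dataset, config$tie_order))
  filt <- run("review_filter",
              apply_review_filters(projections, dataset$review))
  pairs <- run("assemblages", assemblage_pairs(filt$projections))
  trends <- run("trend_groups",
                classify_trend_groups(pairs, config$denominators))
  regional <- run("regional_summary",
                  summarize_regions(pairs, dataset$regions))
  fi <- run("functional_indices",
            functional_indices(filt$projections, dataset$traits,
                               n_axes = config$n_axes,
                               exclude_parks = config$exclude_parks,
                               correction = config$correction))
  tres <- run("restrictedness", {
    out <- list()
    for (season in dataset$seasons) {
      cur <- occurrence_matrix(filt$projections, season, "current",
                               parks = sort(names(dataset$parks)))
      fut <- occurrence_matrix(filt$projections, season, "future",
                               parks = sort(names(dataset$parks)))
      t1 <- taxon_restrictedness(cur, fut)
      t1$season <- rep(season, nrow(t1))
      out[[season]] <- t1
    }
    do.call(rbind, out)
  })
  rownames(tres) <- NULL

  reg_values <- run("regressions", {
    v <- list()
    # SpRich / FRic / FDis across parks, from the functional-index table
    idx <- fi$indices
    if (nrow(idx) > 0) {
      wide <- function(col, label) {
        cur <- idx[idx$period == "current", c("park_id", "season", col)]
        fut <- idx[idx$period == "future", c("park_id", "season", col)]
        m <- merge(cur, fut, by = c("park_id", "season"),
                   suffixes = c("_cur", "_fut"))
        data.frame(index = label, season = m$season,
                   current = m[[paste0(col, "_cur")]],
                   future = m[[paste0(col, "_fut")]],
                   stringsAsFactors = FALSE)
      }
      v$sprich <- wide("sp_rich", "SpRich")
      v$fric <- wide("fric", "FRic")
      v$fdis <- wide("fdis_scaled", "FDis")
    }
    if (nrow(tres) > 0) {
      cur <- tres[tres$period == "current", ]
      fut <- tres[tres$period == "future", ]
      m <- merge(cur, fut, by = c("species_id", "season"),
                 suffixes = c("_cur", "_fut"))
      v$tres <- data.frame(index = "TRes", season = m$season,
                           current = m$tres_cur, future = m$tres_fut,
                           stringsAsFactors = FALSE)
    }
    do.call(rbind, v)
  })
  regression <- run("regressions",
                    ma_regression_table(reg_values, n_perm = config$n_perm,
                                        seed = config$seed))

  dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
  outputs <- c(projections = "projections.csv",
               trend_groups = "trend_groups.csv",
               regional_summary = "regional_summary.csv",
               functional_indices = "functional_indices.csv",
               restrictedness = "restrictedness.csv",
               regression_table = "regression_table.csv")
  write_csv_lf(filt$projections, file.path(config$output, outputs[[1]]))
  write_csv_lf(trends, file.path(config$output, outputs[[2]]))
  write_csv_lf(regional, file.path(config$output, outputs[[3]]))
  write_csv_lf(fi$indices, file.path(config$output, outputs[[4]]))
  write_csv_lf(tres, file.path(config$output, outputs[[5]]))
  write_csv_lf(regression, file.path(config$output, outputs[[6]]))

  cfg_txt <- paste(deparse(config[setdiff(names(config), c("input",
                                                           "output"))]),
                   collapse = "\n")
  tmp <- tempfile()
  writeLines(cfg_txt, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- lapply(unname(outputs), function(f)
    list(file = f,
         md5 = unname(tools::md5sum(file.path(config$output, f)))))
  msd <- lapply(fi$spaces, function(s) s$msd)
  report <- structure(list(
    seed = config$seed,
    config_hash = cfg_hash,
    seasons = dataset$seasons,
    record_counts = list(
      projections_raw = nrow(projections),
      projections_filtered = nrow(filt$projections),
      assemblage_pairs = nrow(pairs),
      functional_indices = nrow(fi$indices),
      restrictedness = nrow(tres),
      regressions = nrow(regression)),
    removal_fractions = stats::setNames(
      as.list(filt$removals$fraction_removed), filt$removals$flag),
    space_msd = msd,
    warnings = warnings_log,
    outputs = manifest), class = "run_report")
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  con <- file(file.path(config$output, "run_report.json"), "wb")
  writeLines(json, con)
  close(con)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (seed", x$seed, ")\n")
  cat("  seasons:", paste(x$seasons, collapse = ", "), "\n")
  cat("  records:", x$record_counts$projections_raw, "projected,",
      x$record_counts$projections_filtered, "after review filters\n")
  cat("  removal fractions:",
      paste(sprintf("%s=%.3f", names(x$removal_fractions),
                    unlist(x$removal_fractions)), collapse = ", "), "\n")
  cat("  warnings:", length(x$warnings), "\n")
  cat("  outputs:", length(x$outputs), "files\n")
  invisible(x)
}
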