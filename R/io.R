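#' Read and write headered text grids
#'
#' Suitability surfaces are stored as plain text: a first line with the row
#' and column counts, then one whitespace-delimited line per grid row.
#' Values round-trip at full double precision.
#'
#' @param surface Numeric matrix of suitability values.
#' @param path File path.
#' @return `read_surface` returns the matrix; `write_surface` returns the
#'   path invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(is.matrix(surface), is.numeric(surface))
  con <- file(path, "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(c(paste(nrow(surface), ncol(surface)),
               apply(surface, 1, function(r)
                 paste(sprintf("%.17g", r), collapse = " "))),
             con)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  hdr <- scan(path, what = integer(), n = 2, quiet = TRUE)
  vals <- scan(path, what = double(), skip = 1, quiet = TRUE)
  if (length(vals) != hdr[1] * hdr[2])
    stop("grid file ", path, " does not match its header dimensions")
  matrix(vals, nrow = hdr[1], ncol = hdr[2], byrow = TRUE)
}

write_csv_lf <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a dataset to the pipeline's on-disk input layout
#'
#' Layout: `surfaces/<species>_<season>_<period>.txt` text grids with a
#' `manifest.csv` (species_id, season, period, threshold, file),
#' `parks.csv` (park_id, cell: 0-based row-major indices), `regions.csv`,
#' `traits.csv`, `review.csv` and `dataset.yaml` (grid dimensions, seasons,
#' size-level order, seed).
#'
#' @param dataset An `assemblage_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "surfaces"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- list()
  k <- 0L
  for (season in dataset$seasons) {
    for (sp in dataset$species) {
      for (period in c("baseline", "scenario")) {
        f <- file.path("surfaces", paste0(sp, "_", season, "_", period,
                                          ".txt"))
        write_surface(dataset$surfaces[[season]][[sp]][[period]],
                      file.path(dir, f))
        k <- k + 1L
        manifest[[k]] <- data.frame(
          species_id = sp, season = season, period = period,
          threshold = dataset$thresholds[[sp]], file = f,
          stringsAsFactors = FALSE)
      }
    }
  }
  write_csv_lf(do.call(rbind, manifest), file.path(dir, "manifest.csv"))
  parks <- do.call(rbind, lapply(names(dataset$parks), function(pk)
    data.frame(park_id = pk, cell = dataset$parks[[pk]]$cells,
               stringsAsFactors = FALSE)))
  write_csv_lf(parks, file.path(dir, "parks.csv"))
  write_csv_lf(data.frame(park_id = names(dataset$regions),
                          region = unname(dataset$regions),
                          stringsAsFactors = FALSE),
               file.path(dir, "regions.csv"))
  tr <- dataset$traits
  tr$relative_size <- as.character(tr$relative_size)
  write_csv_lf(tr, file.path(dir, "traits.csv"))
  review <- dataset$review
  if (is.null(review))
    review <- data.frame(species_id = character(), park_id = character(),
                         season = character(), flag = character())
  write_csv_lf(review, file.path(dir, "review.csv"))
  meta <- list(grid_rows = unname(dataset$grid[["rows"]]),
               grid_cols = unname(dataset$grid[["cols"]]),
               seasons = as.list(dataset$seasons),
               size_levels = as.list(size_levels()))
  if (!is.null(dataset$config)) meta$seed <- dataset$config$seed
  writeLines(yaml::as.yaml(meta), file.path(dir, "dataset.yaml"))
  invisible(dir)
}

#' Read a dataset from the on-disk input layout
#'
#' Inverse of [write_dataset()]; ground-truth assemblages are not stored on
#' disk and come back `NULL`.
#'
#' @param dir Dataset directory.
#' @return An `assemblage_dataset`.
#' @export
read_dataset <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "dataset.yaml"))
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  seasons <- unlist(meta$seasons)
  species <- sort(unique(manifest$species_id))
  surfaces <- list()
  for (season in seasons) {
    surfaces[[season]] <- list()
    for (sp in species) {
      rows <- manifest[manifest$species_id == sp &
                         manifest$season == season, , drop = FALSE]
      surfaces[[season]][[sp]] <- list()
      for (i in seq_len(nrow(rows)))
        surfaces[[season]][[sp]][[rows$period[i]]] <-
          read_surface(file.path(dir, rows$file[i]))
    }
  }
  thresholds <- tapply(manifest$threshold, manifest$species_id,
                       function(v) v[1])
  thresholds <- stats::setNames(as.numeric(thresholds[species]), species)
  parks_df <- read.csv(file.path(dir, "parks.csv"), stringsAsFactors = FALSE)
  parks <- lapply(split(parks_df$cell, parks_df$park_id),
                  function(x) list(cells = as.integer(sort(x))))
  regions_df <- read.csv(file.path(dir, "regions.csv"),
                         stringsAsFactors = FALSE)
  regions <- stats::setNames(regions_df$region, regions_df$park_id)
  traits <- read.csv(file.path(dir, "traits.csv"), stringsAsFactors = FALSE)
  if ("relative_size" %in% names(traits))
    traits$relative_size <- factor(traits$relative_size,
                                   levels = unlist(meta$size_levels),
                                   ordered = TRUE)
  review <- read.csv(file.path(dir, "review.csv"), stringsAsFactors = FALSE)
  structure(list(
    grid = c(rows = meta$grid_rows, cols = meta$grid_cols),
    seasons = seasons, species = species, surfaces = surfaces,
    thresholds = thresholds, parks = parks, regions = regions,
    traits = traits, review = review, truth = NULL, config = NULL),
    class = "assemblage_dataset")
}
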