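#' Configuration for a synthetic landscape
#'
#' Describes a rectangular grid with a purely latitudinal (row-wise)
#' environmental gradient. Each species gets a Gaussian niche along the
#' gradient; the warming scenario displaces the gradient northwards by
#' `shift_cells` rows, so that scenario suitability at row `r` equals
#' baseline suitability at row `r - shift_cells` (before noise). Parks are
#' disjoint axis-aligned rectangles.
#'
#' @param grid_rows,grid_cols Grid dimensions in cells (>= 4).
#' @param n_species Number of species (>= 2).
#' @param n_parks Number of parks; they must fit disjointly on the grid.
#' @param shift_cells Signed northward displacement of the gradient under the
#'   scenario, in rows.
#' @param response_width Gaussian niche breadth, in rows.
#' @param noise_sd Standard deviation of i.i.d. Gaussian suitability noise;
#'   surfaces are clipped to `[0, 1]` afterwards.
#' @param threshold Occurrence threshold in (0, 1) shared by all synthetic
#'   species (the pipeline itself supports per-species thresholds).
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   dataset.
#' @param seasons Season labels; each species gets an independent niche
#'   optimum per season.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(grid_rows = 40L, grid_cols = 30L,
                             n_species = 30L, n_parks = 8L,
                             shift_cells = 6L, response_width = 6,
                             noise_sd = 0.05, threshold = 0.35,
                             seed = 1L, seasons = c("summer", "winter")) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              n_species = as.integer(n_species),
              n_parks = as.integer(n_parks),
              shift_cells = as.integer(shift_cells),
              response_width = as.numeric(response_width),
              noise_sd = as.numeric(noise_sd),
              threshold = as.numeric(threshold),
              seed = as.integer(seed),
              seasons = as.character(seasons))
  if (cfg$grid_rows < 4 || cfg$grid_cols < 4)
    stop("grid dimensions must be at least 4 cells")
  if (cfg$n_species < 2) stop("need at least 2 species")
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop("threshold must lie in (0, 1)")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$response_width <= 0) stop("response_width must be positive")
  if (cfg$n_parks < 1) stop("need at least 1 park")
  class(cfg) <- "landscape_config"
  cfg
}

# Park placement: partition the grid into blocks of at least 6x6 cells and
# drop one 3-5 cell rectangle into each of n_parks randomly chosen blocks.
# Guarantees disjoint masks; errors when the grid has too few blocks.
place_parks <- function(cfg) {
  kr <- cfg$grid_rows %/% 6L
  kc <- cfg$grid_cols %/% 6L
  if (kr * kc < cfg$n_parks)
    stop("parks cannot be placed disjointly: grid of ", cfg$grid_rows, "x",
         cfg$grid_cols, " holds at most ", kr * kc, " parks")
  blocks <- sample.int(kr * kc, cfg$n_parks)
  parks <- list()
  for (i in seq_len(cfg$n_parks)) {
    bi <- (blocks[i] - 1L) %/% kc  # block row, 0-based
    bj <- (blocks[i] - 1L) %% kc
    h <- sample(3:5, 1L)
    w <- sample(3:5, 1L)
    r0 <- bi * 6L + sample.int(6L - h, 1L) - 1L
    c0 <- bj * 6L + sample.int(6L - w, 1L) - 1L
    rows <- r0 + seq_len(h) - 1L
    cols <- c0 + seq_len(w) - 1L
    cells <- as.integer(outer(rows * cfg$grid_cols, cols, "+"))
    parks[[sprintf("park%02d", i)]] <- sort(cells)
  }
  parks
}

gaussian_surface <- function(cfg, mu, shift, noise_sd) {
  g <- seq_len(cfg$grid_rows) - shift
  s <- exp(-(g - mu)^2 / (2 * cfg$response_width^2))
  m <- matrix(rep(s, cfg$grid_cols), nrow = cfg$grid_rows)
  if (noise_sd > 0)
    m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow = nrow(m))
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

#' Generate a synthetic landscape dataset with known ground truth
#'
#' Produces per-species baseline and scenario suitability surfaces per
#' season, disjoint rectangular parks with region labels, a mixed-type trait
#' table, an expert-review flag table, and the ground-truth assemblages
#' computed by the independent brute-force oracle
#' ([oracle_assemblages()]).
#'
#' Review flags are sampled at the rates typical of expert screening of
#' model output: by default 17\% of records flagged as unconfirmed baseline
#' presences and 3.2\% as improbable colonisations.
#'
#' @param config A [landscape_config()].
#' @param review_fractions Named numeric vector with elements
#'   `unconfirmed_baseline` and `improbable_colonisation`: fractions of all
#'   projection records to flag (capped at the number of compatible records).
#' @return A list of class `assemblage_dataset` with elements `grid`,
#'   `seasons`, `species`, `surfaces`, `thresholds`, `parks`, `regions`,
#'   `traits`, `review`, `truth` and `config`.
#' @examples
#' d <- generate_landscape(landscape_config(seed = 7))
#' str(d$parks[1])
#' @export
generate_landscape <- function(config,
                               review_fractions = c(
                                 unconfirmed_baseline = 0.17,
                                 improbable_colonisation = 0.032)) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  species <- sprintf("sp%03d", seq_len(config$n_species))
  parks <- place_parks(config)
  # region label from park centroid latitude (row) tercile
  cent <- vapply(parks, function(cl) mean(cl %/% config$grid_cols), 0)
  breaks <- stats::quantile(cent, c(1 / 3, 2 / 3), type = 7)
  regions <- ifelse(cent <= breaks[1], "south",
                    ifelse(cent <= breaks[2], "central", "north"))
  names(regions) <- names(parks)

  surfaces <- list()
  for (season in config$seasons) {
    mu <- stats::runif(config$n_species, 1, config$grid_rows)
    surfaces[[season]] <- list()
    for (i in seq_along(species)) {
      surfaces[[season]][[species[i]]] <- list(
        baseline = gaussian_surface(config, mu[i], 0, config$noise_sd),
        scenario = gaussian_surface(config, mu[i], config$shift_cells,
                                    config$noise_sd))
    }
  }
  thresholds <- stats::setNames(rep(config$threshold, config$n_species),
                                species)
  traits <- generate_trait_table(config$n_species, seed = config$seed + 1L)
  traits$species_id <- species

  dataset <- structure(list(
    grid = c(rows = config$grid_rows, cols = config$grid_cols),
    seasons = config$seasons, species = species, surfaces = surfaces,
    thresholds = thresholds, parks = lapply(parks, function(x) list(cells = x)),
    regions = regions, traits = traits, review = NULL, truth = NULL,
    config = config), class = "assemblage_dataset")
  dataset$truth <- oracle_assemblages(dataset)
  dataset$review <- generate_review_flags(dataset, review_fractions,
                                          seed = config$seed + 2L)
  dataset
}

#' Generate a synthetic species-by-trait table
#'
#' Five traits per species: feeding behavior, primary food type, preferred
#' habitat and nesting behavior as unordered categories, plus relative size
#' as an ordered factor (`very_small < small < medium < large < very_large`).
#' No missing values.
#'
#' @param n_species Number of species (>= 2; a single species leaves the
#'   downstream distance matrix undefined).
#' @param seed Integer seed.
#' @return Data frame with a `species_id` column and the five trait columns.
#' @export
generate_trait_table <- function(n_species, seed = 1L) {
  if (n_species < 2)
    stop("need at least 2 species: a trait distance matrix is undefined ",
         "for a single species")
  set.seed(seed)
  levs <- list(
    feeding_behavior = c("aerial_forager", "foliage_gleaner",
                         "ground_forager", "bark_forager", "probing"),
    primary_food = c("insects", "seeds", "fruit", "fish", "omnivore"),
    habitat = c("forest", "grassland", "wetland", "shoreline", "tundra"),
    nesting = c("ground", "shrub", "tree", "cavity", "cliff"))
  out <- data.frame(species_id = sprintf("sp%03d", seq_len(n_species)),
                    stringsAsFactors = FALSE)
  for (tr in names(levs))
    out[[tr]] <- sample(levs[[tr]], n_species, replace = TRUE)
  out$relative_size <- factor(
    sample(size_levels(), n_species, replace = TRUE),
    levels = size_levels(), ordered = TRUE)
  out
}

#' Ordered levels of the relative-size trait
#' @return Character vector of the five size levels, smallest first.
#' @export
size_levels <- function() {
  c("very_small", "small", "medium", "large", "very_large")
}

#' Sample an expert-review flag table for a synthetic dataset
#'
#' Flags are drawn from the records that can legitimately carry them:
#' `unconfirmed_baseline` from records with a non-colonisation majority,
#' `improbable_colonisation` from colonisation-majority records, using the
#' dataset's ground-truth projections.
#'
#' @param dataset An `assemblage_dataset` with a `truth` element.
#' @param fractions Named fractions of all records to flag per class.
#' @param seed Integer seed.
#' @return Review data frame (`species_id`, `park_id`, `season`, `flag`).
#' @export
generate_review_flags <- function(dataset,
                                  fractions = c(unconfirmed_baseline = 0.17,
                                                improbable_colonisation = 0.032),
                                  seed = 1L) {
  set.seed(seed)
  recs <- list()
  k <- 0L
  for (season in dataset$seasons) {
    tr <- dataset$truth[[season]]
    for (pk in names(tr)) {
      maj <- tr[[pk]]$majority
      if (length(maj) == 0) next
      k <- k + 1L
      recs[[k]] <- data.frame(species_id = names(maj), park_id = pk,
                              season = season, majority = unname(maj),
                              stringsAsFactors = FALSE)
    }
  }
  recs <- do.call(rbind, recs)
  n_total <- nrow(recs)
  out <- list()
  for (fl in names(fractions)) {
    compatible <- if (fl == "unconfirmed_baseline") {
      which(recs$majority != "potential_colonisation")
    } else {
      which(recs$majority == "potential_colonisation")
    }
    n_take <- min(length(compatible), round(fractions[[fl]] * n_total))
    if (n_take == 0) next
    pick <- sample(compatible, n_take)
    out[[fl]] <- data.frame(species_id = recs$species_id[pick],
                            park_id = recs$park_id[pick],
                            season = recs$season[pick], flag = fl,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(species_id = character(), park_id = character(),
                      season = character(), flag = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$season, out$park_id, out$species_id), , drop = FALSE]
}

#' Ground-truth park assemblages by exhaustive per-cell enumeration
#'
#' An independent oracle for testing: classifies every park cell one at a
#' time with scalar arithmetic (no shared code with [classify_cell()] /
#' [summarize_park()]), tallies the five categories, applies the majority
#' rule with the default tie order, and derives presence sets.
#'
#' @param dataset An `assemblage_dataset`.
#' @return Nested list: `truth[[season]][[park_id]]` holds `majority` (named
#'   character vector over species with at least one occupied cell),
#'   `current` and `future` (character vectors of species ids).
#' @export
oracle_assemblages <- function(dataset) {
  priority <- c(potential_extirpation = 1, potential_colonisation = 2,
                worsening = 3, improving = 4, stable = 5)
  nr <- dataset$grid[["rows"]]
  nc <- dataset$grid[["cols"]]
  truth <- list()
  for (season in dataset$seasons) {
    truth[[season]] <- list()
    for (pk in names(dataset$parks)) {
      cells <- dataset$parks[[pk]]$cells
      maj <- character(0)
      for (sp in dataset$species) {
        b <- dataset$surfaces[[season]][[sp]]$baseline
        s <- dataset$surfaces[[season]][[sp]]$scenario
        thr <- dataset$thresholds[[sp]]
        tally <- c(potential_extirpation = 0L, potential_colonisation = 0L,
                   worsening = 0L, improving = 0L, stable = 0L)
        for (cell in cells) {
          r <- cell %/% nc + 1L
          cc <- cell %% nc + 1L
          bv <- b[r, cc]
          sv <- s[r, cc]
          if (bv >= thr && sv < thr) {
            tally["potential_extirpation"] <-
              tally["potential_extirpation"] + 1L
          } else if (bv < thr && sv >= thr) {
            tally["potential_colonisation"] <-
              tally["potential_colonisation"] + 1L
          } else if (bv >= thr && sv >= thr) {
            d <- 100 * (sv - bv) / bv
            if (d < -25) {
              tally["worsening"] <- tally["worsening"] + 1L
            } else if (d > 25) {
              tally["improving"] <- tally["improving"] + 1L
            } else {
              tally["stable"] <- tally["stable"] + 1L
            }
          }  # both below threshold: no vote
        }
        if (sum(tally) == 0L) next
        best <- names(tally)[tally == max(tally)]
        best <- best[order(priority[best])][1]
        maj[sp] <- best
      }
      cur <- names(maj)[maj %in% c("potential_extirpation", "worsening",
                                   "stable", "improving")]
      fut <- names(maj)[maj %in% c("worsening", "stable", "improving",
                                   "potential_colonisation")]
      truth[[season]][[pk]] <- list(majority = maj, current = cur,
                                    future = fut)
    }
  }
  truth
}
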