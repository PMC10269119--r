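#' Build a synthetic-survey configuration
#'
#' Describes a camera-trap survey generator with known truth: grid count and
#' survey length, a guild-level latent co-occurrence structure (a
#' [natural_params()] object), and per-species detection intensity and diel
#' activity. Detection is a Poisson event process: at an occupied site each
#' species produces Poisson(lambda) events per day, each stamped with a time
#' drawn from the species' von Mises diel mixture; the implied per-occasion
#' guild detection probability is p_s = 1 - exp(-sum of member lambdas).
#'
#' @param n_grids Number of 1-km2 grids / stations (>= 5).
#' @param n_days Survey occasions (days), all stations concurrent.
#' @param f Guild-level [natural_params()]; guild names define the guilds.
#' @param species A tibble with columns `species`, `guild`, `lambda`
#'   (events per occupied site-day) and `diel` (list column, each element a
#'   data frame with `mean_angle`, `kappa`, `weight`; weights sum to 1).
#' @param start_date Deployment start (all stations).
#' @param seed Root seed; presence, event counts and event times use derived
#'   substreams so each stage is independently reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_grids, n_days, f, species,
                       start_date = as.Date("2015-12-01"), seed = 1) {
  stopifnot(inherits(f, "natural_params"))
  if (n_grids < 5) stop("n_grids must be at least 5")
  if (n_days < 1) stop("n_days must be at least 1")
  if (!all(c("species", "guild", "lambda", "diel") %in% names(species))) {
    stop("species table needs columns species, guild, lambda, diel")
  }
  if (any(species$lambda <= 0)) stop("lambda must be positive")
  if (!all(species$guild %in% f$guilds)) stop("species guild not in f$guilds")
  for (d in species$diel) {
    if (abs(sum(d$weight) - 1) > 1e-8) stop("diel mixture weights must sum to 1")
  }
  structure(list(n_grids = as.integer(n_grids), n_days = as.integer(n_days),
                 f = f, species = species, start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# derived substream seeds (kept below 2^31)
substream <- function(seed, k) as.integer((as.double(seed) * 7919 + k) %% 2147483647)

#' Study-conditions preset configuration
#'
#' The default generator emulates the survey the pipeline was designed for:
#' 88 one-km2 grids, 20 concurrent days, three guilds (prey, predator,
#' human). First-order natural parameters are solved deterministically so
#' the guild marginal occupancies are 0.78 / 0.42 / 0.38, with a positive
#' human-prey co-occurrence term (f = 1) and no human-predator or
#' prey-predator interaction. Species encounter rates are calibrated so
#' expected independent-capture counts match a realistic survey of this
#' effort (humans most frequent, leopard least). Diel presets: humans,
#' spotted deer and wild boar diurnal (unimodal, midday); tiger and sambar
#' deer nocturnal (unimodal, around 01:00); leopard and barking deer
#' crepuscular (bimodal at dawn and dusk).
#'
#' @param n_grids,n_days Survey dimensions (default 88 x 20).
#' @param seed Root seed.
#' @return A `sim_config`.
#' @export
sim_preset <- function(n_grids = 88, n_days = 20, seed = 1) {
  f2 <- c("prey:predator" = 0, "prey:human" = 1, "predator:human" = 0)
  f1 <- solve_marginal_f(c(prey = 0.78, predator = 0.42, human = 0.38), f2)
  f <- natural_params(f1, f2)
  hr <- function(h) 2 * pi * h / 24
  unimodal <- function(h, k) data.frame(mean_angle = hr(h), kappa = k, weight = 1)
  crep <- function(k) data.frame(mean_angle = hr(c(6, 18)), kappa = k, weight = c(0.5, 0.5))
  species <- tibble::tibble(
    species = c("human", "spotted deer", "wild boar", "barking deer",
                "sambar deer", "tiger", "leopard"),
    guild = c("human", "prey", "prey", "prey", "prey", "predator", "predator"),
    lambda = c(1.6, 0.35, 0.09, 0.09, 0.09, 0.11, 0.07),
    diel = list(unimodal(13, 3), unimodal(13, 3), unimodal(12, 2.5), crep(4),
                unimodal(1, 2), unimodal(1, 2), crep(4))
  )
  sim_config(n_grids, n_days, f, species, seed = seed)
}

#' Solve first-order parameters for target marginal occupancies
#'
#' Deterministic numerical inversion: finds f_s such that the multinomial-
#' logit state distribution (with the given second-order terms held fixed)
#' has the requested marginal occupancy for each guild.
#'
#' @param targets Named numeric vector of marginal occupancies in (0, 1).
#' @param second_order Named pairwise terms (as in [natural_params()]).
#' @return Named first-order vector.
#' @export
solve_marginal_f <- function(targets, second_order = NULL) {
  guilds <- names(targets)
  S <- length(guilds)
  states <- enumerate_states(S)
  marg <- function(f1) {
    p <- state_prob_vector(natural_params(stats::setNames(f1, guilds), second_order), states)
    vapply(seq_len(S), function(s) sum(p[states[, s] == 1]), numeric(1))
  }
  obj <- function(f1) sum((marg(f1) - targets)^2)
  opt <- stats::optim(stats::qlogis(targets), obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-16))
  if (opt$value > 1e-10) stop("marginal inversion failed to converge")
  stats::setNames(opt$par, guilds)
}

#' Simulate latent guild presence
#'
#' Each grid's presence vector is drawn independently from the state
#' distribution implied by the configuration's natural parameters.
#'
#' @param config A `sim_config`.
#' @return Integer matrix n_grids x S (columns = guilds), with the grid ids
#'   as row names.
#' @export
simulate_presence <- function(config) {
  S <- length(config$f$guilds)
  states <- enumerate_states(S)
  p <- state_prob_vector(config$f, states)
  set.seed(substream(config$seed, 1))
  idx <- sample.int(nrow(states), config$n_grids, replace = TRUE, prob = p)
  z <- states[idx, , drop = FALSE]
  dimnames(z) <- list(station_ids(config$n_grids), config$f$guilds)
  z
}

station_ids <- function(n) sprintf("S%03d", seq_len(n))
grid_labels <- function(n) sprintf("G%03d", seq_len(n))

#' Survey design implied by a configuration
#'
#' @param config A `sim_config`.
#' @return A design tibble (see [read_design()]), one station per grid.
#' @export
sim_design <- function(config) {
  tibble::tibble(station_id = station_ids(config$n_grids),
                 grid_label = grid_labels(config$n_grids),
                 start_date = config$start_date,
                 n_occasions = config$n_days)
}

#' Simulate timestamped detection records
#'
#' For every occupied (grid, species, day), the event count is
#' Poisson(lambda) and each event time is drawn from the species' diel von
#' Mises mixture (clustering event times within site-days around the
#' species' activity peaks). Unoccupied sites never yield events.
#'
#' @param z Presence matrix from [simulate_presence()].
#' @param config The same `sim_config`.
#' @return A record tibble sorted by timestamp, ready for [filter_independent()].
#' @export
simulate_events <- function(z, config) {
  set.seed(substream(config$seed, 2))
  sp <- config$species
  recs <- list()
  for (i in seq_len(nrow(sp))) {
    g <- match(sp$guild[i], colnames(z))
    occ <- which(z[, g] == 1L)
    if (length(occ) == 0) next
    counts <- stats::rpois(length(occ) * config$n_days, sp$lambda[i])
    total <- sum(counts)
    if (total == 0) next
    site_day <- tibble::tibble(
      station = rep(rep(rownames(z)[occ], each = config$n_days), times = counts),
      day = rep(rep(seq_len(config$n_days), times = length(occ)), times = counts)
    )
    mix <- sp$diel[[i]]
    comp <- sample.int(nrow(mix), total, replace = TRUE, prob = mix$weight)
    ang <- numeric(total)
    for (k in seq_len(nrow(mix))) {
      sel <- comp == k
      if (any(sel)) ang[sel] <- rvonmises(sum(sel), mix$mean_angle[k], mix$kappa[k])
    }
    secs <- floor(ang / (2 * pi) * 86400)
    ts <- as.POSIXct(config$start_date, tz = "UTC") +
      (site_day$day - 1) * 86400 + secs
    recs[[length(recs) + 1]] <- tibble::tibble(
      station_id = site_day$station, species = sp$species[i],
      timestamp = ts, camera_id = "C1")
  }
  if (length(recs) == 0) {
    return(tibble::tibble(station_id = character(), species = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          camera_id = character()))
  }
  out <- dplyr::bind_rows(recs)
  out <- out[sample.int(nrow(out)), ]  # shuffle, then timestamp order
  dplyr::arrange(out, .data$timestamp, .data$station_id, .data$species)
}

#' Simulate a full survey with known truth
#'
#' @param config A `sim_config` (default [sim_preset()]).
#' @return A list: `records` (tibble), `design` (tibble), `truth` (list with
#'   the presence matrix `z`, implied per-occasion guild detection
#'   probabilities `p`, and the `config`).
#' @export
simulate_survey <- function(config = sim_preset()) {
  z <- simulate_presence(config)
  records <- simulate_events(z, config)
  p <- vapply(config$f$guilds, function(g) {
    1 - exp(-sum(config$species$lambda[config$species$guild == g]))
  }, numeric(1))
  list(records = records, design = sim_design(config),
       truth = list(z = z, p = p, config = config))
}

#' Simulate detection histories directly from (f, p)
#'
#' Bypasses the event process: draws latent presence from the state
#' distribution and occasion-wise Bernoulli detections with fixed per-guild
#' p. Used for estimator-recovery studies where exact detection truth is
#' needed.
#'
#' @param f A [natural_params()].
#' @param p Named per-guild detection probabilities in (0, 1).
#' @param n_sites Number of sites.
#' @param n_occasions Occasions per site.
#' @param seed Integer seed.
#' @return Named list of site x occasion 0/1 matrices, one per guild.
#' @export
simulate_histories <- function(f, p, n_sites, n_occasions, seed = 1) {
  stopifnot(inherits(f, "natural_params"), all(p > 0 & p < 1))
  S <- length(f$guilds)
  states <- enumerate_states(S)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  idx <- sample.int(nrow(states), n_sites, replace = TRUE,
                    prob = state_prob_vector(f, states))
  z <- states[idx, , drop = FALSE]
  out <- lapply(seq_len(S), function(s) {
    det <- matrix(stats::rbinom(n_sites * n_occasions, 1, p[s]), n_sites)
    det * z[, s]
  })
  stats::setNames(out, f$guilds)
}

#' Write a synthetic survey to disk
#'
#' Writes `records.csv` and `design.csv` in the dialects read by
#' [read_records()] / [read_design()], plus `truth.json` holding the full
#' configuration and latent presence. Re-running with the same seed
#' reproduces the files byte for byte.
#'
#' @param config A `sim_config`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  sv <- simulate_survey(config)
  paths <- c(records = file.path(out_dir, "records.csv"),
             design = file.path(out_dir, "design.csv"),
             truth = file.path(out_dir, "truth.json"))
  rec <- sv$records
  rec$timestamp <- format(rec$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(rec, paths["records"])
  readr::write_csv(sv$design, paths["design"])
  truth <- list(
    config = list(n_grids = config$n_grids, n_days = config$n_days,
                  start_date = as.character(config$start_date),
                  seed = config$seed,
                  f = list(first_order = as.list(config$f$first_order),
                           second_order = as.list(config$f$second_order)),
                  species = lapply(seq_len(nrow(config$species)), function(i) {
                    list(species = config$species$species[i],
                         guild = config$species$guild[i],
                         lambda = config$species$lambda[i],
                         diel = config$species$diel[[i]])
                  })),
    p = as.list(sv$truth$p),
    z = apply(sv$truth$z, 2, as.integer, simplify = FALSE)
  )
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Rebuild a configuration from a truth JSON
#'
#' Inverse of the `truth.json` written by [write_fixture()].
#'
#' @param path Path to a truth JSON file.
#' @return A `sim_config`.
#' @export
read_truth_config <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = FALSE)
  cf <- tr$config
  f <- natural_params(unlist(cf$f$first_order),
                      if (length(cf$f$second_order) > 0) unlist(cf$f$second_order))
  species <- dplyr::bind_rows(lapply(cf$species, function(s) {
    tibble::tibble(species = s$species, guild = s$guild, lambda = s$lambda,
                   diel = list(dplyr::bind_rows(lapply(s$diel, tibble::as_tibble))))
  }))
  species$diel <- lapply(species$diel, as.data.frame)
  sim_config(cf$n_grids, cf$n_days, f, species,
             start_date = as.Date(cf$start_date), seed = cf$seed)
}
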