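#' Summarise survey effort and capture counts
#'
#' Trap-nights (the sum of station-occasions), per-species independent
#' capture counts and naive occupancies, and the grand capture total.
#'
#' @param design A survey-design tibble.
#' @param records An independence-filtered record tibble.
#' @return An `effort_summary` list: `trap_nights`, `per_species` (tibble
#'   with `species`, `n_captures`, `naive_occupancy`), `total_captures`.
#' @examples
#' design <- tibble::tibble(station_id = sprintf("S%02d", 1:88),
#'                          grid_label = sprintf("G%02d", 1:88),
#'                          start_date = as.Date("2015-12-01"), n_occasions = 20L)
#' summarize_effort(design, tibble::tibble(station_id = character(),
#'                                         species = character(),
#'                                         timestamp = as.POSIXct(character()),
#'                                         camera_id = character()))
#' @export
summarize_effort <- function(design, records) {
  validate_design(design)
  n_stations <- nrow(design)
  per_species <- records |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_captures = dplyr::n(),
                     naive_occupancy = dplyr::n_distinct(.data$station_id) / n_stations,
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_captures))
  structure(list(trap_nights = sum(design$n_occasions),
                 per_species = per_species,
                 total_captures = sum(per_species$n_captures)),
            class = "effort_summary")
}

#' @export
print.effort_summary <- function(x, ...) {
  cat("<effort_summary>", x$trap_nights, "trap-nights,",
      x$total_captures, "independent captures\n")
  print(x$per_species)
  invisible(x)
}

#' Assemble a pipeline configuration
#'
#' Either `records` + `design` (tibbles or file paths) or a `simulate`
#' configuration must be given. Defaults mirror the reference analysis: a
#' 15-minute independence window, MSOM fits with and without pairwise
#' interactions, human-vs-each-species activity pairs, and 1000 bootstrap
#' resamples.
#'
#' @param records,design Input tibbles or file paths (or `NULL` to simulate).
#' @param simulate A [sim_config()] used when no inputs are given.
#' @param guilds Guild map tibble.
#' @param window_minutes Independence window.
#' @param interaction_orders MSOM models to fit (subset of `c(1, 2)`).
#' @param activity_pairs Two-column data frame of species pairs, or `NULL`
#'   for human vs every other recorded species.
#' @param B Bootstrap resamples for activity and spatiotemporal stages.
#' @param seed Root seed.
#' @param st_unit Spatiotemporal bootstrap resampling unit.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(records = NULL, design = NULL, simulate = NULL,
                            guilds = guild_map(), window_minutes = 15,
                            interaction_orders = c(1, 2), activity_pairs = NULL,
                            B = 1000, seed = 1, st_unit = "grid") {
  if (is.null(simulate) && (is.null(records) || is.null(design))) {
    stop("either records + design or a simulate block is required")
  }
  if (B < 100) stop("B must be at least 100")
  structure(list(records = records, design = design, simulate = simulate,
                 guilds = guilds, window_minutes = window_minutes,
                 interaction_orders = interaction_orders,
                 activity_pairs = activity_pairs, B = as.integer(B),
                 seed = as.integer(seed), st_unit = st_unit),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `records`, `design` (paths), `simulate` (either
#' `preset: true` with optional `n_grids`, `n_days`, or a `truth` path),
#' `window_minutes`, `interaction_orders`, `activity_pairs` (list of
#' two-element lists), `B`, `seed`, `st_unit`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  simulate <- NULL
  if (!is.null(y$simulate)) {
    simulate <- if (!is.null(y$simulate$truth)) {
      read_truth_config(y$simulate$truth)
    } else {
      sim_preset(n_grids = y$simulate$n_grids %||% 88,
                 n_days = y$simulate$n_days %||% 20,
                 seed = y$simulate$seed %||% y$seed %||% 1)
    }
  }
  pairs <- NULL
  if (!is.null(y$activity_pairs)) {
    pairs <- dplyr::bind_rows(lapply(y$activity_pairs, function(p) {
      tibble::tibble(a = p[[1]], b = p[[2]])
    }))
  }
  pipeline_config(records = y$records, design = y$design, simulate = simulate,
                  window_minutes = y$window_minutes %||% 15,
                  interaction_orders = unlist(y$interaction_orders %||% c(1, 2)),
                  activity_pairs = pairs, B = y$B %||% 1000,
                  seed = y$seed %||% 1, st_unit = y$st_unit %||% "grid")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: independence filtering; effort summary and per-guild
#' naive occupancy; MSOM fits (with and without pairwise interactions) and
#' the AIC ranking; derived marginal/pairwise/conditional occupancy table;
#' diel-activity overlap per species pair with bootstrap intervals plus
#' plot-ready density grids; spatiotemporal overlap with grid-bootstrap
#' intervals and Venn region counts. All outputs are written under
#' `out_dir` with a manifest recording the seed, a configuration hash and
#' wall time. A stage failure aborts with the stage name; files already
#' written are left in place.
#'
#' @param config A `pipeline_config` or the path to a YAML file.
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(...)
  guilds <- config$guilds

  # -- inputs
  inp <- run_stage("input", {
    if (!is.null(config$simulate)) {
      sv <- simulate_survey(config$simulate)
      list(records = sv$records, design = sv$design, truth = sv$truth)
    } else {
      rec <- if (is.character(config$records)) read_records(config$records) else config$records
      des <- if (is.character(config$design)) read_design(config$design) else config$design
      list(records = rec, design = des, truth = NULL)
    }
  })
  say("input: ", nrow(inp$records), " raw records at ", nrow(inp$design), " stations")

  # -- independence filter
  filtered <- run_stage("filter",
    filter_independent(inp$records, window_minutes = config$window_minutes))
  say("filter: ", nrow(filtered), " independent events (window ",
      config$window_minutes, " min)")

  # -- effort + naive occupancy
  effort <- run_stage("effort", summarize_effort(inp$design, filtered))
  readr::write_csv(effort$per_species, file.path(out_dir, "effort.csv"))
  guild_names <- sort(unique(guilds$guild))
  histories <- run_stage("histories", {
    h <- lapply(guild_names, function(g)
      build_detection_history(filtered, inp$design, guilds, g))
    stats::setNames(h, guild_names)
  })
  naive <- tibble::tibble(guild = guild_names,
                          naive_occupancy = vapply(histories, naive_occupancy, numeric(1)))
  readr::write_csv(naive, file.path(out_dir, "naive_occupancy.csv"))
  say("effort: ", effort$trap_nights, " trap-nights, ",
      effort$total_captures, " independent captures")

  # -- MSOM fits + AIC
  fits <- run_stage("occupancy", {
    f <- lapply(config$interaction_orders, function(ord)
      fit_msom(histories, interaction_order = ord, seed = config$seed))
    stats::setNames(f, ifelse(config$interaction_orders == 2,
                              "pairwise_interaction", "no_interaction"))
  })
  ranking <- compare_models(fits)
  best <- fits[[ranking$model[1]]]
  fit_report <- lapply(fits, function(f) {
    list(guilds = f$spec$guild_names, interaction_order = f$spec$interaction_order,
         estimates = as.list(f$estimates), se = as.list(sqrt(diag(f$vcov))),
         vcov = f$vcov, loglik = f$loglik, aic = f$aic, n_params = f$n_params,
         convergence = f$convergence)
  })
  jsonlite::write_json(list(models = fit_report,
                            ranking = ranking),
                       file.path(out_dir, "msom_fits.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  occ <- run_stage("occupancy_estimates", occupancy_estimates(best, seed = config$seed))
  occ$seed <- config$seed
  readr::write_csv(occ, file.path(out_dir, "occupancy_estimates.csv"))
  say("occupancy: best model '", ranking$model[1], "' (AIC ",
      round(ranking$AIC[1], 1), ", dAIC next ", round(ranking$delta_aic[2] %||% NA, 1), ")")

  # -- diel activity overlap
  act <- run_stage("activity", {
    pairs <- config$activity_pairs
    if (is.null(pairs)) {
      sp <- effort$per_species$species
      others <- setdiff(sp[order(match(sp, guilds$species))], "human")
      others <- others[vapply(others, function(s)
        sum(filtered$species == s) >= 2, logical(1))]
      if (!"human" %in% sp || length(others) == 0) {
        tibble::tibble()
      } else {
        data.frame(a = "human", b = others)
      }
    } else pairs
  })
  if (is.data.frame(act) && nrow(act) > 0) {
    overlap_tbl <- run_stage("activity",
      activity_overlap(filtered, act, B = config$B, seed = config$seed))
    grids_tbl <- dplyr::bind_rows(lapply(seq_len(nrow(act)), function(i) {
      density_grid(time_to_radians(filtered$timestamp[filtered$species == act$a[i]]),
                   time_to_radians(filtered$timestamp[filtered$species == act$b[i]]),
                   labels = c(act$a[i], act$b[i]))
    }))
  } else {
    overlap_tbl <- tibble::tibble()
    grids_tbl <- tibble::tibble()
  }
  readr::write_csv(overlap_tbl, file.path(out_dir, "activity_overlap.csv"))
  readr::write_csv(grids_tbl, file.path(out_dir, "density_grids.csv"))
  say("activity: ", nrow(overlap_tbl), " species pairs")

  # -- spatiotemporal overlap
  st <- run_stage("spatiotemporal",
    bootstrap_spatiotemporal(filtered, inp$design, guilds, B = config$B,
                             seed = config$seed, unit = config$st_unit))
  readr::write_csv(st, file.path(out_dir, "spatiotemporal.csv"))
  venn <- run_stage("venn", {
    cells <- activity_cells(grid_hour_counts(filtered, inp$design, guilds))
    gn <- sort(unique(guilds$guild))
    if (length(gn) == 3) venn_regions(cells, gn) else tibble::tibble()
  })
  jsonlite::write_json(venn, file.path(out_dir, "venn_regions.json"),
                       auto_unbox = TRUE, digits = NA)
  say("spatiotemporal: ", nrow(st), " statistics over ",
      length(attr(activity_cells(grid_hour_counts(filtered, inp$design, guilds)),
                  "grids")), " grids")

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "guilds")]),
    package_version = as.character(utils::packageVersion("camshield")),
    r_version = as.character(getRversion()),
    trap_nights = effort$trap_nights,
    total_captures = effort$total_captures,
    n_raw_records = nrow(inp$records),
    n_independent = nrow(filtered),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(records = filtered, design = inp$design, truth = inp$truth,
                 effort = effort, naive = naive, histories = histories,
                 fits = fits, ranking = ranking, occupancy = occ,
                 activity = overlap_tbl, density_grids = grids_tbl,
                 spatiotemporal = st, venn = venn, manifest = manifest))
}
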