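#' Grid-by-hour detection counts per guild
#'
#' Builds the spatiotemporal detection matrix: for each guild, the number of
#' (independence-filtered) records at each grid in each hour-of-day bin
#' (floor of local clock hour, 24 bins), aggregated over the whole survey.
#' Records at stations absent from the design, or outside a station's
#' deployment window, are an error.
#'
#' @param records An independence-filtered record tibble.
#' @param design A survey-design tibble; `grid_label` maps stations to grids.
#' @param guilds A guild map; records of species outside the map are dropped.
#' @return A `grid_hour_counts` tibble with columns `guild`, `grid_label`,
#'   `hour` (0-23) and `n`, containing every guild x grid x hour combination
#'   (zeros included); attribute `grids` lists all design grids.
#' @export
grid_hour_counts <- function(records, design, guilds) {
  validate_design(design)
  unknown <- setdiff(unique(records$station_id), design$station_id)
  if (length(unknown) > 0) {
    stop("record(s) at station(s) absent from design: ", paste(unknown, collapse = ", "))
  }
  all_grids <- sort(unique(design$grid_label))
  rec <- dplyr::inner_join(records, guilds, by = "species") |>
    dplyr::left_join(design, by = "station_id")
  if (nrow(rec) > 0) {
    day <- as.integer(as.Date(rec$timestamp, tz = attr(rec$timestamp, "tzone") %||% "UTC") -
                        rec$start_date) + 1L
    outside <- day < 1L | day > rec$n_occasions
    if (any(outside)) {
      stop(sum(outside), " record(s) fall outside the deployment window")
    }
  }
  counted <- rec |>
    dplyr::mutate(hour = as.POSIXlt(.data$timestamp)$hour) |>
    dplyr::count(.data$guild, .data$grid_label, .data$hour)
  out <- tidyr::expand_grid(guild = sort(unique(guilds$guild)),
                            grid_label = all_grids, hour = 0:23) |>
    dplyr::left_join(counted, by = c("guild", "grid_label", "hour")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
  structure(out, grids = all_grids, class = c("grid_hour_counts", class(out)))
}

#' One guild's counts as a grids-by-24 matrix
#'
#' @param counts A [grid_hour_counts()] tibble.
#' @param guild Guild name.
#' @return An integer matrix, rows = grids, columns = hours 0-23.
#' @export
grid_hour_matrix <- function(counts, guild) {
  sub <- counts[counts$guild == guild, ]
  if (nrow(sub) == 0) stop("unknown guild: ", guild)
  grids <- attr(counts, "grids") %||% sort(unique(counts$grid_label))
  m <- matrix(0L, length(grids), 24, dimnames = list(grids, paste0("h", 0:23)))
  m[cbind(match(sub$grid_label, grids), sub$hour + 1L)] <- as.integer(sub$n)
  m
}

#' Active grid-hour cells
#'
#' Binarises the spatiotemporal counts: the set of (grid, hour) cells where
#' each guild was detected at least once. Idempotent.
#'
#' @param counts A [grid_hour_counts()] tibble (or its own output).
#' @return An `activity_cells` tibble with columns `guild`, `grid_label`,
#'   `hour`; attribute `grids` preserved.
#' @export
activity_cells <- function(counts) {
  out <- counts |>
    dplyr::filter(if ("n" %in% names(counts)) .data$n > 0 else TRUE) |>
    dplyr::distinct(.data$guild, .data$grid_label, .data$hour)
  structure(out, grids = attr(counts, "grids"),
            class = c("activity_cells", class(tibble::as_tibble(out))))
}

cell_keys <- function(cells, guild) {
  sub <- cells[cells$guild == guild, ]
  paste(sub$grid_label, sub$hour, sep = "\r")
}

st_row <- function(statistic, guilds, num, den) {
  tibble::tibble(statistic = statistic, guilds = guilds,
                 numerator = num, denominator = den,
                 proportion = if (den > 0) num / den else NA_real_)
}

#' Exclusive activity proportion of a guild
#'
#' The share of the focal guild's active (grid, hour) cells where no other
#' guild was active: |focal minus union(others)| / |focal|.
#'
#' @param cells An [activity_cells()] tibble.
#' @param focal Focal guild name.
#' @param others Other guild names; default all remaining guilds in `cells`.
#' @return A one-row tibble: statistic, guilds, numerator, denominator,
#'   proportion.
#' @export
exclusive_proportion <- function(cells, focal, others = NULL) {
  if (is.null(others)) others <- setdiff(unique(cells$guild), focal)
  a <- cell_keys(cells, focal)
  if (length(a) == 0) stop("focal guild has no active cells; proportion undefined")
  rest <- unique(unlist(lapply(others, cell_keys, cells = cells)))
  st_row("exclusive", focal, sum(!a %in% rest), length(a))
}

#' Pairwise spatiotemporal overlap of two guilds
#'
#' Jaccard overlap of the active-cell sets: |a intersect b| / |a union b|.
#'
#' @param cells An [activity_cells()] tibble.
#' @param a,b Guild names.
#' @return A one-row tibble as in [exclusive_proportion()].
#' @export
pairwise_overlap <- function(cells, a, b) {
  ka <- cell_keys(cells, a); kb <- cell_keys(cells, b)
  u <- union(ka, kb)
  if (length(u) == 0) stop("both guilds have empty cell sets")
  st_row("pairwise", paste(a, b, sep = ":"), length(intersect(ka, kb)), length(u))
}

#' Triple spatiotemporal overlap
#'
#' |a intersect b intersect c| / |a union b union c| over active cells.
#'
#' @param cells An [activity_cells()] tibble.
#' @param a,b,c Guild names; default the three guilds of `cells`.
#' @return A one-row tibble as in [exclusive_proportion()].
#' @export
triple_overlap <- function(cells, a, b, c) {
  ka <- cell_keys(cells, a); kb <- cell_keys(cells, b); kc <- cell_keys(cells, c)
  u <- union(union(ka, kb), kc)
  if (length(u) == 0) stop("all three guilds have empty cell sets")
  st_row("triple", paste(a, b, c, sep = ":"),
         length(intersect(intersect(ka, kb), kc)), length(u))
}

st_statistics <- function(cells, guild_names) {
  rows <- list()
  for (g in guild_names) {
    rows[[length(rows) + 1]] <- tryCatch(
      exclusive_proportion(cells, g, setdiff(guild_names, g)),
      error = function(e) st_row("exclusive", g, NA_integer_, 0L))
  }
  if (length(guild_names) >= 2) {
    prs <- utils::combn(guild_names, 2)
    for (j in seq_len(ncol(prs))) {
      rows[[length(rows) + 1]] <- tryCatch(
        pairwise_overlap(cells, prs[1, j], prs[2, j]),
        error = function(e) st_row("pairwise", paste(prs[1, j], prs[2, j], sep = ":"),
                                   NA_integer_, 0L))
    }
  }
  if (length(guild_names) == 3) {
    rows[[length(rows) + 1]] <- tryCatch(
      triple_overlap(cells, guild_names[1], guild_names[2], guild_names[3]),
      error = function(e) st_row("triple", paste(guild_names, collapse = ":"),
                                 NA_integer_, 0L))
  }
  dplyr::bind_rows(rows)
}

#' Counts of the seven Venn regions of three cell sets
#'
#' Partition of the union of three guilds' active cells into the seven
#' exclusive membership regions (a only, b only, c only, each pair only, all
#' three). Counts sum to |a union b union c|.
#'
#' @param cells An [activity_cells()] tibble.
#' @param guild_names The three guilds; default the guilds present.
#' @return A tibble with `region` (e.g. `"a_only"`, `"ab"`, `"abc"` spelt
#'   with guild names) and `count`.
#' @export
venn_regions <- function(cells, guild_names = NULL) {
  if (is.null(guild_names)) guild_names <- sort(unique(cells$guild))
  if (length(guild_names) != 3) stop("venn_regions needs exactly three guilds")
  keys <- lapply(guild_names, cell_keys, cells = cells)
  u <- unique(unlist(keys))
  member <- vapply(keys, function(k) u %in% k, logical(length(u)))
  if (length(u) == 0) member <- matrix(logical(0), 0, 3)
  pattern <- member %*% c(1, 2, 4)  # bitmask: 1 = first guild, ...
  masks <- 1:7
  region_name <- vapply(masks, function(m) {
    paste(guild_names[bitwAnd(m, c(1, 2, 4)) > 0], collapse = "&")
  }, character(1))
  tibble::tibble(region = region_name,
                 count = vapply(masks, function(m) sum(pattern == m), numeric(1)))
}

#' Bootstrap the spatiotemporal overlap summary
#'
#' Point estimates plus bootstrap standard errors and percentile confidence
#' intervals for the exclusive, pairwise and triple overlap statistics. The
#' resampling unit defaults to the grid (the independent spatial unit of the
#' design): grids are drawn with replacement and each draw carries the
#' grid's full record set as a new pseudo-grid. `"record"` resamples
#' individual records and `"grid_hour"` resamples active cells, for
#' sensitivity analysis.
#'
#' @param records Independence-filtered record tibble.
#' @param design Survey-design tibble.
#' @param guilds Guild map.
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param unit Resampling unit: `"grid"` (default), `"record"`, `"grid_hour"`.
#' @param conf_level Interval coverage.
#' @return An `overlap_summary` tibble: statistic, guilds, numerator,
#'   denominator, proportion, se, ci_low, ci_high, B, seed, unit.
#' @export
bootstrap_spatiotemporal <- function(records, design, guilds, B = 1000, seed = 1,
                                     unit = c("grid", "record", "grid_hour"),
                                     conf_level = 0.95) {
  unit <- match.arg(unit)
  if (B < 100) stop("B must be at least 100")
  counts <- grid_hour_counts(records, design, guilds)
  grids <- attr(counts, "grids")
  if (length(grids) < 5) stop("fewer than 5 grids: grid resampling is degenerate")
  guild_names <- sort(unique(guilds$guild))
  cells <- activity_cells(counts)
  point <- st_statistics(cells, guild_names)
  # per-grid cell lists for fast grid resampling
  per_grid <- lapply(guild_names, function(g) {
    sub <- cells[cells$guild == g, ]
    split(sub$hour, factor(sub$grid_label, levels = grids))
  })
  names(per_grid) <- guild_names
  set.seed(as.integer(seed) %% .Machine$integer.max)
  boots <- matrix(NA_real_, B, nrow(point))
  for (b in seq_len(B)) {
    if (unit == "grid") {
      draw <- sample.int(length(grids), replace = TRUE)
      cb <- dplyr::bind_rows(lapply(guild_names, function(g) {
        hrs <- per_grid[[g]][draw]
        len <- lengths(hrs)
        tibble::tibble(guild = g,
                       grid_label = rep(sprintf("bg%04d", seq_along(draw)), len),
                       hour = unlist(hrs, use.names = FALSE))
      }))
    } else if (unit == "record") {
      idx <- sample.int(nrow(records), replace = TRUE)
      cb <- activity_cells(grid_hour_counts(records[idx, ], design, guilds))
    } else {
      cb <- dplyr::slice_sample(tibble::as_tibble(cells), n = nrow(cells), replace = TRUE) |>
        dplyr::distinct()
    }
    stat_b <- st_statistics(cb, guild_names)  # fixed row order
    boots[b, ] <- stat_b$proportion
  }
  alpha <- 1 - conf_level
  point$se <- apply(boots, 2, stats::sd, na.rm = TRUE)
  point$ci_low <- apply(boots, 2, stats::quantile, probs = alpha / 2, na.rm = TRUE, names = FALSE)
  point$ci_high <- apply(boots, 2, stats::quantile, probs = 1 - alpha / 2, na.rm = TRUE, names = FALSE)
  point$B <- as.integer(B)
  point$seed <- as.integer(seed)
  point$unit <- unit
  class(point) <- c("overlap_summary", class(point))
  point
}
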