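#' Default species-to-guild map
#'
#' The analysis groups species into three detection units: a prey guild of
#' four ungulates, a predator guild of two large felids, and humans. Guild
#' membership drives detection-history construction and all guild-level
#' statistics; a species may belong to exactly one guild.
#'
#' @param prey,predator,human Character vectors of species names per guild.
#' @return A tibble with columns `species` and `guild`.
#' @examples
#' guild_map()
#' @export
guild_map <- function(prey = c("sambar deer", "spotted deer", "wild boar", "barking deer"),
                      predator = c("tiger", "leopard"),
                      human = "human") {
  gm <- dplyr::bind_rows(
    tibble::tibble(species = prey, guild = "prey"),
    tibble::tibble(species = predator, guild = "predator"),
    tibble::tibble(species = human, guild = "human")
  )
  dup <- gm$species[duplicated(gm$species)]
  if (length(dup) > 0) {
    stop("species assigned to more than one guild: ", paste(unique(dup), collapse = ", "))
  }
  gm
}

#' Read camera-trap detection records
#'
#' Reads a delimited file of timestamped detections with header
#' `station_id,species,timestamp[,camera_id]`. Timestamps must be
#' `YYYY-MM-DD HH:MM:SS` local clock time; an unparseable timestamp is an
#' error naming the offending row. Species names are not validated here:
#' records whose species is absent from the active guild map are dropped
#' later, at guild aggregation.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default comma).
#' @param tz Time zone used to interpret timestamps (default `"UTC"`; the
#'   analysis uses local clock time, so any fixed zone works).
#' @return A tibble with columns `station_id`, `species`, `timestamp`
#'   (POSIXct) and `camera_id` (character, `NA` when absent), one row per
#'   input row in file order.
#' @export
read_records <- function(path, delim = ",", tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  needed <- c("station_id", "species", "timestamp")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("records file lacks required column(s): ", paste(missing, collapse = ", "))
  }
  if (!"camera_id" %in% names(raw)) raw$camera_id <- NA_character_
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%d %H:%M:%S", tz = tz)
  bad <- which(is.na(ts) & !is.na(raw$timestamp))
  bad <- c(bad, which(is.na(raw$timestamp)))
  if (length(bad) > 0) {
    stop("unparseable timestamp at row(s): ", paste(sort(unique(bad)), collapse = ", "))
  }
  tibble::tibble(
    station_id = raw$station_id,
    species = raw$species,
    timestamp = ts,
    camera_id = raw$camera_id
  )
}

#' Read a survey-design table
#'
#' The design lists every camera station with its grid label, deployment
#' start date and number of daily occasions. In the reference design all
#' stations run concurrently (88 stations, 20 occasions).
#'
#' @param path Path to delimited text with header
#'   `station_id,grid_label,start_date,n_occasions`.
#' @param delim Field delimiter.
#' @return A tibble with columns `station_id`, `grid_label`, `start_date`
#'   (Date) and `n_occasions` (integer).
#' @export
read_design <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  needed <- c("station_id", "grid_label", "start_date", "n_occasions")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("design file lacks required column(s): ", paste(missing, collapse = ", "))
  }
  design <- tibble::tibble(
    station_id = raw$station_id,
    grid_label = raw$grid_label,
    start_date = as.Date(raw$start_date),
    n_occasions = as.integer(raw$n_occasions)
  )
  validate_design(design)
  design
}

validate_design <- function(design) {
  if (anyDuplicated(design$station_id)) stop("station ids must be unique")
  if (any(is.na(design$start_date))) stop("unparseable start_date in design")
  if (any(is.na(design$n_occasions)) || any(design$n_occasions < 1)) {
    stop("n_occasions must be a positive integer for every station")
  }
  invisible(design)
}

#' Filter records to independent capture events
#'
#' Applies the standard camera-trap independence rule: within each
#' (station, species) series sorted by time, the first event is retained and
#' each later event is retained only if it falls at least `window_minutes`
#' after the last *retained* event of that series (a greedy scan, which makes
#' the filter deterministic and idempotent). With `per_station = FALSE` the
#' series are per species study-wide, pooling all stations.
#'
#' @param records A record tibble (see [read_records()]).
#' @param window_minutes Independence window in minutes (default 15).
#' @param per_station Logical; group series by station as well as species
#'   (default `TRUE`).
#' @return The retained records, sorted by station, species and time.
#' @examples
#' rec <- tibble::tibble(
#'   station_id = "S1", species = "tiger",
#'   timestamp = as.POSIXct("2015-12-01 08:00:00", tz = "UTC") + c(0, 10, 20) * 60,
#'   camera_id = NA_character_
#' )
#' filter_independent(rec)  # events at minutes 0 and 20 survive
#' @export
filter_independent <- function(records, window_minutes = 15, per_station = TRUE) {
  if (!is.numeric(window_minutes) || length(window_minutes) != 1 ||
      is.na(window_minutes) || window_minutes < 0) {
    stop("window_minutes must be a nonnegative number")
  }
  if (nrow(records) == 0) return(records)
  keys <- if (per_station) c("station_id", "species") else "species"
  records |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "timestamp")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::filter(greedy_keep(as.numeric(.data$timestamp), window_minutes * 60)) |>
    dplyr::ungroup()
}

# Greedy scan: keep an event iff it is >= window seconds after the last kept
# event of the same series. Anchoring at the last *retained* event (not the
# previous event) is what makes the rule idempotent.
greedy_keep <- function(t, window_s) {
  n <- length(t)
  keep <- logical(n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (t[i] - last >= window_s || !is.finite(last)) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  keep
}

#' Build a guild-level detection history
#'
#' Collapses records to the sites-by-occasions binary matrix that feeds the
#' occupancy likelihood: entry (site, day) is 1 if at least one member of the
#' guild was recorded at that station on that calendar day within its
#' deployment window, 0 if the station was active that day with no guild
#' detection, and `NA` outside the deployment. Occasion `k` is the calendar
#' day `start_date + (k - 1)`, beginning at local midnight.
#'
#' Records are expected to be independence-filtered already; this is not
#' enforced (day-level binarisation makes the history insensitive to
#' within-day duplicates in any case).
#'
#' @param records A record tibble.
#' @param design A survey-design tibble (see [read_design()]).
#' @param guilds A guild map (see [guild_map()]).
#' @param guild Name of the guild to build the history for.
#' @return A `detection_history`: an integer matrix (stations x occasions,
#'   dimnames set) with attribute `guild`.
#' @export
build_detection_history <- function(records, design, guilds, guild) {
  validate_design(design)
  if (!guild %in% guilds$guild) stop("unknown guild: ", guild)
  unknown_station <- setdiff(unique(records$station_id), design$station_id)
  if (length(unknown_station) > 0) {
    stop("record(s) at station(s) absent from design: ",
         paste(unknown_station, collapse = ", "))
  }
  k_max <- max(design$n_occasions)
  mat <- matrix(0L, nrow = nrow(design), ncol = k_max,
                dimnames = list(design$station_id, paste0("occ", seq_len(k_max))))
  for (i in seq_len(nrow(design))) {
    ki <- design$n_occasions[i]
    if (ki < k_max) mat[i, (ki + 1L):k_max] <- NA_integer_
  }
  members <- guilds$species[guilds$guild == guild]
  rec <- records[records$species %in% members, , drop = FALSE]
  if (nrow(rec) > 0) {
    rec <- dplyr::left_join(rec, design, by = "station_id")
    occ <- as.integer(as.Date(rec$timestamp, tz = attr(rec$timestamp, "tzone") %||% "UTC") -
                        rec$start_date) + 1L
    inside <- occ >= 1L & occ <= rec$n_occasions
    if (any(!inside)) {
      warning(sum(!inside), " record(s) outside the deployment window ignored")
    }
    rec <- rec[inside, , drop = FALSE]
    occ <- occ[inside]
    mat[cbind(match(rec$station_id, design$station_id), occ)] <- 1L
  }
  structure(mat, guild = guild, class = c("detection_history", "matrix", "array"))
}

#' @export
print.detection_history <- function(x, ...) {
  cat("<detection_history> guild:", attr(x, "guild"),
      "-", nrow(x), "sites x", ncol(x), "occasions\n")
  cat("detections:", sum(x == 1L, na.rm = TRUE),
      "| naive occupancy:", round(naive_occupancy(x), 3), "\n")
  invisible(x)
}

#' @export
as_tibble.detection_history <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "station_id") |>
    tidyr::pivot_longer(-"station_id", names_to = "occasion", values_to = "detected") |>
    dplyr::mutate(occasion = as.integer(sub("^occ", "", .data$occasion)))
}

#' Naive occupancy
#'
#' The fraction of sites with at least one detection, uncorrected for
#' imperfect detection.
#'
#' @param history A `detection_history` or a 0/1/NA matrix with sites as rows.
#' @return A proportion in \[0, 1\].
#' @export
naive_occupancy <- function(history) {
  m <- unclass(history)
  if (!is.matrix(m) || nrow(m) == 0) stop("history must have at least one site")
  mean(apply(m, 1, function(r) any(r == 1L, na.rm = TRUE)))
}

#' Write a detection history to delimited text
#'
#' One row per station, one column per occasion, entries 0/1/NA.
#'
#' @param history A `detection_history`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  df <- tibble::as_tibble(unclass(history), rownames = "station_id")
  readr::write_csv(df, path, na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
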