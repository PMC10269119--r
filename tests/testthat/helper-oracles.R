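# Independent oracles and fixture builders used across the suite.

# Record tibble from minute offsets at one station/species.
make_records <- function(minutes, station = "S1", species = "tiger",
                         origin = "2015-12-01 08:00:00") {
  tibble::tibble(
    station_id = station, species = species,
    timestamp = as.POSIXct(origin, tz = "UTC") + minutes * 60,
    camera_id = NA_character_
  )
}

make_design <- function(n_stations = 1, n_occasions = 5,
                        start = as.Date("2015-12-01")) {
  tibble::tibble(station_id = sprintf("S%d", seq_len(n_stations)),
                 grid_label = sprintf("G%d", seq_len(n_stations)),
                 start_date = start, n_occasions = as.integer(n_occasions))
}

# Brute-force greedy independence scan, written independently of the package.
oracle_independent <- function(times_sec, window_sec) {
  times_sec <- sort(times_sec)
  kept <- c()
  for (t in times_sec) {
    if (length(kept) == 0 || t - kept[length(kept)] >= window_sec) {
      kept <- c(kept, t)
    }
  }
  kept
}

# Exhaustive latent-state enumeration of the occupancy mixture likelihood,
# working occasion-by-occasion on the raw history (no sufficient-statistic
# shortcut), for S guilds with histories h (list of 0/1 vectors) and
# detection probabilities p.
oracle_site_likelihood <- function(histories, p, state_probs) {
  S <- length(histories)
  states <- as.matrix(expand.grid(rep(list(0:1), S)))[, S:1, drop = FALSE]
  # expand.grid varies the first factor fastest; reorder columns so column 1
  # is the least significant bit, matching canonical order after re-sorting
  states <- states[order(states %*% 2^(seq_len(S) - 1)), , drop = FALSE]
  total <- 0
  for (r in seq_len(nrow(states))) {
    term <- state_probs[r]
    for (s in seq_len(S)) {
      h <- histories[[s]]
      if (states[r, s] == 1) {
        for (o in h) term <- term * (if (o == 1) p[s] else 1 - p[s])
      } else {
        if (any(h == 1)) term <- 0
      }
    }
    total <- total + term
  }
  total
}

# Enumeration of the multinomial-logit state distribution for S = 2.
oracle_state_probs2 <- function(f1, f2, f12) {
  w <- c(1, exp(f1), exp(f2), exp(f1 + f2 + f12))
  w / sum(w)
}

# Numeric integral of min of two von Mises mixture densities over the circle.
dvm <- function(t, mu, kappa) exp(kappa * cos(t - mu)) / (2 * pi * besselI(kappa, 0))
oracle_min_integral <- function(mu1, k1, mu2, k2, n = 10000) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  sum(pmin(dvm(t, mu1, k1), dvm(t, mu2, k2))) * 2 * pi / n
}

# Brute-force set statistics over explicit (grid, hour) membership matrices.
oracle_cells <- function(mat) {
  which(mat > 0, arr.ind = TRUE) |> apply(1, paste, collapse = "-")
}
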