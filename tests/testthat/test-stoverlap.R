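make_st_records <- function(df, start = "2015-12-01") {
  # df: station, species, day, hour (possibly fractional)
  tibble::tibble(
    station_id = df$station, species = df$species,
    timestamp = as.POSIXct(start, tz = "UTC") + (df$day - 1) * 86400 +
      round(df$hour * 3600),
    camera_id = NA_character_
  )
}

test_that("grid-hour counts bin by floor hour and aggregate across days", {
  design <- make_design(6, 10)
  rec <- make_st_records(data.frame(
    station = c("S5", "S5", "S5", "S1", "S1", "S2"),
    species = c("tiger", "tiger", "tiger", "human", "human", "spotted deer"),
    day = c(1, 3, 7, 2, 2, 4),
    hour = c(14.62, 14.01, 14.99, 6.5, 23.9, 0.0)
  ))
  counts <- grid_hour_counts(rec, design, guild_map())
  m <- grid_hour_matrix(counts, "predator")
  expect_equal(m["G5", "h14"], 3L)     # same grid, same hour, different days add
  expect_equal(sum(m), 3L)
  mh <- grid_hour_matrix(counts, "human")
  expect_equal(mh["G1", "h6"] + mh["G1", "h23"], 2L)
  expect_equal(dim(m), c(6, 24))
  # empty records give all-zero matrices
  m0 <- grid_hour_matrix(grid_hour_counts(rec[0, ], design, guild_map()), "prey")
  expect_true(all(m0 == 0L))
  # records outside the deployment window are an error
  bad <- make_st_records(data.frame(station = "S1", species = "tiger",
                                    day = 30, hour = 1))
  expect_error(grid_hour_counts(bad, design, guild_map()), "outside the deployment")
  # counts are invariant to record order and to camera splitting
  rec2 <- rec[sample(nrow(rec)), ]
  rec2$camera_id <- rep(c("C1", "C2"), 3)
  expect_equal(grid_hour_matrix(grid_hour_counts(rec2, design, guild_map()), "predator"), m)
})

test_that("activity cells binarise counts idempotently", {
  design <- make_design(4, 5)
  rec <- make_st_records(data.frame(station = c("S1", "S1", "S2"),
                                    species = "tiger", day = c(1, 2, 1),
                                    hour = c(3, 3, 3)))
  cells <- activity_cells(grid_hour_counts(rec, design, guild_map()))
  pred <- cells[cells$guild == "predator", ]
  expect_equal(nrow(pred), 2)          # (G1,3) once despite two detections
  expect_equal(nrow(activity_cells(cells)), nrow(cells))
  empty <- activity_cells(grid_hour_counts(rec[0, ], design, guild_map()))
  expect_equal(nrow(empty), 0)
})

cells_from_sets <- function(...) {
  sets <- list(...)
  dplyr::bind_rows(lapply(names(sets), function(g) {
    if (nrow(sets[[g]]) == 0) return(NULL)
    tibble::tibble(guild = g, grid_label = sets[[g]]$grid, hour = sets[[g]]$hour)
  }))
}

test_that("exclusive, pairwise and triple proportions match hand arithmetic", {
  a <- data.frame(grid = paste0("G", 1:5), hour = 1)          # 5 cells
  b <- data.frame(grid = paste0("G", c(1, 2, 9)), hour = 1)   # overlaps 2 of a
  cells <- cells_from_sets(a = a, b = b)
  ex <- exclusive_proportion(cells, "a", "b")
  expect_equal(ex$proportion, 3 / 5)
  expect_equal(ex$numerator, 3); expect_equal(ex$denominator, 5)
  pw <- pairwise_overlap(cells, "a", "b")
  expect_equal(pw$proportion, 2 / 6, tolerance = 1e-12)
  # boundaries
  only_a <- cells_from_sets(a = a, b = data.frame(grid = character(), hour = integer()))
  expect_equal(exclusive_proportion(only_a, "a", "b")$proportion, 1)
  nested <- cells_from_sets(a = a[1:2, ], b = a)
  expect_equal(exclusive_proportion(nested, "a", "b")$proportion, 0)
  expect_equal(pairwise_overlap(cells_from_sets(a = a, b = a), "a", "b")$proportion, 1)
  disj <- cells_from_sets(a = a, b = data.frame(grid = "G9", hour = 5))
  expect_equal(pairwise_overlap(disj, "a", "b")$proportion, 0)
  expect_error(exclusive_proportion(cells_from_sets(a = a[0, ], b = b), "a", "b"))
})

test_that("triple overlap and Venn regions agree with brute-force enumeration", {
  set.seed(14)
  for (i in 1:200) {
    ng <- sample(3:10, 1)
    mats <- lapply(1:3, function(j)
      matrix(rbinom(ng * 24, 1, runif(1, 0.02, 0.3)), ng, 24,
             dimnames = list(paste0("G", 1:ng), NULL)))
    keys <- lapply(mats, oracle_cells)
    cells <- dplyr::bind_rows(lapply(1:3, function(j) {
      idx <- which(mats[[j]] > 0, arr.ind = TRUE)
      tibble::tibble(guild = c("a", "b", "c")[j],
                     grid_label = rownames(mats[[j]])[idx[, 1]],
                     hour = idx[, 2] - 1L)
    }))
    u <- unique(unlist(keys))
    if (length(u) == 0) next
    if (length(keys[[1]]) > 0) {
      expect_equal(exclusive_proportion(cells, "a", c("b", "c"))$proportion,
                   sum(!keys[[1]] %in% union(keys[[2]], keys[[3]])) / length(keys[[1]]))
    }
    if (length(union(keys[[1]], keys[[2]])) > 0) {
      expect_equal(pairwise_overlap(cells, "a", "b")$proportion,
                   length(intersect(keys[[1]], keys[[2]])) /
                     length(union(keys[[1]], keys[[2]])))
    }
    tri <- triple_overlap(cells, "a", "b", "c")
    expect_equal(tri$proportion,
                 length(intersect(intersect(keys[[1]], keys[[2]]), keys[[3]])) / length(u))
    vr <- venn_regions(cells, c("a", "b", "c"))
    expect_equal(sum(vr$count), length(u))
    in1 <- u %in% keys[[1]]; in2 <- u %in% keys[[2]]; in3 <- u %in% keys[[3]]
    expect_equal(vr$count[vr$region == "a"], sum(in1 & !in2 & !in3))
    expect_equal(vr$count[vr$region == "a&b&c"], sum(in1 & in2 & in3))
  }
})

test_that("pairwise overlap is symmetric and triple is permutation invariant", {
  set.seed(2)
  mats <- lapply(1:3, function(j)
    matrix(rbinom(8 * 24, 1, 0.15), 8, 24, dimnames = list(paste0("G", 1:8), NULL)))
  cells <- dplyr::bind_rows(lapply(1:3, function(j) {
    idx <- which(mats[[j]] > 0, arr.ind = TRUE)
    tibble::tibble(guild = c("a", "b", "c")[j],
                   grid_label = rownames(mats[[j]])[idx[, 1]], hour = idx[, 2] - 1L)
  }))
  expect_equal(pairwise_overlap(cells, "a", "b")$proportion,
               pairwise_overlap(cells, "b", "a")$proportion)
  perms <- list(c("a", "b", "c"), c("c", "a", "b"), c("b", "c", "a"))
  vals <- vapply(perms, function(p) triple_overlap(cells, p[1], p[2], p[3])$proportion,
                 numeric(1))
  expect_true(all(abs(vals - vals[1]) < 1e-12))
  # all-disjoint and all-equal degenerate patterns
  dis <- cells_from_sets(a = data.frame(grid = "G1", hour = 1),
                         b = data.frame(grid = "G2", hour = 1),
                         c = data.frame(grid = "G3", hour = 1))
  expect_equal(triple_overlap(dis, "a", "b", "c")$proportion, 0)
  vr <- venn_regions(dis, c("a", "b", "c"))
  expect_true(all(vr$count[grepl("&", vr$region)] == 0))
  same <- cells_from_sets(a = data.frame(grid = "G1", hour = 1:3),
                          b = data.frame(grid = "G1", hour = 1:3),
                          c = data.frame(grid = "G1", hour = 1:3))
  expect_equal(triple_overlap(same, "a", "b", "c")$proportion, 1)
  vr2 <- venn_regions(same, c("a", "b", "c"))
  expect_equal(vr2$count[vr2$region == "a&b&c"], 3)
  expect_equal(sum(vr2$count), 3)
})

test_that("the grid bootstrap is seeded and brackets the point estimate", {
  cfg <- sim_preset(n_grids = 30, n_days = 10, seed = 3)
  sv <- simulate_survey(cfg)
  fl <- filter_independent(sv$records)
  s1 <- bootstrap_spatiotemporal(fl, sv$design, guild_map(), B = 150, seed = 5)
  s2 <- bootstrap_spatiotemporal(fl, sv$design, guild_map(), B = 150, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1$proportion >= 0 & s1$proportion <= 1, na.rm = TRUE))
  expect_true(all(s1$ci_low <= s1$ci_high, na.rm = TRUE))
  expect_true(all(c("exclusive", "pairwise", "triple") %in% s1$statistic))
  expect_true(all(nzchar(s1$guilds)))  # every statistic names its guilds
  expect_true(all(s1$denominator > 0, na.rm = TRUE))
  expect_error(bootstrap_spatiotemporal(fl, sv$design, guild_map(), B = 50, seed = 1))
  small <- sv$design[1:4, ]
  expect_error(bootstrap_spatiotemporal(fl[fl$station_id %in% small$station_id, ],
                                        small, guild_map(), B = 150, seed = 1),
               "fewer than 5 grids")
})

test_that("bootstrap intervals bracket the point estimate across datasets", {
  ok <- 0; total <- 0
  for (i in 1:50) {
    cfg <- sim_preset(n_grids = 25, n_days = 8, seed = 100 + i)
    sv <- simulate_survey(cfg)
    fl <- filter_independent(sv$records)
    s <- bootstrap_spatiotemporal(fl, sv$design, guild_map(), B = 100, seed = i)
    s <- s[!is.na(s$proportion), ]
    total <- total + nrow(s)
    ok <- ok + sum(s$ci_low <= s$proportion + 1e-9 & s$ci_high >= s$proportion - 1e-9)
  }
  expect_gte(ok / total, 0.95)
})

test_that("single-guild data give exclusive one with a degenerate interval", {
  design <- make_design(8, 5)
  rec <- make_st_records(data.frame(station = paste0("S", 1:6), species = "tiger",
                                    day = 1, hour = 1:6))
  gm <- guild_map()[guild_map()$guild == "predator", ]
  s <- bootstrap_spatiotemporal(rec, design, gm, B = 100, seed = 1)
  ex <- s[s$statistic == "exclusive", ]
  expect_equal(ex$proportion, 1)
  expect_equal(ex$ci_low, 1)
  expect_equal(ex$ci_high, 1)
})
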