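# Allele accounting, ensemble summaries, and the long-format table.

# hand-built trajectory over a given set of places
fake_traj <- function(places, counts, times = seq_len(nrow(counts)) - 1) {
  colnames(counts) <- places
  structure(list(time = times, counts = counts, places = places,
                 sampler = "tau", seed = 1, dt = 1, record_dt = 1,
                 hazard_mode = "dense", events = NULL, sprays = list(),
                 n_evaluated = 0, n_skipped = 0, model_kind = "lifecycle"),
            class = "trajectory")
}

fig2d_cube <- function() fig2d_objects()$cube_off

test_that("allele counting follows simple adult arithmetic", {
  cube <- fig2d_cube()
  # 5 GW adults, nothing else
  tr <- fake_traj(c("M_GW", "U_WW"), matrix(c(5, 0), 1))
  s <- allele_series(tr, cube, features = c("G", "W"))
  expect_equal(s$value[s$feature == "G"], 5)
  expect_equal(s$value[s$feature == "W"], 5)
  p <- allele_series(tr, cube, features = c("G", "W"), proportions = TRUE)
  expect_equal(p$value, c(0.5, 0.5))
  # 3 GG + 1 WW -> G: 6/8, W: 2/8
  tr2 <- fake_traj(c("M_GG", "M_WW"), matrix(c(3, 1), 1))
  p2 <- allele_series(tr2, cube, features = c("G", "W"),
                      proportions = TRUE)
  expect_equal(p2$value, c(0.75, 0.25))
})

test_that("an all-wild population has W proportion 1 at every time", {
  sc <- fig2d_objects()
  tr <- simulate_spn(sc$model, sc$x0, sampler = "tau", t_end = 20,
                     dt = 0.25, record_dt = 1, seed = 9)
  p <- allele_series(tr, sc$cube_off, features = "W", proportions = TRUE)
  expect_true(all(p$value == 1))
})

test_that("aquatic stages and stored mates are excluded by default", {
  cube <- fig2d_cube()
  places <- c("E1_GG", "L2_GG", "U_WW", "F_WW|GG")
  tr <- fake_traj(places, matrix(c(100, 50, 1, 1), 1))
  s <- allele_series(tr, cube, features = c("G", "W"))
  expect_equal(s$value[s$feature == "G"], 0)   # only the 2 adult females
  expect_equal(s$value[s$feature == "W"], 4)
  sm <- allele_series(tr, cube, features = c("G", "W"),
                      include_mates = TRUE)
  expect_equal(sm$value[sm$feature == "G"], 2) # mate genotype GG counted
  sa <- allele_series(tr, cube, features = c("G", "W"),
                      include_aquatic = TRUE)
  expect_equal(sa$value[sa$feature == "G"], 300)
})

test_that("genotype features are normalized by adult totals", {
  cube <- fig2d_cube()
  tr <- fake_traj(c("M_GG", "M_WW", "U_GW"), matrix(c(3, 1, 4), 1))
  g <- allele_series(tr, cube, features = c("GG", "GW"),
                     proportions = TRUE)
  expect_equal(g$value, c(3 / 8, 4 / 8))
})

test_that("unknown features fail with the valid labels listed", {
  cube <- fig2d_cube()
  tr <- fake_traj("M_GG", matrix(1, 1))
  expect_error(allele_series(tr, cube, features = "Q"),
               "unknown feature")
  expect_error(allele_series(tr, cube, features = "Q"), "GW")
  expect_error(allele_series(tr, cube, features = character(0)),
               "nonempty")
})

test_that("proportions close to 1 over the full alphabet", {
  sc <- fig2d_objects()
  tr <- simulate_spn(sc$model, sc$x0, sampler = "tau", t_end = 150,
                     dt = 0.25, record_dt = 5, seed = 13,
                     releases = sc$releases)
  p <- allele_series(tr, sc$cube_off, features = sc$cube_off$alphabet,
                     proportions = TRUE)
  tot <- tapply(p$value, p$time, sum)
  expect_true(all(abs(tot - 1) < 1e-12))
})

test_that("sex-filtered counts add up to the combined counts", {
  sc <- fig2d_objects()
  tr <- simulate_spn(sc$model, sc$x0, sampler = "tau", t_end = 120,
                     dt = 0.25, record_dt = 10, seed = 14,
                     releases = sc$releases)
  feats <- c("G", "W")
  both <- allele_series(tr, sc$cube_off, feats, sex = "both")
  fem <- allele_series(tr, sc$cube_off, feats, sex = "female")
  mal <- allele_series(tr, sc$cube_off, feats, sex = "male")
  expect_equal(fem$value + mal$value, both$value)
})

test_that("ensemble summary computes the documented statistics", {
  mk <- function(v) tibble::tibble(time = 0, sex = "both", feature = "G",
                                   value = v)
  tab <- summarize_ensemble(list(mk(1), mk(2), mk(3)))
  get <- function(s) tab$value[tab$stat == s]
  expect_equal(get("mean"), 2)
  expect_equal(get("min"), 1)
  expect_equal(get("max"), 3)
  expect_equal(get("median"), 2)
  # single repetition: every statistic equals the observed value
  tab1 <- summarize_ensemble(list(mk(7)))
  expect_true(all(tab1$value == 7))
})

test_that("empirical 95% band matches the normal quantiles", {
  set.seed(506)
  draws <- stats::rnorm(10000)
  series <- lapply(draws, function(v)
    tibble::tibble(time = 0, sex = "both", feature = "z", value = v))
  tab <- summarize_ensemble(series, stats = c("q2.5", "q97.5"))
  expect_equal(tab$value[tab$stat == "q2.5"], -1.96, tolerance = 0.05 / 1.96)
  expect_equal(tab$value[tab$stat == "q97.5"], 1.96, tolerance = 0.05 / 1.96)
})

test_that("summary statistics are correctly ordered at every record", {
  sc <- fig2d_objects()
  series <- lapply(1:8, function(i) {
    tr <- simulate_spn(sc$model, sc$x0, sampler = "tau", t_end = 60,
                       dt = 0.25, record_dt = 10, seed = 800 + i,
                       releases = sc$releases)
    allele_series(tr, sc$cube_off, c("G", "W"), proportions = TRUE)
  })
  tab <- summarize_ensemble(series)
  wide <- tidyr::pivot_wider(tab, names_from = "stat",
                             values_from = "value")
  expect_true(all(wide$min <= wide$q2.5 + 1e-12))
  expect_true(all(wide$q2.5 <= wide$median + 1e-12))
  expect_true(all(wide$median <= wide$q97.5 + 1e-12))
  expect_true(all(wide$q97.5 <= wide$max + 1e-12))
  expect_true(all(wide$min <= wide$mean & wide$mean <= wide$max))
  # rows = times x sexes x features x statistics
  expect_equal(nrow(tab), 7 * 1 * 2 * 6)
})

test_that("mismatched time grids are an alignment error", {
  a <- tibble::tibble(time = 0:1, sex = "both", feature = "G", value = 0)
  b <- tibble::tibble(time = 0:2, sex = "both", feature = "G", value = 0)
  expect_error(summarize_ensemble(list(a, b)), "alignment")
})

test_that("long tables round-trip losslessly through CSV", {
  mk <- function(v) tibble::tibble(time = c(0, 1), sex = "both",
                                   feature = "G", value = v)
  tab <- summarize_ensemble(list(mk(c(0.1234567890123, 1 / 3)),
                                 mk(c(0.9, 2 / 7))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_long_table(tab, path)
  expect_identical(readLines(path, n = 1), "time,sex,feature,stat,value")
  back <- read_long_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  # empty table -> header-only file
  write_long_table(tab[0, ], path)
  expect_identical(readLines(path), "time,sex,feature,stat,value")
})

test_that("trajectory CSVs round-trip for the analysis pipeline", {
  sc <- fig2d_objects()
  tr <- simulate_spn(sc$model, sc$x0, sampler = "tau", t_end = 10,
                     dt = 0.25, record_dt = 1, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$counts[, sc$model$places], tr$counts)
  expect_equal(back$time, tr$time)
  a <- allele_series(back, sc$cube_off, "W", proportions = TRUE)
  b <- allele_series(tr, sc$cube_off, "W", proportions = TRUE)
  expect_equal(a$value, b$value)
})
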