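# Samplers: direct method, tau-leaping, mean-field; events; sparsity.

test_that("pure-death chain extinction matches the harmonic closed form", {
  # E[T] = sum_{k=1..n} 1/(mu k) for a linear death chain
  m <- semdrive:::.death_chain_spn(mu = 1)
  n0 <- 10
  reps <- 3000
  set.seed(501)
  times <- vapply(seq_len(reps), function(i) {
    x <- c(N = n0); t <- 0
    while (x[1] > 0) {
      s <- step_direct(m, x, t, t_max = Inf)
      x <- s$state; t <- s$time
    }
    t
  }, 0)
  expected <- sum(1 / (1:n0))
  se <- sqrt(sum(1 / (1:n0)^2)) / sqrt(reps)
  expect_lt(abs(mean(times) - expected), 3 * se)
})

test_that("direct-method waiting times are exponential (KS test)", {
  # constant-rate self-loop: waiting times iid Exp(lambda)
  lambda <- 2
  pi <- data.frame(place = "A", kind = "generic", genotype = NA,
                   mate = NA, sex = NA, stringsAsFactors = FALSE)
  m <- semdrive:::.new_spn(
    "A", pi,
    list(name = "loop", kind = "linear", src = 1L, out = 1L,
         mate = NA_integer_, coef = lambda, kernel = NA_integer_),
    kernels = list(), larval_idx = integer(0), male_idx = integer(0),
    K = 1, lp = NULL, kind = "fixture", extra = list())
  set.seed(502)
  t <- 0; x <- c(A = 1); w <- numeric(2000)
  for (i in seq_along(w)) {
    s <- step_direct(m, x, t)
    w[i] <- s$time - t
    t <- s$time; x <- s$state
  }
  expect_gt(stats::ks.test(w, "pexp", rate = lambda)$p.value, 0.01)
})

test_that("zero total rate advances time without changing state", {
  m <- semdrive:::.death_chain_spn(mu = 1)
  s <- step_direct(m, c(N = 0), t = 3, t_max = 50)
  expect_equal(s$time, 50)
  expect_equal(as.numeric(s$state), 0)
  expect_true(is.na(s$fired))
})

test_that("tau-leap increments have Poisson moments for a constant rate", {
  # non-consuming source: births into B at rate lambda
  lambda <- 5
  pi <- data.frame(place = c("A", "B"), kind = "generic", genotype = NA,
                   mate = NA, sex = NA, stringsAsFactors = FALSE)
  m <- semdrive:::.new_spn(
    c("A", "B"), pi,
    list(name = "birth", kind = "source", src = 1L, out = 2L,
         mate = NA_integer_, coef = lambda, kernel = NA_integer_),
    kernels = list(), larval_idx = integer(0), male_idx = integer(0),
    K = 1, lp = NULL, kind = "fixture", extra = list())
  set.seed(503)
  reps <- 10000
  inc <- vapply(seq_len(reps), function(i)
    step_tau_leap(m, c(A = 1, B = 0), dt = 1)[["B"]], 0)
  se_mean <- sqrt(lambda / reps)
  # var of sample variance for Poisson ~ (2 lambda^2 + lambda) / n
  se_var <- sqrt((2 * lambda^2 + lambda) / reps)
  expect_lt(abs(mean(inc) - lambda), 3 * se_mean)
  expect_lt(abs(stats::var(inc) - lambda), 3 * se_var)
})

test_that("tau-leap approaches the Euler drift as dt -> 0", {
  m <- semdrive:::.death_chain_spn(mu = 1)
  set.seed(504)
  for (dt in c(0.01, 0.001)) {
    reps <- 4000
    x0 <- 1000
    ch <- vapply(seq_len(reps), function(i)
      step_tau_leap(m, c(N = x0), dt = dt)[["N"]] - x0, 0)
    drift <- mean(ch)
    se <- sqrt(x0 * dt / reps)
    expect_lt(abs(drift + x0 * dt), 3 * se + 10 * x0 * dt^2)
  }
})

test_that("tau-leap leaves an empty state unchanged", {
  m <- semdrive:::.death_chain_spn(mu = 1)
  expect_equal(step_tau_leap(m, c(N = 0), dt = 1)[["N"]], 0)
})

test_that("mean-field pure decay matches the exponential closed form", {
  m <- semdrive:::.death_chain_spn(mu = 0.7)
  x <- c(N = 1000)
  for (i in 1:100) x <- step_mean_field(m, x, dt = 0.01)
  expect_equal(x[["N"]], 1000 * exp(-0.7), tolerance = 1e-8)
})

test_that("sparse and dense hazard modes agree everywhere", {
  set.seed(505)
  for (k in 1:5) {
    m <- make_fixture_spn(places = 60, density = 0.15, seed = 600 + k)
    for (r in 1:20) {
      x <- ifelse(stats::runif(m$n_places) < 0.2,
                  stats::rpois(m$n_places, 5), 0)
      hs <- hazard_vector(m, x, mode = "sparse_first_order")
      hd <- hazard_vector(m, x, mode = "dense")
      expect_identical(as.numeric(hs), as.numeric(hd))
      empty_first <- sum(x[m$trans$src] == 0)
      expect_equal(attr(hs, "n_skipped"), empty_first)
      expect_equal(attr(hd, "n_skipped"), 0)
    }
  }
})

test_that("same-seed sparse and dense trajectories are bit-identical", {
  sc <- fig2d_objects()
  for (sampler in c("tau", "direct")) {
    t_end <- if (sampler == "direct") 0.05 else 40
    a <- simulate_spn(sc$model, sc$x0, sampler = sampler, t_end = t_end,
                      dt = 0.25, record_dt = t_end / 4, seed = 77,
                      hazard_mode = "sparse_first_order")
    b <- simulate_spn(sc$model, sc$x0, sampler = sampler, t_end = t_end,
                      dt = 0.25, record_dt = t_end / 4, seed = 77,
                      hazard_mode = "dense")
    expect_identical(a$counts, b$counts, label = sampler)
    expect_gt(a$n_skipped, 0)
    expect_equal(b$n_skipped, 0)
    expect_lt(a$n_evaluated, b$n_evaluated)
  }
})

test_that("simulation is deterministic given seed, sampler, and step", {
  sc <- fig2d_objects()
  a <- simulate_spn(sc$model, sc$x0, sampler = "tau", t_end = 30,
                    dt = 0.25, record_dt = 1, seed = 123)
  b <- simulate_spn(sc$model, sc$x0, sampler = "tau", t_end = 30,
                    dt = 0.25, record_dt = 1, seed = 123)
  expect_identical(a$counts, b$counts)
  c <- simulate_spn(sc$model, sc$x0, sampler = "tau", t_end = 30,
                    dt = 0.25, record_dt = 1, seed = 124)
  expect_false(identical(c$counts, a$counts))
})

test_that("releases add exactly their token count at the release time", {
  # all rates zero: releases are the only dynamics
  lp <- lifecycle_params(beta = 0, mu_E = 0, mu_L = 0, mu_P = 0,
                         mu_M = 0, mu_F = 0)
  wc <- wildtype_cube()
  m <- build_lifecycle_spn(lp, wc, wc, K = 100)
  x0 <- stats::setNames(numeric(m$n_places), m$places)
  x0["M_WW"] <- 50
  rel <- list(release_event(3, "male", "WW", 100),
              release_event(7, "female", "WW", 25))
  tr <- simulate_spn(m, x0, sampler = "tau", t_end = 10, dt = 1,
                     record_dt = 1, seed = 1, releases = rel)
  tot <- rowSums(tr$counts)
  expect_equal(tot, c(50, 50, 50, 150, 150, 150, 150, 175, 175, 175, 175))
  expect_equal(unname(tr$counts[4, "M_WW"]), 150)
  expect_equal(unname(tr$counts[8, "U_WW"]), 25)
})

test_that("release genotypes must exist in the model", {
  sc <- fig2d_objects()
  expect_error(
    simulate_spn(sc$model, sc$x0, sampler = "tau", t_end = 5, seed = 1,
                 releases = list(release_event(1, "male", "ZZ", 10))),
    "ZZ")
})

test_that("overlapping spray windows are rejected", {
  sc <- fig2d_objects()
  expect_error(
    simulate_spn(sc$model, sc$x0, sampler = "tau", t_end = 5, seed = 1,
                 sprays = list(spray_window(0, 10), spray_window(5, 20))),
    "overlap")
  expect_error(spray_window(10, 10), "start < end")
})

test_that("inducible SEM produces no V without a spray window", {
  sc <- fig2d_objects()
  tr <- simulate_spn(sc$model, sc$x0, sampler = "tau", t_end = 150,
                     dt = 0.25, record_dt = 10, seed = 31,
                     releases = sc$releases)
  vplaces <- grepl("V", sc$model$places)
  expect_true(all(tr$counts[, vplaces] == 0))
  hplaces <- grepl("H", sc$model$places)
  expect_true(all(tr$counts[, hplaces] == 0))
  # the drive itself is spreading, though
  gplaces <- grepl("G", sc$model$places)
  expect_gt(sum(tr$counts[nrow(tr$counts), gplaces]), 0)
})

test_that("tau ensemble mean agrees with mean-field at day 50", {
  sc <- fig2d_objects()
  reps <- 40
  finals <- vapply(seq_len(reps), function(i) {
    tr <- simulate_spn(sc$model, sc$x0, sampler = "tau", t_end = 50,
                       dt = 0.25, record_dt = 50, seed = 700 + i)
    total_adults(sc$model, tr$counts[2, ])
  }, 0)
  mf <- simulate_spn(sc$model, sc$x0, sampler = "ode", t_end = 50,
                     dt = 0.1, record_dt = 50)
  target <- total_adults(sc$model, mf$counts[2, ])
  se <- stats::sd(finals) / sqrt(reps)
  expect_lt(abs(mean(finals) - target), 3 * se)
})
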