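# Forward simulation of an spn_model: Gillespie direct method, Poisson
# tau-leaping, and a deterministic mean-field (RK4) integrator, all driven
# by the same hazard evaluation with optional first-order sparsity-aware
# skipping. Timed releases add tokens exactly at their event times; spray
# windows toggle the global molecule state, which selects the inheritance
# kernel used at oviposition.

#' A timed release of adults
#'
#' @param time Release day (>= 0).
#' @param sex `"male"` (adult male place) or `"female"` (unmated female
#'   place).
#' @param genotype Genotype label of the released individuals.
#' @param count Number released (positive integer).
#' @return A `release_event`.
#' @export
release_event <- function(time, sex = c("male", "female"), genotype, count) {
  sex <- match.arg(sex)
  stopifnot(is.numeric(time), length(time) == 1L, time >= 0,
            is.numeric(count), count > 0, count == round(count))
  structure(list(time = time, sex = sex, genotype = genotype,
                 count = as.integer(count)), class = "release_event")
}

#' A small-molecule spray window
#'
#' Daily spraying over `[start, end)` is approximated as sustained
#' induction: the molecule state is on for the whole window.
#'
#' @param start,end Window boundaries in days, `start < end`.
#' @return A `spray_window`.
#' @export
spray_window <- function(start, end) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1L,
            length(end) == 1L, start >= 0)
  if (start >= end) stop("spray window must have start < end", call. = FALSE)
  structure(list(start = start, end = end), class = "spray_window")
}

.check_sprays <- function(sprays) {
  if (length(sprays) == 0L) return(invisible(sprays))
  st <- vapply(sprays, `[[`, numeric(1), "start")
  en <- vapply(sprays, `[[`, numeric(1), "end")
  o <- order(st)
  st <- st[o]; en <- en[o]
  if (any(st[-1] < en[-length(en)]))
    stop("spray windows may not overlap", call. = FALSE)
  invisible(sprays)
}

.molecule_on <- function(t, sprays) {
  for (w in sprays) if (t >= w$start && t < w$end) return(TRUE)
  FALSE
}

.release_place <- function(model, ev) {
  p <- paste0(if (ev$sex == "male") "M_" else "U_", ev$genotype)
  i <- match(p, model$places)
  if (is.na(i))
    stop("release genotype ", deparse(ev$genotype),
         " has no ", ev$sex, " place in the model", call. = FALSE)
  i
}

.consuming <- function(kind) !kind %in% c("ovi", "source")

# one tau-leap step of length dt; fires Poisson counts per transition,
# applied in fixed group order (oviposition, advances, emergence, deaths,
# larval deaths, mating) with removals truncated at available tokens.
.step_tau <- function(model, x, dt, molecule, sparse, counters) {
  h <- .hazards(model, x, sparse)
  counters$evals <- counters$evals + attr(h, "n_evaluated")
  counters$skips <- counters$skips + attr(h, "n_skipped")
  n <- stats::rpois(model$n_transitions, h * dt)
  tr <- model$trans
  for (gname in names(model$grp)) {
    ti <- model$grp[[gname]]
    nz <- ti[n[ti] > 0L]
    if (length(nz) == 0L) next
    if (gname == "ovi") {
      for (j in nz) {
        k <- model$kernels[[tr$kernel[j]]]
        p <- if (molecule) k$p_on else k$p_off
        draws <- stats::rmultinom(1L, n[j], p)[, 1]
        keep <- k$dest > 0L & draws > 0L
        if (any(keep)) {
          x[k$dest[keep]] <- x[k$dest[keep]] + draws[keep]
        }
      }
    } else if (gname == "mating") {
      for (j in nz) {
        n_act <- min(n[j], x[tr$src[j]])
        if (n_act > 0) {
          x[tr$src[j]] <- x[tr$src[j]] - n_act
          x[tr$out[j]] <- x[tr$out[j]] + n_act
        }
      }
    } else if (gname == "source") {
      # non-consuming births: no cap needed
      oi <- tr$out[nz]
      for (w in seq_along(nz)) x[oi[w]] <- x[oi[w]] + n[nz[w]]
    } else {
      # unique src within these groups: vectorized truncation
      src <- tr$src[nz]
      n_act <- pmin(n[nz], x[src])
      x[src] <- x[src] - n_act
      has_out <- !is.na(tr$out[nz])
      if (any(has_out)) {
        oi <- tr$out[nz][has_out]
        x[oi] <- x[oi] + n_act[has_out]
      }
      has_ker <- !is.na(tr$kernel[nz])
      for (w in which(has_ker)) {
        if (n_act[w] == 0) next
        k <- model$kernels[[tr$kernel[nz[w]]]]
        p <- if (molecule) k$p_on else k$p_off
        draws <- stats::rmultinom(1L, n_act[w], p)[, 1]
        keep <- k$dest > 0L & draws > 0L
        if (any(keep)) x[k$dest[keep]] <- x[k$dest[keep]] + draws[keep]
      }
    }
  }
  if (any(x < 0)) stop("internal invariant violation: negative token count")
  x
}

# one Gillespie event (or advance to t_stop if none fires before it);
# returns list(x, t, fired)
.step_direct_once <- function(model, x, t, t_stop, molecule, sparse,
                              counters) {
  tr <- model$trans
  h <- .hazards(model, x, sparse)
  counters$evals <- counters$evals + attr(h, "n_evaluated")
  counters$skips <- counters$skips + attr(h, "n_skipped")
  H <- sum(h)
  if (H <= 0) return(list(x = x, t = t_stop, fired = NA_integer_))
  dt <- stats::rexp(1L, H)
  if (t + dt > t_stop) return(list(x = x, t = t_stop, fired = NA_integer_))
  t <- t + dt
  j <- sample.int(model$n_transitions, 1L, prob = h)
  if (.consuming(tr$kind[j])) x[tr$src[j]] <- x[tr$src[j]] - 1L
  if (!is.na(tr$kernel[j])) {
    k <- model$kernels[[tr$kernel[j]]]
    p <- if (molecule) k$p_on else k$p_off
    d <- k$dest[sample.int(length(p), 1L, prob = p)]
    if (d > 0L) x[d] <- x[d] + 1L
  } else if (!is.na(tr$out[j])) {
    x[tr$out[j]] <- x[tr$out[j]] + 1L
  }
  if (x[tr$src[j]] < 0) stop("internal invariant violation: negative count")
  list(x = x, t = t, fired = j)
}

# advance the direct (Gillespie) sampler until t_stop; returns list(x, t)
.run_direct <- function(model, x, t, t_stop, molecule, sparse, counters) {
  repeat {
    res <- .step_direct_once(model, x, t, t_stop, molecule, sparse,
                             counters)
    x <- res$x; t <- res$t
    if (t >= t_stop) break
  }
  list(x = x, t = t)
}

.null_counters <- function() {
  e <- new.env(parent = emptyenv())
  e$evals <- 0; e$skips <- 0
  e
}

#' Single Gillespie direct-method event
#'
#' Draws an exponential waiting time at the summed transition rate, picks a
#' transition proportional to its rate, and applies it (input token
#' removed, outputs added; kernel transitions draw their categorical
#' outcome). If no transition can fire before `t_max`, the state is
#' unchanged and time jumps to `t_max`.
#'
#' @param model An `spn_model`.
#' @param state Token counts.
#' @param t Current time.
#' @param t_max Time horizon for this step.
#' @param molecule Molecule state.
#' @param hazard_mode `"sparse_first_order"` or `"dense"`.
#' @return List with `state`, `time`, and `fired` (transition index, `NA`
#'   if none fired).
#' @export
step_direct <- function(model, state, t, t_max = Inf, molecule = FALSE,
                        hazard_mode = c("sparse_first_order", "dense")) {
  hazard_mode <- match.arg(hazard_mode)
  res <- .step_direct_once(model, as.numeric(state), t, t_max, molecule,
                           hazard_mode == "sparse_first_order",
                           .null_counters())
  names(res$x) <- model$places
  list(state = res$x, time = res$t, fired = res$fired)
}

#' Single tau-leap step
#'
#' Each transition fires a Poisson(rate x dt) number of times; removals are
#' truncated at the tokens available at group entry, processed in fixed
#' group order (oviposition, advances, emergence, deaths, larval deaths,
#' mating), so counts stay nonnegative and the update is deterministic
#' given the RNG stream.
#'
#' @inheritParams step_direct
#' @param dt Leap length (days).
#' @return Updated named state vector.
#' @export
step_tau_leap <- function(model, state, dt, molecule = FALSE,
                          hazard_mode = c("sparse_first_order", "dense")) {
  hazard_mode <- match.arg(hazard_mode)
  x <- .step_tau(model, as.numeric(state), dt, molecule,
                 hazard_mode == "sparse_first_order", .null_counters())
  names(x) <- model$places
  x
}

#' Single deterministic mean-field step (classical RK4)
#'
#' Real-valued states; each place changes by (inflow - outflow) expected
#' rates, with kernel transitions contributing their expected offspring
#' distribution.
#'
#' @inheritParams step_tau_leap
#' @return Updated named state vector.
#' @export
step_mean_field <- function(model, state, dt, molecule = FALSE) {
  x <- .step_mean_field(model, as.numeric(state), dt, molecule)
  names(x) <- model$places
  x
}

# mean-field derivative: expected flow per place
.mf_deriv <- function(model, x, molecule) {
  x[x < 0] <- 0
  h <- .hazards(model, x, sparse = FALSE)
  tr <- model$trans
  d <- numeric(model$n_places)
  cons <- .consuming(tr$kind)
  add_at <- function(d, idx, val) {
    s <- rowsum(val, idx)
    ii <- as.integer(rownames(s))
    d[ii] <- d[ii] + s[, 1]
    d
  }
  if (any(cons)) d <- add_at(d, tr$src[cons], -h[cons])
  has_out <- !is.na(tr$out)
  if (any(has_out)) d <- add_at(d, tr$out[has_out], h[has_out])
  ker <- which(!is.na(tr$kernel) & h > 0)
  for (j in ker) {
    k <- model$kernels[[tr$kernel[j]]]
    p <- if (molecule) k$p_on else k$p_off
    keep <- k$dest > 0L & p > 0
    if (any(keep)) d <- add_at(d, k$dest[keep], h[j] * p[keep])
  }
  d
}

# classical RK4 step for the mean-field system
.step_mean_field <- function(model, x, dt, molecule) {
  k1 <- .mf_deriv(model, x, molecule)
  k2 <- .mf_deriv(model, x + dt / 2 * k1, molecule)
  k3 <- .mf_deriv(model, x + dt / 2 * k2, molecule)
  k4 <- .mf_deriv(model, x + dt * k3, molecule)
  out <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  out[out < 0 & out > -1e-9] <- 0
  out
}

#' Simulate an SPN model forward in time
#'
#' Integrates to `t_end`, toggling the molecule state at spray-window
#' boundaries, adding release tokens exactly at release times, and
#' recording token counts on a fixed grid. With identical
#' `(seed, sampler, dt, hazard_mode)` the trajectory is bit-identical;
#' sparse and dense hazard modes with the same seed also produce identical
#' trajectories, because the hazard vectors agree and randomness
#' consumption does not depend on skipping.
#'
#' @param model An `spn_model`.
#' @param x0 Initial token counts (named vector aligned with
#'   `model$places`), e.g. from [equilibrium_state()].
#' @param sampler `"tau"` (Poisson tau-leap, default), `"direct"`
#'   (Gillespie), or `"ode"` (deterministic mean-field, RK4).
#' @param t_end Horizon in days.
#' @param dt Sampler step (tau-leap step or RK4 step), days.
#' @param record_dt Recording grid spacing, days.
#' @param releases List of [release_event()]s.
#' @param sprays List of [spray_window()]s (must not overlap).
#' @param seed RNG seed (required for stochastic samplers).
#' @param hazard_mode `"sparse_first_order"` or `"dense"`.
#' @return A `trajectory`: recorded `time` grid, `counts` matrix (times x
#'   places), event log, and hazard-evaluation counters.
#' @export
simulate_spn <- function(model, x0, sampler = c("tau", "direct", "ode"),
                         t_end, dt = 1, record_dt = 1,
                         releases = list(), sprays = list(), seed = NULL,
                         hazard_mode = c("sparse_first_order", "dense")) {
  sampler <- match.arg(sampler)
  hazard_mode <- match.arg(hazard_mode)
  sparse <- hazard_mode == "sparse_first_order"
  stopifnot(inherits(model, "spn_model"), t_end > 0, dt > 0, record_dt > 0)
  .check_sprays(sprays)
  if (length(x0) != model$n_places)
    stop("x0 length does not match the model's places", call. = FALSE)
  x <- as.numeric(x0)
  if (sampler != "ode") {
    if (is.null(seed)) stop("stochastic samplers require a seed",
                            call. = FALSE)
    set.seed(as.integer(seed))
    x <- round(x)
  }
  rel_idx <- vapply(releases, function(ev) .release_place(model, ev), 0L)
  rel_time <- vapply(releases, `[[`, numeric(1), "time")
  rec_times <- seq(0, t_end, by = record_dt)
  bounds <- sort(unique(c(rec_times, rel_time,
                          unlist(lapply(sprays, function(w)
                            c(w$start, w$end))), t_end)))
  bounds <- bounds[bounds >= 0 & bounds <= t_end]
  counters <- new.env(parent = emptyenv())
  counters$evals <- 0; counters$skips <- 0
  traj <- matrix(NA_real_, length(rec_times), model$n_places,
                 dimnames = list(NULL, model$places))
  ev_log <- data.frame(time = numeric(0), kind = character(0),
                       detail = character(0), stringsAsFactors = FALSE)
  apply_releases <- function(x, t) {
    hit <- which(abs(rel_time - t) < 1e-9)
    for (j in hit) {
      x[rel_idx[j]] <- x[rel_idx[j]] + releases[[j]]$count
      ev_log[nrow(ev_log) + 1L, ] <<- list(
        t, "release", paste0(releases[[j]]$count, " ", releases[[j]]$sex,
                             " ", releases[[j]]$genotype))
    }
    x
  }
  record <- function(x, t) {
    hit <- which(abs(rec_times - t) < 1e-9)
    if (length(hit)) traj[hit, ] <<- x
  }
  t <- 0
  x <- apply_releases(x, 0)
  record(x, 0)
  mol_prev <- NA
  for (bi in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[bi]; t1 <- bounds[bi + 1L]
    molecule <- .molecule_on(t0, sprays)
    if (!identical(molecule, mol_prev)) {
      ev_log[nrow(ev_log) + 1L, ] <- list(t0, "molecule",
                                          if (molecule) "on" else "off")
      mol_prev <- molecule
    }
    if (sampler == "tau") {
      while (t < t1 - 1e-12) {
        step <- min(dt, t1 - t)
        x <- .step_tau(model, x, step, molecule, sparse, counters)
        t <- t + step
      }
    } else if (sampler == "ode") {
      while (t < t1 - 1e-12) {
        step <- min(dt, t1 - t)
        x <- .step_mean_field(model, x, step, molecule)
        t <- t + step
      }
    } else {
      res <- .run_direct(model, x, t, t1, molecule, sparse, counters)
      x <- res$x; t <- res$t
    }
    t <- t1
    x <- apply_releases(x, t)
    record(x, t)
  }
  structure(list(time = rec_times, counts = traj, places = model$places,
                 sampler = sampler, seed = seed, dt = dt,
                 record_dt = record_dt, hazard_mode = hazard_mode,
                 events = ev_log, sprays = sprays,
                 n_evaluated = counters$evals, n_skipped = counters$skips,
                 model_kind = model$kind),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$sampler, " sampler, ", length(x$time),
      " records x ", ncol(x$counts), " places, seed=",
      if (is.null(x$seed)) "NULL" else x$seed, "\n", sep = "")
  cat("  hazard mode ", x$hazard_mode, ": ", x$n_evaluated,
      " evaluated, ", x$n_skipped, " skipped\n", sep = "")
  invisible(x)
}

#' Run a stochastic ensemble
#'
#' Repetition `i` uses seed `seed + i - 1` on a fresh RNG stream, so
#' ensembles are reproducible and individual repetitions can be re-run in
#' isolation.
#'
#' @inheritParams simulate_spn
#' @param reps Number of repetitions.
#' @param seed Base seed.
#' @return List of `trajectory` objects.
#' @export
run_ensemble <- function(model, x0, reps, seed, ...) {
  lapply(seq_len(reps), function(i)
    simulate_spn(model, x0, seed = seed + i - 1L, ...))
}

#' Write a trajectory as a long-format CSV plus run manifest
#'
#' @param traj A `trajectory`.
#' @param path Output CSV (columns `time`, `place`, `count`); the manifest
#'   (seed, sampler, dt, events, spray windows) is written alongside with
#'   extension `.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  long <- data.frame(
    time = rep(traj$time, times = ncol(traj$counts)),
    place = rep(colnames(traj$counts), each = nrow(traj$counts)),
    count = as.vector(traj$counts), stringsAsFactors = FALSE)
  readr::write_csv(long, path)
  manifest <- list(sampler = traj$sampler, seed = traj$seed, dt = traj$dt,
                   record_dt = traj$record_dt,
                   hazard_mode = traj$hazard_mode,
                   events = traj$events,
                   sprays = lapply(traj$sprays, unclass),
                   model_kind = traj$model_kind)
  jsonlite::write_json(manifest, paste0(sub("\\.csv$", "", path),
                                        ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return A `trajectory` (without sampler counters).
#' @export
read_trajectory <- function(path) {
  long <- readr::read_csv(path, col_types = readr::cols(
    time = readr::col_double(), place = readr::col_character(),
    count = readr::col_double()))
  places <- unique(long$place)
  times <- unique(long$time)
  counts <- matrix(long$count, nrow = length(times),
                   dimnames = list(NULL, places))
  mpath <- paste0(sub("\\.csv$", "", path), ".manifest.json")
  manifest <- if (file.exists(mpath)) jsonlite::read_json(mpath) else list()
  structure(list(time = times, counts = counts, places = places,
                 sampler = manifest$sampler, seed = manifest$seed,
                 dt = manifest$dt, record_dt = manifest$record_dt,
                 hazard_mode = manifest$hazard_mode,
                 events = NULL, sprays = manifest$sprays,
                 n_evaluated = NA, n_skipped = NA,
                 model_kind = manifest$model_kind),
            class = "trajectory")
}
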