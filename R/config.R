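# Scenario configuration: a single JSON document describing the design,
# drive/SEM probabilities, lifecycle rates, target population, release and
# spray schedules, and sampler settings. Validation collects every
# violation (with its key path) rather than stopping at the first.

#' Construct a scenario configuration
#'
#' @param design List with `design_id`, `flavor`, `sem_resistance`,
#'   `inducible_drive`, `inducible_sem` (see [design_spec()]).
#' @param drive List with `p`, `q`, and optionally `rho`.
#' @param sem List with `a`, `b`, `c`.
#' @param lifecycle Named list of [lifecycle_params()] overrides.
#' @param target_adults Equilibrium adult population the larval density
#'   parameter is solved for.
#' @param releases List of lists with `time`, `sex`, `genotype`, `count`.
#' @param sprays List of lists with `start`, `end`.
#' @param sampler List with `kind` ("tau", "direct", or "ode"), `dt`,
#'   `record_dt`, `hazard_mode`.
#' @param t_end Horizon (days).
#' @param reps Ensemble size.
#' @param seed Base seed.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(design, drive, sem, lifecycle = list(),
                            target_adults, releases = list(),
                            sprays = list(),
                            sampler = list(kind = "tau", dt = 0.25,
                                           record_dt = 1,
                                           hazard_mode = "sparse_first_order"),
                            t_end, reps = 100, seed = 1) {
  cfg <- structure(
    list(design = design, drive = drive, sem = sem, lifecycle = lifecycle,
         target_adults = target_adults, releases = releases,
         sprays = sprays, sampler = sampler, t_end = t_end,
         reps = reps, seed = seed),
    class = "scenario_config")
  errs <- validate_config(cfg)
  if (length(errs))
    stop("invalid scenario configuration:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  cfg
}

#' Validate a scenario configuration
#'
#' @param cfg A `scenario_config` (or plain list with the same shape).
#' @return Character vector of violation messages, each prefixed by the
#'   offending key path; empty when valid.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  push <- function(path, msg) errs <<- c(errs, paste0(path, ": ", msg))
  d <- cfg$design
  spec <- NULL
  if (is.null(d$design_id) || !is.character(d$design_id) ||
      !d$design_id %in% SEM_DESIGNS) {
    push("design.design_id", "must be one of CIS_AUTO, CIS_X, TRANS_AUTO_AUTO, TRANS_AUTO_X, TRANS_X_AUTO")
  } else if (is.null(d$flavor) || !d$flavor %in% SEM_FLAVORS) {
    push("design.flavor", "must be one of COMPLETE, REDUCED, SIMPLIFIED")
  } else {
    spec <- tryCatch(
      design_spec(d$design_id, d$flavor,
                  isTRUE(d$sem_resistance),
                  isTRUE(d$inducible_drive),
                  !isFALSE(d$inducible_sem)),
      error = function(e) { push("design", conditionMessage(e)); NULL })
  }
  prob_ok <- function(v) is.numeric(v) && length(v) == 1L && !is.na(v) &&
    v >= 0 && v <= 1
  for (nm in c("p", "q")) if (!prob_ok(cfg$drive[[nm]]))
    push(paste0("drive.", nm), "must be a probability in [0, 1]")
  if (!is.null(cfg$drive$rho) && !prob_ok(cfg$drive$rho))
    push("drive.rho", "must be a probability in [0, 1]")
  for (nm in c("a", "b", "c")) if (!prob_ok(cfg$sem[[nm]]))
    push(paste0("sem.", nm), "must be a probability in [0, 1]")
  lp <- tryCatch(do.call(lifecycle_params, cfg$lifecycle),
                 error = function(e) { push("lifecycle",
                                            conditionMessage(e)); NULL })
  if (!is.numeric(cfg$target_adults) || length(cfg$target_adults) != 1L ||
      cfg$target_adults <= 0)
    push("target_adults", "must be a positive number")
  genos <- if (!is.null(spec)) {
    list(male = enumerate_genotypes(spec, "male"),
         female = enumerate_genotypes(spec, "female"))
  } else NULL
  for (i in seq_along(cfg$releases)) {
    r <- cfg$releases[[i]]
    path <- paste0("releases[", i, "]")
    if (!is.numeric(r$time) || r$time < 0)
      push(paste0(path, ".time"), "must be a nonnegative day")
    if (is.null(r$sex) || !r$sex %in% c("male", "female"))
      push(paste0(path, ".sex"), "must be \"male\" or \"female\"")
    if (!is.numeric(r$count) || r$count <= 0 || r$count != round(r$count))
      push(paste0(path, ".count"), "must be a positive integer")
    if (!is.null(genos) && !is.null(r$sex) &&
        r$sex %in% c("male", "female") &&
        (is.null(r$genotype) || !r$genotype %in% genos[[r$sex]]))
      push(paste0(path, ".genotype"),
           paste0("not a valid ", r$sex, " genotype for ", d$design_id,
                  "/", d$flavor))
  }
  last_end <- -Inf
  sp <- cfg$sprays
  if (length(sp)) {
    st <- vapply(sp, function(w) as.numeric(w$start %||% NA), 0)
    en <- vapply(sp, function(w) as.numeric(w$end %||% NA), 0)
    for (i in seq_along(sp)) {
      path <- paste0("sprays[", i, "]")
      if (is.na(st[i]) || is.na(en[i]) || st[i] >= en[i])
        push(path, "must have numeric start < end")
    }
    if (!anyNA(st) && !anyNA(en)) {
      o <- order(st)
      if (any(st[o][-1] < en[o][-length(en)]))
        push("sprays", "windows may not overlap")
    }
  }
  if (is.null(cfg$sampler$kind) ||
      !cfg$sampler$kind %in% c("tau", "direct", "ode"))
    push("sampler.kind", "must be \"tau\", \"direct\" or \"ode\"")
  if (!is.numeric(cfg$sampler$dt) || cfg$sampler$dt <= 0)
    push("sampler.dt", "must be a positive step in days")
  if (!is.null(cfg$sampler$hazard_mode) &&
      !cfg$sampler$hazard_mode %in% c("sparse_first_order", "dense"))
    push("sampler.hazard_mode", "must be \"sparse_first_order\" or \"dense\"")
  if (!is.numeric(cfg$t_end) || cfg$t_end <= 0)
    push("t_end", "must be a positive horizon in days")
  if (!is.numeric(cfg$reps) || cfg$reps < 1)
    push("reps", "must be >= 1")
  errs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a scenario configuration as JSON
#'
#' @param cfg A `scenario_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load and validate a scenario configuration
#'
#' @param path JSON file written by [save_config()] (or by hand).
#' @return A validated `scenario_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  raw$lifecycle <- lapply(raw$lifecycle, function(v) v)
  cfg <- structure(raw, class = "scenario_config")
  errs <- validate_config(cfg)
  if (length(errs))
    stop("invalid scenario configuration (", path, "):\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  cfg
}

#' The canonical inducible cis-acting SEM demonstration scenario
#'
#' A single panmictic population of 2000 adults simulated for 730 days. An
#' autosomal cis-acting SEM drive with no resistance alleles (SIMPLIFIED),
#' cleavage 50%, HR 100%; inducible SEM with cleavage 50% and perfect SSA
#' repair to `V`. Four weekly releases of 100 drive-homozygous (`GG`) males
#' starting at day 91 (~3 months), and a sustained spray window over days
#' [365, 547) (~6 months starting at the 1-year mark). Tau-leap sampler,
#' dt = 0.25 day, 100 repetitions.
#'
#' @return A `scenario_config`.
#' @export
preset_fig2d <- function() {
  scenario_config(
    design = list(design_id = "CIS_AUTO", flavor = "SIMPLIFIED",
                  sem_resistance = FALSE, inducible_drive = FALSE,
                  inducible_sem = TRUE),
    drive = list(p = 0.5, q = 1.0, rho = 1 / 3),
    sem = list(a = 0.5, b = 1.0, c = 1.0),
    lifecycle = list(),
    target_adults = 2000,
    releases = lapply(c(91, 98, 105, 112), function(d)
      list(time = d, sex = "male", genotype = "GG", count = 100)),
    sprays = list(list(start = 365, end = 547)),
    sampler = list(kind = "tau", dt = 0.25, record_dt = 1,
                   hazard_mode = "sparse_first_order"),
    t_end = 730, reps = 100, seed = 1)
}

#' Assemble the simulation objects for a scenario
#'
#' Builds the off/on inheritance cubes, solves the larval density parameter
#' for the target adult population, builds the lifecycle SPN, and computes
#' the wild-type equilibrium initial state.
#'
#' @param cfg A `scenario_config`.
#' @return List with `spec`, `cube_off`, `cube_on`, `lp`, `K`, `model`,
#'   `x0`, `releases`, `sprays`.
#' @export
build_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config") || is.list(cfg))
  d <- cfg$design
  spec <- design_spec(d$design_id, d$flavor, isTRUE(d$sem_resistance),
                      isTRUE(d$inducible_drive), !isFALSE(d$inducible_sem))
  dp <- drive_params(cfg$drive$p, cfg$drive$q, cfg$drive$rho %||% 1 / 3)
  sp <- sem_params(cfg$sem$a, cfg$sem$b, cfg$sem$c)
  cube_off <- build_cube(spec, dp, sp, molecule_present = FALSE)
  cube_on <- build_cube(spec, dp, sp, molecule_present = TRUE)
  lp <- do.call(lifecycle_params, cfg$lifecycle)
  K <- solve_carrying_capacity(lp, cfg$target_adults)
  model <- build_lifecycle_spn(lp, cube_off, cube_on, K)
  x0 <- equilibrium_state(model, cfg$target_adults)
  releases <- lapply(cfg$releases, function(r)
    release_event(r$time, r$sex, r$genotype, r$count))
  sprays <- lapply(cfg$sprays, function(w) spray_window(w$start, w$end))
  list(spec = spec, cube_off = cube_off, cube_on = cube_on, lp = lp, K = K,
       model = model, x0 = x0, releases = releases, sprays = sprays)
}

#' Run a scenario ensemble
#'
#' @param cfg A `scenario_config`.
#' @param reps,seed Override the configured ensemble size / base seed.
#' @return List with the assembled `scenario` objects and `trajectories`
#'   (one per repetition; a single trajectory for the `"ode"` sampler).
#' @export
run_scenario <- function(cfg, reps = NULL, seed = NULL) {
  sc <- build_scenario(cfg)
  reps <- reps %||% cfg$reps
  seed <- seed %||% cfg$seed
  sk <- cfg$sampler
  if (identical(sk$kind, "ode")) {
    trajectories <- list(simulate_spn(
      sc$model, sc$x0, sampler = "ode", t_end = cfg$t_end, dt = sk$dt,
      record_dt = sk$record_dt %||% 1, releases = sc$releases,
      sprays = sc$sprays))
  } else {
    trajectories <- lapply(seq_len(reps), function(i)
      simulate_spn(sc$model, sc$x0, sampler = sk$kind, t_end = cfg$t_end,
                   dt = sk$dt, record_dt = sk$record_dt %||% 1,
                   releases = sc$releases, sprays = sc$sprays,
                   seed = seed + i - 1L,
                   hazard_mode = sk$hazard_mode %||% "sparse_first_order"))
  }
  c(sc, list(trajectories = trajectories, config = cfg))
}
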