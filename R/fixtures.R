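# Synthetic fixtures: a minimal single-genotype cube and random
# linear-hazard SPNs used to exercise sparse-vs-dense hazard equivalence
# and skip counting.

#' A single-genotype wild-type inheritance cube
#'
#' The smallest valid cube: one sexless genotype `WW` whose offspring are
#' always `WW`. Useful for lifecycle-only models and engine tests.
#'
#' @return An `inheritance_cube`.
#' @export
wildtype_cube <- function() {
  tau <- array(1, dim = c(1, 1, 1), dimnames = list("WW", "WW", "WW"))
  structure(
    list(tau = tau, females = "WW", males = "WW", offspring = "WW",
         offspring_sex = "either", viability = c(WW = 1),
         allele_counts = matrix(2L, 1, 1, dimnames = list("WW", "W")),
         alphabet = "W", spec = NULL, drive_params = NULL,
         sem_params = NULL, molecule = FALSE),
    class = "inheritance_cube")
}

#' Random linear-hazard SPN fixture
#'
#' Generates a random SPN in which every place has a death transition and a
#' random subset of places are connected by movement transitions, with a
#' configurable fraction of initially occupied places. Used to exercise the
#' first-order sparsity-aware sampler: transitions whose input place starts
#' empty must be skipped without changing any hazard value.
#'
#' @param places Number of places (>= 1).
#' @param density Fraction of places initially occupied, in (0, 1].
#' @param seed RNG seed; the same seed reproduces the same fixture.
#' @return An `spn_model` with an `x0` element holding the initial state.
#' @export
make_fixture_spn <- function(places, density, seed) {
  stopifnot(places >= 1, density > 0, density <= 1)
  set.seed(as.integer(seed))
  pl <- sprintf("P%03d", seq_len(places))
  tn <- character(0); tk <- character(0)
  tsrc <- integer(0); tout <- integer(0); tcoef <- numeric(0)
  for (i in seq_len(places)) {
    tn <- c(tn, paste0("death_", pl[i])); tk <- c(tk, "linear")
    tsrc <- c(tsrc, i); tout <- c(tout, NA_integer_)
    tcoef <- c(tcoef, stats::runif(1, 0.5, 1.5))
  }
  n_move <- max(1L, places %/% 2L)
  for (k in seq_len(n_move)) {
    ij <- sample.int(places, 2L)
    tn <- c(tn, paste0("move_", pl[ij[1]], "_", pl[ij[2]]))
    tk <- c(tk, "linear")
    tsrc <- c(tsrc, ij[1]); tout <- c(tout, ij[2])
    tcoef <- c(tcoef, stats::runif(1, 0.2, 1))
  }
  occupied <- stats::runif(places) < density
  if (!any(occupied)) occupied[sample.int(places, 1L)] <- TRUE
  x0 <- ifelse(occupied, stats::rpois(places, 10) + 1L, 0L)
  names(x0) <- pl
  place_info <- data.frame(place = pl, kind = "generic",
                           genotype = NA_character_, mate = NA_character_,
                           sex = NA_character_, stringsAsFactors = FALSE)
  .new_spn(pl, place_info,
           list(name = tn, kind = tk, src = tsrc, out = tout,
                mate = rep(NA_integer_, length(tn)), coef = tcoef,
                kernel = rep(NA_integer_, length(tn))),
           kernels = list(), larval_idx = integer(0), male_idx = integer(0),
           K = 1, lp = NULL, kind = "fixture", extra = list(x0 = x0))
}

# minimal pure-death chain: n0 tokens in one place, unit per-capita rate
.death_chain_spn <- function(mu = 1) {
  place_info <- data.frame(place = "N", kind = "generic",
                           genotype = NA_character_, mate = NA_character_,
                           sex = NA_character_, stringsAsFactors = FALSE)
  .new_spn("N", place_info,
           list(name = "death", kind = "linear", src = 1L,
                out = NA_integer_, mate = NA_integer_, coef = mu,
                kernel = NA_integer_),
           kernels = list(), larval_idx = integer(0), male_idx = integer(0),
           K = 1, lp = NULL, kind = "fixture", extra = list())
}
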