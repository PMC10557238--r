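# Stage-structured mosquito lifecycle: egg -> larva -> pupa -> adult, with
# Erlang-distributed aquatic dwell times (sub-stage chains), logistic-type
# density-dependent larval mortality mu_L * (1 + N_L / K), near-instant
# mating, and genotype bookkeeping through an inheritance cube.
#
# The unmated-female pool is a transient mating compartment: females are
# assumed to mate within ~1/nu days of emergence and adult female mortality
# acts on the mated compartment. Mated females store their mate's genotype;
# remating is disallowed.

#' Lifecycle rate and structure parameters
#'
#' Defaults are Aedes/Anopheles-scale values: 32 eggs per female per day,
#' 1-day egg and pupal stages, a 14-day larval stage (each an Erlang chain
#' with 2 sub-stages), adult mortality 0.123/day (~8-day life expectancy),
#' mating rate 1/day, even primary sex ratio. Aquatic baseline mortality is
#' concentrated in the density-dependent larval term.
#'
#' @param beta Eggs per female per day.
#' @param mu_E,mu_L,mu_P Aquatic baseline mortality rates (per day); the
#'   realized larval rate is `mu_L * (1 + N_L / K)`.
#' @param mu_M,mu_F Adult male / female mortality (per day).
#' @param t_E,t_L,t_P Mean stage durations (days).
#' @param n_E,n_L,n_P Erlang shape (sub-stage counts, integers >= 1).
#' @param nu Mating rate (per day).
#' @param phi Probability an emerging adult is female, where sex is not
#'   forced by the sex chromosomes.
#' @return A `lifecycle_params` object.
#' @export
lifecycle_params <- function(beta = 32, mu_E = 0, mu_L = 0.3, mu_P = 0,
                             mu_M = 0.123, mu_F = 0.123,
                             t_E = 1, t_L = 14, t_P = 1,
                             n_E = 2, n_L = 2, n_P = 2,
                             nu = 1, phi = 0.5) {
  num <- c(beta = beta, mu_E = mu_E, mu_L = mu_L, mu_P = mu_P,
           mu_M = mu_M, mu_F = mu_F, t_E = t_E, t_L = t_L, t_P = t_P,
           nu = nu, phi = phi)
  if (any(!is.finite(num)) || any(num < 0))
    stop("lifecycle parameters must be finite and nonnegative", call. = FALSE)
  # zero rates are allowed (useful for conservation checks); the
  # equilibrium solver enforces the positivity it needs
  if (t_E <= 0 || t_L <= 0 || t_P <= 0 || nu <= 0)
    stop("stage durations and nu must be positive", call. = FALSE)
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]", call. = FALSE)
  for (nm in c("n_E", "n_L", "n_P")) {
    v <- get(nm)
    if (length(v) != 1L || v < 1 || v != round(v))
      stop("Erlang shape `", nm, "` must be an integer >= 1", call. = FALSE)
  }
  structure(list(beta = beta, mu_E = mu_E, mu_L = mu_L, mu_P = mu_P,
                 mu_M = mu_M, mu_F = mu_F, t_E = t_E, t_L = t_L, t_P = t_P,
                 n_E = as.integer(n_E), n_L = as.integer(n_L),
                 n_P = as.integer(n_P), nu = nu, phi = phi),
            class = "lifecycle_params")
}

# stage survival through an Erlang chain with per-substage exit rate g and
# per-substage death rate mu
.erlang_survival <- function(g, mu, n) (g / (g + mu))^n

# closed-form mean-field equilibrium of the wild-type lifecycle.
# Balance of the adult loop fixes the larval survival required at
# equilibrium independently of K:
#   beta * s_E * s_L * s_P * phi = mu_F
# from which the equilibrium per-capita larval death rate d_L, and then all
# stage occupancies, follow. Returns NULL if no positive equilibrium.
.lifecycle_equilibrium <- function(lp, N_adult_eq) {
  if (lp$beta <= 0 || lp$mu_L <= 0 || lp$mu_M <= 0 || lp$mu_F <= 0)
    stop("parameter error: beta, mu_L, mu_M and mu_F must be positive for ",
         "a demographic equilibrium to exist", call. = FALSE)
  g_E <- lp$n_E / lp$t_E; g_L <- lp$n_L / lp$t_L; g_P <- lp$n_P / lp$t_P
  s_E <- .erlang_survival(g_E, lp$mu_E, lp$n_E)
  s_P <- .erlang_survival(g_P, lp$mu_P, lp$n_P)
  s_L_req <- lp$mu_F / (lp$beta * s_E * s_P * lp$phi)
  R0 <- 1 / s_L_req  # net reproduction with perfect larval survival
  if (s_L_req >= 1) {
    return(list(ok = FALSE, R0 = R0))
  }
  s_sub <- s_L_req^(1 / lp$n_L)
  d_L <- g_L * (1 / s_sub - 1)   # equilibrium per-capita larval death rate
  if (d_L <= lp$mu_L) {
    return(list(ok = FALSE, R0 = (g_L / (g_L + lp$mu_L))^lp$n_L / s_L_req))
  }
  # adult emergence rate lambda_A that yields the target adult total
  denom <- (1 - lp$phi) / lp$mu_M + lp$phi / lp$nu + lp$phi / lp$mu_F
  lambda_A <- N_adult_eq / denom
  Fm <- lambda_A * lp$phi / lp$mu_F      # mated females
  U  <- lambda_A * lp$phi / lp$nu        # unmated (transient)
  M  <- lambda_A * (1 - lp$phi) / lp$mu_M
  lambda_E <- lp$beta * Fm
  lambda_L <- lambda_E * s_E
  # substage occupancies: x_i = inflow * s^(i-1) / (g + mu)
  occ <- function(lambda, g, mu, n) {
    s <- g / (g + mu)
    lambda * s^(seq_len(n) - 1) / (g + mu)
  }
  E_occ <- occ(lambda_E, g_E, lp$mu_E, lp$n_E)
  L_occ <- occ(lambda_L, g_L, d_L, lp$n_L)
  lambda_P <- lambda_L * s_L_req
  P_occ <- occ(lambda_P, g_P, lp$mu_P, lp$n_P)
  N_L <- sum(L_occ)
  K <- N_L / (d_L / lp$mu_L - 1)
  list(ok = TRUE, R0 = R0, d_L = d_L, K = K, E = E_occ, L = L_occ,
       P = P_occ, U = U, M = M, Fm = Fm, lambda_A = lambda_A,
       N_adult = U + M + Fm)
}

#' Solve the larval density parameter for a target adult population
#'
#' Returns `K` such that the deterministic (mean-field) equilibrium of the
#' wild-type lifecycle has the requested total adult count (males, unmated
#' and mated females). The stage-structured equilibrium has a closed form:
#' balancing the adult loop fixes the larval survival required at
#' equilibrium, hence the per-capita larval death rate, and `K` follows
#' from the equilibrium larval population.
#'
#' @param lp [lifecycle_params()].
#' @param N_adult_eq Target total adult population at equilibrium.
#' @return `K` (individuals).
#' @export
solve_carrying_capacity <- function(lp, N_adult_eq) {
  stopifnot(inherits(lp, "lifecycle_params"), N_adult_eq > 0)
  eq <- .lifecycle_equilibrium(lp, N_adult_eq)
  if (!eq$ok)
    stop("parameter error: no positive equilibrium exists ",
         "(net reproductive number at baseline survival = ",
         format(eq$R0, digits = 4), " must exceed 1)", call. = FALSE)
  eq$K
}

#' Mean-field equilibrium state for a lifecycle model
#'
#' Token counts (rounded to integers for stochastic initialization) with
#' all mass on the wild-type genotype, molecule off, time 0.
#'
#' @param model An `spn_model` from [build_lifecycle_spn()].
#' @param N_adult_eq The adult total the model's `K` was solved for.
#' @param round Round to integer token counts (the default, for stochastic
#'   initialization)? With `round = FALSE` the state is the exact mean-field
#'   fixed point.
#' @return Named numeric vector of token counts aligned with
#'   `model$places`.
#' @export
equilibrium_state <- function(model, N_adult_eq, round = TRUE) {
  stopifnot(inherits(model, "spn_model"), model$kind == "lifecycle")
  lp <- model$lp
  eq <- .lifecycle_equilibrium(lp, N_adult_eq)
  if (!eq$ok) stop("parameter error: no positive equilibrium", call. = FALSE)
  if (abs(eq$K - model$K) / model$K > 1e-8)
    warning("model K does not match the equilibrium solve for N_adult_eq = ",
            N_adult_eq)
  wildf <- model$wild_female
  wildm <- model$wild_male
  wildo <- model$wild_offspring  # two labels (one per sex) for X designs
  w <- 1 / length(wildo)
  x <- stats::setNames(numeric(length(model$places)), model$places)
  for (i in seq_len(lp$n_E)) x[paste0("E", i, "_", wildo)] <- eq$E[i] * w
  for (i in seq_len(lp$n_L)) x[paste0("L", i, "_", wildo)] <- eq$L[i] * w
  for (i in seq_len(lp$n_P)) x[paste0("P", i, "_", wildo)] <- eq$P[i] * w
  x[paste0("U_", wildf)] <- eq$U
  x[paste0("M_", wildm)] <- eq$M
  x[paste0("F_", wildf, "|", wildm)] <- eq$Fm
  if (round) base::round(x) else x
}
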