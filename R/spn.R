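# Stochastic Petri net representation. Every transition has exactly one
# input place with arc weight 1 (its "first input place"); oviposition and
# mating read their input without consuming it. Categorical output kernels
# (offspring genotype at oviposition, sex at emergence) carry one
# probability vector per molecule state.

.new_spn <- function(places, place_info, trans, kernels, larval_idx,
                     male_idx, K, lp, kind, extra = list()) {
  trans$src <- as.integer(trans$src)
  trans$out <- as.integer(trans$out)
  trans$mate <- as.integer(trans$mate)
  trans$kernel <- as.integer(trans$kernel)
  model <- c(list(places = places, place_info = place_info, trans = trans,
                  kernels = kernels, larval_idx = larval_idx,
                  male_idx = male_idx, K = K, lp = lp, kind = kind,
                  n_places = length(places),
                  n_transitions = length(trans$src)),
             extra)
  # precomputed transition groups in firing order
  model$grp <- lapply(
    split(seq_along(trans$kind), factor(trans$kind, levels = unique(trans$kind))),
    as.integer)
  structure(model, class = "spn_model")
}

#' @export
print.spn_model <- function(x, ...) {
  cat("<spn_model> kind=", x$kind, ": ", x$n_places, " places, ",
      x$n_transitions, " transitions\n", sep = "")
  cat("  transition kinds:",
      paste(names(table(x$trans$kind)), table(x$trans$kind),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Build the single-node lifecycle SPN for an inheritance cube pair
#'
#' Constructs places for aquatic sub-stages, unmated females, adult males,
#' and mated females (which store the mate's genotype), and transitions for
#' oviposition (offspring drawn from the molecule-appropriate cube row,
#' thinned by viability), Erlang stage advances, density-dependent larval
#' death, emergence (sex forced by the sex chromosomes where applicable,
#' otherwise split by `phi`), mating (mate genotype sampled proportional to
#' male counts), and adult mortality.
#'
#' @param lp [lifecycle_params()].
#' @param cube_off Cube built with the molecule absent.
#' @param cube_on Cube built with the molecule present (used during spray
#'   windows). Must share the alphabet and genotype ordering of `cube_off`.
#' @param K Larval density parameter, from [solve_carrying_capacity()].
#' @return An `spn_model`.
#' @export
build_lifecycle_spn <- function(lp, cube_off, cube_on, K) {
  stopifnot(inherits(lp, "lifecycle_params"),
            inherits(cube_off, "inheritance_cube"),
            inherits(cube_on, "inheritance_cube"), K > 0)
  if (!identical(cube_off$offspring, cube_on$offspring) ||
      !identical(cube_off$females, cube_on$females) ||
      !identical(cube_off$males, cube_on$males))
    stop("configuration error: cube_off and cube_on have mismatched ",
         "genotype indices", call. = FALSE)

  females <- cube_off$females
  males <- cube_off$males
  viab <- cube_off$viability
  ok <- viab > 0
  ogeno <- cube_off$offspring[ok]       # viable offspring genotypes
  osex <- cube_off$offspring_sex[ok]

  g_E <- lp$n_E / lp$t_E; g_L <- lp$n_L / lp$t_L; g_P <- lp$n_P / lp$t_P

  places <- character(0)
  kind <- character(0); geno <- character(0); mate <- character(0)
  sex <- character(0)
  add_place <- function(p, k, g, mt, sx) {
    places <<- c(places, p); kind <<- c(kind, k); geno <<- c(geno, g)
    mate <<- c(mate, mt); sex <<- c(sex, sx)
  }
  for (g in ogeno) {
    for (i in seq_len(lp$n_E)) add_place(paste0("E", i, "_", g), "egg", g, NA, NA)
    for (i in seq_len(lp$n_L)) add_place(paste0("L", i, "_", g), "larva", g, NA, NA)
    for (i in seq_len(lp$n_P)) add_place(paste0("P", i, "_", g), "pupa", g, NA, NA)
  }
  for (g in females) add_place(paste0("U_", g), "unmated_female", g, NA, "female")
  for (g in males) add_place(paste0("M_", g), "male", g, NA, "male")
  for (gf in females) for (gm in males)
    add_place(paste0("F_", gf, "|", gm), "mated_female", gf, gm, "female")
  pidx <- stats::setNames(seq_along(places), places)

  tn <- character(0); tk <- character(0)
  tsrc <- integer(0); tout <- integer(0); tmate <- integer(0)
  tcoef <- numeric(0); tker <- integer(0)
  kernels <- list()
  add_trans <- function(name, k, src, out = NA_integer_,
                        mate = NA_integer_, coef, ker = NA_integer_) {
    tn <<- c(tn, name); tk <<- c(tk, k); tsrc <<- c(tsrc, src)
    tout <<- c(tout, out); tmate <<- c(tmate, mate)
    tcoef <<- c(tcoef, coef); tker <<- c(tker, ker)
  }
  add_kernel <- function(dest, p_off, p_on) {
    kernels[[length(kernels) + 1L]] <<- list(dest = as.integer(dest),
                                             p_off = p_off, p_on = p_on)
    length(kernels)
  }

  egg1 <- pidx[paste0("E1_", ogeno)]
  # 1. oviposition, one per mated-female place
  for (gf in females) for (gm in males) {
    pr_off <- cube_off$tau[gf, gm, ok] * viab[ok]
    pr_on <- cube_on$tau[gf, gm, ok] * viab[ok]
    ker <- add_kernel(c(egg1, 0L),
                      c(pr_off, max(0, 1 - sum(pr_off))),
                      c(pr_on, max(0, 1 - sum(pr_on))))
    add_trans(paste0("ovi_", gf, "|", gm), "ovi",
              pidx[paste0("F_", gf, "|", gm)], coef = lp$beta, ker = ker)
  }
  # 2. stage advances; the last pupal advance is emergence
  for (g in ogeno) {
    for (i in seq_len(lp$n_E)) {
      nxt <- if (i < lp$n_E) paste0("E", i + 1L, "_", g) else paste0("L1_", g)
      add_trans(paste0("advE", i, "_", g), "advance",
                pidx[paste0("E", i, "_", g)], out = pidx[nxt], coef = g_E)
    }
    for (i in seq_len(lp$n_L)) {
      nxt <- if (i < lp$n_L) paste0("L", i + 1L, "_", g) else paste0("P1_", g)
      add_trans(paste0("advL", i, "_", g), "advance",
                pidx[paste0("L", i, "_", g)], out = pidx[nxt], coef = g_L)
    }
    if (lp$n_P > 1L) for (i in seq_len(lp$n_P - 1L)) {
      add_trans(paste0("advP", i, "_", g), "advance",
                pidx[paste0("P", i, "_", g)],
                out = pidx[paste0("P", i + 1L, "_", g)], coef = g_P)
    }
    gsex <- osex[match(g, ogeno)]
    lastP <- pidx[paste0("P", lp$n_P, "_", g)]
    if (gsex == "either") {
      ker <- add_kernel(c(pidx[paste0("U_", g)], pidx[paste0("M_", g)]),
                        c(lp$phi, 1 - lp$phi), c(lp$phi, 1 - lp$phi))
      add_trans(paste0("emerge_", g), "emergence", lastP, coef = g_P,
                ker = ker)
    } else {
      dest <- if (gsex == "female") pidx[paste0("U_", g)]
              else pidx[paste0("M_", g)]
      add_trans(paste0("emerge_", g), "emergence", lastP, out = dest,
                coef = g_P)
    }
  }
  # 3. aquatic deaths
  for (g in ogeno) {
    for (i in seq_len(lp$n_E))
      add_trans(paste0("dE", i, "_", g), "death",
                pidx[paste0("E", i, "_", g)], coef = lp$mu_E)
    for (i in seq_len(lp$n_L))
      add_trans(paste0("dL", i, "_", g), "larval_death",
                pidx[paste0("L", i, "_", g)], coef = lp$mu_L)
    for (i in seq_len(lp$n_P))
      add_trans(paste0("dP", i, "_", g), "death",
                pidx[paste0("P", i, "_", g)], coef = lp$mu_P)
  }
  # 4. mating: consumes the unmated female; mate genotype in proportion to
  # male counts (males are not consumed)
  for (gf in females) for (gm in males)
    add_trans(paste0("mate_", gf, "|", gm), "mating",
              pidx[paste0("U_", gf)], out = pidx[paste0("F_", gf, "|", gm)],
              mate = pidx[paste0("M_", gm)], coef = lp$nu)
  # 5. adult deaths
  for (g in males)
    add_trans(paste0("dM_", g), "death", pidx[paste0("M_", g)],
              coef = lp$mu_M)
  for (gf in females) for (gm in males)
    add_trans(paste0("dF_", gf, "|", gm), "death",
              pidx[paste0("F_", gf, "|", gm)], coef = lp$mu_F)

  place_info <- data.frame(place = places, kind = kind, genotype = geno,
                           mate = mate, sex = sex, stringsAsFactors = FALSE)
  larval_idx <- which(kind == "larva")
  male_idx <- which(kind == "male")

  wild_allele <- function(lab) !grepl("[GHVSRB]", sub(":.*", "", lab)) &
    !grepl("E", sub(".*:", "", lab))
  wildf <- females[wild_allele(females) &
                     !grepl("E", females)][1]
  wildm <- males[wild_allele(males)][1]
  wildo <- ogeno[wild_allele(ogeno)]

  .new_spn(places, place_info,
           list(name = tn, kind = tk, src = tsrc, out = tout, mate = tmate,
                coef = tcoef, kernel = tker),
           kernels, larval_idx, male_idx, K, lp, kind = "lifecycle",
           extra = list(females = females, males = males, ogeno = ogeno,
                        osex = osex, wild_female = wildf, wild_male = wildm,
                        wild_offspring = wildo))
}

#' Transition hazard vector
#'
#' Evaluates the rate of every transition at a state. In
#' `"sparse_first_order"` mode, any transition whose first (and only) input
#' place holds zero tokens has its rate set to 0 without evaluating the
#' hazard function, and the skip counter increments; `"dense"` mode
#' evaluates every hazard. Both modes return identical vectors, because the
#' SPN enabling rule forces a zero rate whenever the input place is empty.
#'
#' @param model An `spn_model`.
#' @param state Named or plain numeric vector of token counts per place.
#' @param molecule Is the small molecule present (selects the cube kernel;
#'   does not change hazards)?
#' @param mode `"sparse_first_order"` or `"dense"`.
#' @return Numeric vector of rates with attributes `n_evaluated` and
#'   `n_skipped`.
#' @export
hazard_vector <- function(model, state, molecule = FALSE,
                          mode = c("sparse_first_order", "dense")) {
  mode <- match.arg(mode)
  h <- .hazards(model, state, sparse = mode == "sparse_first_order")
  h
}

# internal hazard evaluation; returns vector with eval/skip counts
.hazards <- function(model, x, sparse) {
  tr <- model$trans
  nT <- model$n_transitions
  h <- numeric(nT)
  src_tokens <- x[tr$src]
  active <- if (sparse) src_tokens > 0 else rep(TRUE, nT)
  kinds <- tr$kind
  lin <- kinds %in% c("ovi", "advance", "emergence", "death", "linear",
                      "source")
  sel <- lin & active
  h[sel] <- tr$coef[sel] * src_tokens[sel]
  ld <- kinds == "larval_death"
  if (any(ld)) {
    sel <- ld & active
    if (any(sel)) {
      dens <- 1 + sum(x[model$larval_idx]) / model$K
      h[sel] <- tr$coef[sel] * dens * src_tokens[sel]
    }
  }
  mt <- kinds == "mating"
  if (any(mt)) {
    sel <- mt & active
    if (any(sel)) {
      Mtot <- sum(x[model$male_idx])
      if (Mtot > 0) {
        h[sel] <- tr$coef[sel] * src_tokens[sel] * x[tr$mate[sel]] / Mtot
      }
    }
  }
  attr(h, "n_evaluated") <- sum(active)
  attr(h, "n_skipped") <- nT - sum(active)
  h
}

#' Export an SPN model summary as JSON
#'
#' Writes places, transitions (kind, input, output, rate coefficient), and
#' hazard kinds for audit and golden-file comparison.
#'
#' @param model An `spn_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_spn_summary <- function(model, path) {
  tr <- model$trans
  out <- list(
    kind = model$kind,
    n_places = model$n_places,
    n_transitions = model$n_transitions,
    places = model$places,
    transitions = data.frame(
      name = tr$name, kind = tr$kind,
      input = model$places[tr$src],
      output = ifelse(is.na(tr$out), NA_character_, model$places[tr$out]),
      coef = tr$coef, has_kernel = !is.na(tr$kernel),
      stringsAsFactors = FALSE))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
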