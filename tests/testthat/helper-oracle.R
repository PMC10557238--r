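# Shared test fixtures and the independent Monte-Carlo gamete oracle.
# The oracle simulates the branching repair tree draw by draw, with its own
# genotype parsing, so it shares no code path with the analytic gamete
# distributions it is used to check.

ALL_DESIGNS <- c("CIS_AUTO", "CIS_X", "TRANS_AUTO_AUTO", "TRANS_AUTO_X",
                 "TRANS_X_AUTO")
ALL_FLAVORS <- c("COMPLETE", "REDUCED", "SIMPLIFIED")

# greedy allele tokenizer ("B0" before "B")
split_alleles <- function(s) {
  tokens <- c("B0", "B", "G", "H", "R", "S", "V", "W", "E", "w", "Y")
  out <- character(0)
  while (nchar(s) > 0) {
    hit <- tokens[startsWith(s, tokens)][1]
    if (is.na(hit)) stop("cannot tokenize ", s)
    out <- c(out, hit)
    s <- substring(s, nchar(hit) + 1)
  }
  out
}

# n Monte-Carlo draws of the full gametogenesis (homing then SEM), as a
# named probability vector over observed gamete labels
mc_gamete_oracle <- function(g, dp, sp, spec, molecule, n) {
  parts <- strsplit(g, ":", fixed = TRUE)[[1]]
  dal <- split_alleles(parts[1])
  sal <- if (length(parts) > 1) split_alleles(parts[2]) else NULL
  stopifnot(length(dal) == 2, is.null(sal) || length(sal) == 2)

  p_eff <- if (spec$inducible_drive && !molecule) 0 else dp$p
  sem_on <- !(spec$inducible_sem && !molecule)
  has_E <- !is.null(sal) && any(sal == "E")
  sem_applies <- sem_on && (is.null(sal) || has_E)
  if (!startsWith(spec$design_id, "TRANS")) sem_applies <- sem_on

  resolve_drive <- function(a, partner, n) {
    out <- rep(a, n)
    if (a == "W" && partner %in% c("G", "H", "S")) {
      cleaved <- stats::runif(n) < p_eff
      conv <- stats::runif(n) < dp$q
      target <- if (partner == "S") "S" else "G"
      out[cleaved & conv] <- target
      nhej <- cleaved & !conv
      if (any(nhej)) {
        out[nhej] <- switch(spec$flavor,
          COMPLETE = ifelse(stats::runif(sum(nhej)) < dp$rho, "R", "B"),
          REDUCED = "R",
          SIMPLIFIED = "B0")
      }
    }
    out
  }
  d1 <- resolve_drive(dal[1], dal[2], n)
  d2 <- resolve_drive(dal[2], dal[1], n)
  pick <- stats::runif(n) < 0.5
  dg <- ifelse(pick, d1, d2)
  if (sem_applies) {
    isH <- dg == "H"  # parental H (homing never produces H)
    if (any(isH)) {
      m <- sum(isH)
      ssa <- stats::runif(m) < sp$b
      toV <- stats::runif(m) < sp$c
      res <- ifelse(ssa, ifelse(toV, "V", "W"),
                    if (spec$sem_resistance) "S" else "H")
      dg[isH] <- res
    }
    isG <- dg == "G"
    if (any(isG)) {
      act <- stats::runif(sum(isG)) < sp$a
      dg[isG][act] <- "H"
    }
  }
  lab <- dg
  if (!is.null(sal)) {
    sg <- ifelse(stats::runif(n) < 0.5, sal[1], sal[2])
    lab <- paste(dg, sg, sep = ":")
  }
  table(lab) / n
}

# compare analytic distribution to the oracle within k standard errors
expect_oracle_match <- function(analytic, mc, n, k = 4) {
  labs <- union(names(analytic), names(mc))
  for (l in labs) {
    pa <- if (l %in% names(analytic)) analytic[[l]] else 0
    pm <- if (l %in% names(mc)) as.numeric(mc[[l]]) else 0
    se <- sqrt(pa * (1 - pa) / n)
    if (se == 0) {
      expect_equal(pm, pa, tolerance = 1e-12,
                   label = paste0("degenerate outcome ", l))
    } else {
      expect_lt(abs(pm - pa), k * se + 1e-12,
                label = paste0("outcome ", l, " |diff|"))
    }
  }
}

# small fig-2D style scenario objects shared across engine/analysis tests
fig2d_objects <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- preset_fig2d()
      cache <<- build_scenario(cfg)
      cache$cfg <- cfg
    }
    cache
  }
})

adult_kinds <- c("unmated_female", "male", "mated_female")

total_adults <- function(model, counts_row) {
  sum(counts_row[model$place_info$kind %in% adult_kinds])
}
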