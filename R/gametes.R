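# Gamete distributions: homing at the drive locus followed by SEM
# activation/resolution, then independent assortment across loci.
#
# Serialization of the two construct behaviors within one gametogenesis:
#   1. homing resolves each cleavable W (producing the gamete pool),
#   2. SEM activation turns gamete G alleles into H with probability a,
#   3. parental H alleles resolve to V / W / S (the per-symbol transform is
#      applied once, so an H newly created in step 2 is NOT re-resolved).
# Homologous-recombination conversion copies the partner's DNA: a G or H
# template yields G (endonuclease activation is not heritable through
# copying), an S template yields S.

# per-case drive-allele outcome distributions, rows = cases, cols = drive
# gamete alleles (union incl. Y); depends on DriveParams and flavor
.drive_case_matrix <- function(sk, dp, p_eff) {
  cols <- unique(c(sk$dga_m, sk$dga_f))
  D <- matrix(0, length(sk$cases), length(cols),
              dimnames = list(sk$cases, cols))
  for (cs in sk$cases) {
    if (startsWith(cs, "pass_")) {
      al <- sub("^pass_", "", cs)
      if (al %in% cols) D[cs, al] <- 1
    } else {
      target <- if (cs == "convG") "G" else "S"
      if (!target %in% cols) next  # convS unreachable without allele S
      D[cs, "W"] <- 1 - p_eff
      D[cs, target] <- D[cs, target] + p_eff * dp$q
      nh <- p_eff * (1 - dp$q)
      if (nh > 0) {
        switch(sk$spec$flavor,
               COMPLETE = {
                 D[cs, "R"] <- D[cs, "R"] + nh * dp$rho
                 D[cs, "B"] <- D[cs, "B"] + nh * (1 - dp$rho)
               },
               REDUCED = D[cs, "R"] <- D[cs, "R"] + nh,
               SIMPLIFIED = D[cs, "B0"] <- D[cs, "B0"] + nh)
      }
    }
  }
  D
}

# per-symbol SEM transform over a drive gamete allele set
.sem_transform_matrix <- function(alleles, sp, sem_resistance) {
  T <- diag(length(alleles))
  dimnames(T) <- list(alleles, alleles)
  if ("G" %in% alleles) {
    T["G", "G"] <- 1 - sp$a
    T["G", "H"] <- sp$a
  }
  if ("H" %in% alleles) {
    T["H", ] <- 0
    T["H", "V"] <- sp$b * sp$c
    T["H", "W"] <- sp$b * (1 - sp$c)
    if (sem_resistance) T["H", "S"] <- 1 - sp$b
    else T["H", "H"] <- 1 - sp$b
  }
  T
}

# is the SEM transform active at all for this call?
.sem_active <- function(spec, molecule_present) {
  !(spec$inducible_sem && !molecule_present)
}

.drive_active_p <- function(spec, dp, molecule_present) {
  if (spec$inducible_drive && !molecule_present) 0 else dp$p
}

# gamete matrix (parents x gametes of that sex) after homing only
.drive_gamete_matrix <- function(sk, sex, dp, p_eff) {
  D <- .drive_case_matrix(sk, dp, p_eff)
  case <- if (sex == "female") sk$case_f else sk$case_m
  dga <- if (sex == "female") sk$dga_f else sk$dga_m
  Gd <- 0.5 * (D[case[, 1], dga, drop = FALSE] +
               D[case[, 2], dga, drop = FALSE])
  rownames(Gd) <- NULL
  Gd
}

# apply SEM transform to a drive-marginal matrix, honoring trans-design
# gating (rows of parents lacking the E element are left untouched)
.apply_sem <- function(sk, sex, Gd, sp, molecule_present) {
  spec <- sk$spec
  if (!.sem_active(spec, molecule_present)) return(Gd)
  dga <- colnames(Gd)
  T <- .sem_transform_matrix(dga, sp, spec$sem_resistance)
  out <- Gd %*% T
  hasE <- if (sex == "female") sk$hasE_f else sk$hasE_m
  if (!all(hasE)) out[!hasE, ] <- Gd[!hasE, ]
  dimnames(out) <- dimnames(Gd)
  out
}

# full gamete matrix (parents x gamete table rows) for one sex
.gamete_matrix <- function(sk, sex, dp, sp, molecule_present) {
  spec <- sk$spec
  p_eff <- .drive_active_p(spec, dp, molecule_present)
  Gd <- .drive_gamete_matrix(sk, sex, dp, p_eff)
  colnames(Gd) <- if (sex == "female") sk$dga_f else sk$dga_m
  Gd <- .apply_sem(sk, sex, Gd, sp, molecule_present)
  gt <- if (sex == "female") sk$gam_f else sk$gam_m
  if (!has_sem_locus(spec)) {
    G <- Gd[, gt$d, drop = FALSE]
  } else {
    Gs <- if (sex == "female") sk$sem_f else sk$sem_m
    G <- Gd[, gt$d, drop = FALSE] * Gs[, gt$s, drop = FALSE]
  }
  colnames(G) <- gt$label
  G
}

.dist_from_row <- function(row) {
  row <- row[row > 0]
  out <- as.numeric(row)
  names(out) <- names(row)
  out
}

#' Gamete distribution after homing
#'
#' Resolves drive-mediated cleavage and repair for one parental genotype and
#' returns the distribution of gamete haplotypes before any SEM activity.
#' Each cleavable `W` allele opposite an active drive allele (`G`, `H`, or
#' `S`) is independently cleaved with probability `p`; a cleaved allele is
#' converted by homologous recombination with probability `q`, otherwise the
#' NHEJ branch yields the flavor's resistance product (`R`/`B`, `R`, or the
#' unviable token `B0`). Meiosis then draws one allele per locus uniformly;
#' loci assort independently. `V`, `R`, `B`, and `S` are never cleaved.
#'
#' @param g Genotype label from [enumerate_genotypes()].
#' @param dp [drive_params()].
#' @param spec [design_spec()]; with `inducible_drive = TRUE` and
#'   `molecule_present = FALSE`, homing is suppressed (`p` treated as 0).
#' @param molecule_present Is the small molecule applied?
#' @return Named numeric vector of gamete probabilities (zero-mass gametes
#'   dropped); sums to 1.
#' @export
drive_gamete_dist <- function(g, dp, spec, molecule_present = FALSE) {
  stopifnot(inherits(spec, "design_spec"), inherits(dp, "drive_params"))
  loc <- .find_genotype(spec, g)
  sk <- .skeleton(spec)
  p_eff <- .drive_active_p(spec, dp, molecule_present)
  Gd <- .drive_gamete_matrix(sk, loc$sex, dp, p_eff)
  colnames(Gd) <- if (loc$sex == "female") sk$dga_f else sk$dga_m
  gt <- if (loc$sex == "female") sk$gam_f else sk$gam_m
  if (!has_sem_locus(spec)) {
    row <- Gd[loc$row, gt$d]
  } else {
    Gs <- if (loc$sex == "female") sk$sem_f else sk$sem_m
    row <- Gd[loc$row, gt$d] * Gs[loc$row, gt$s]
  }
  names(row) <- gt$label
  .dist_from_row(row)
}

#' Apply the self-elimination transform to a gamete distribution
#'
#' With the molecule present (or an always-on SEM), each `G` allele in the
#' gametes is activated to `H` with probability `a`, and each `H` allele
#' inherited from the parental genotype resolves to the excised
#' cut-resistant wild-type `V` with probability `b*c`, to susceptible `W`
#' with probability `b*(1-c)`, and with probability `1-b` to the
#' SEM-resistant allele `S` (when `sem_resistance`) or remains `H` (to be
#' re-resolved next generation) otherwise. For trans-acting designs the
#' transform requires at least one copy of the SEM element `E` in the
#' parent; with `inducible_sem = TRUE` and no molecule it is the identity.
#'
#' @param d Gamete distribution from [drive_gamete_dist()].
#' @param g The parental genotype label the gametes came from.
#' @param sp [sem_params()].
#' @param spec [design_spec()].
#' @param molecule_present Is the small molecule applied?
#' @return Named numeric vector of gamete probabilities; mass conserved.
#' @export
sem_transform <- function(d, g, sp, spec, molecule_present = FALSE) {
  stopifnot(inherits(spec, "design_spec"), inherits(sp, "sem_params"))
  loc <- .find_genotype(spec, g)
  sk <- .skeleton(spec)
  if (!.sem_active(spec, molecule_present)) return(d)
  hasE <- if (loc$sex == "female") sk$hasE_f[loc$row] else sk$hasE_m[loc$row]
  if (!hasE) return(d)
  gt <- if (loc$sex == "female") sk$gam_f else sk$gam_m
  idx <- match(names(d), gt$label)
  if (anyNA(idx))
    stop("domain error: gamete label(s) ",
         paste(names(d)[is.na(idx)], collapse = ", "),
         " not in the ", spec$design_id, " gamete set", call. = FALSE)
  dga <- if (loc$sex == "female") sk$dga_f else sk$dga_m
  T <- .sem_transform_matrix(dga, sp, spec$sem_resistance)
  out <- numeric(nrow(gt))
  names(out) <- gt$label
  for (k in seq_along(d)) {
    row <- gt[idx[k], ]
    w <- T[row$d, ]
    dest <- if (has_sem_locus(spec)) paste(names(w), row$s, sep = ":")
            else names(w)
    keep <- w > 0
    out[dest[keep]] <- out[dest[keep]] + d[k] * w[keep]
  }
  .dist_from_row(out)
}
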