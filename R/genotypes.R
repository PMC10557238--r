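# Genotype enumeration, canonical labels, and the parameter-independent
# "skeleton" (genotype tables, gamete sets, gamete-pair -> offspring map)
# shared by the gamete and cube builders. Skeletons are cached per design.

.skel_cache <- new.env(parent = emptyenv())

# unordered pairs with repetition, in canonical (rank-sorted) order
.allele_pairs <- function(alleles) {
  n <- length(alleles)
  a1 <- character(0); a2 <- character(0)
  for (i in seq_len(n)) for (j in i:n) {
    a1 <- c(a1, alleles[i]); a2 <- c(a2, alleles[j])
  }
  data.frame(a1 = a1, a2 = a2, stringsAsFactors = FALSE)
}

# hemizygous: one X allele plus the Y placeholder
.hemi_pairs <- function(alleles) {
  data.frame(a1 = alleles, a2 = "Y", stringsAsFactors = FALSE)
}

.locus_label <- function(a1, a2) {
  r1 <- .ALLELE_RANK[a1]; r2 <- .ALLELE_RANK[a2]
  ifelse(r1 <= r2, paste0(a1, a2), paste0(a2, a1))
}

# genotype table for one sex: columns d1, d2 [, s1, s2], label
.genotype_table <- function(spec, sex, offspring = FALSE) {
  da <- drive_alphabet(spec, offspring = offspring)
  dpairs <- if (drive_chrom(spec) == "X" && sex == "male") {
    .hemi_pairs(da)
  } else {
    .allele_pairs(da)
  }
  if (!has_sem_locus(spec)) {
    tab <- dpairs
    names(tab) <- c("d1", "d2")
    tab$label <- .locus_label(tab$d1, tab$d2)
    return(tab)
  }
  spairs <- if (sem_chrom(spec) == "X" && sex == "male") {
    .hemi_pairs(sem_alphabet())
  } else {
    .allele_pairs(sem_alphabet())
  }
  nd <- nrow(dpairs); ns <- nrow(spairs)
  tab <- data.frame(
    d1 = rep(dpairs$a1, each = ns), d2 = rep(dpairs$a2, each = ns),
    s1 = rep(spairs$a1, times = nd), s2 = rep(spairs$a2, times = nd),
    stringsAsFactors = FALSE)
  tab$label <- paste(.locus_label(tab$d1, tab$d2),
                     .locus_label(tab$s1, tab$s2), sep = ":")
  tab
}

# gamete table for one sex: one allele per locus
.gamete_table <- function(spec, sex) {
  da <- drive_alphabet(spec, offspring = TRUE)  # gametes may carry B0
  dg <- if (drive_chrom(spec) == "X" && sex == "male") c(da, "Y") else da
  if (!has_sem_locus(spec)) {
    return(data.frame(d = dg, label = dg, stringsAsFactors = FALSE))
  }
  sa <- sem_alphabet()
  sg <- if (sem_chrom(spec) == "X" && sex == "male") c(sa, "Y") else sa
  tab <- data.frame(d = rep(dg, each = length(sg)),
                    s = rep(sg, times = length(dg)),
                    stringsAsFactors = FALSE)
  tab$label <- paste(tab$d, tab$s, sep = ":")
  tab
}

.sexed_design <- function(spec) {
  drive_chrom(spec) == "X" || (has_sem_locus(spec) && sem_chrom(spec) == "X")
}

# offspring genotype index. For all-autosomal designs genotypes are sexless
# (sex is assigned at adult emergence); for X-linked designs male labels
# carry the Y token and the index spans both sexes.
.offspring_table <- function(spec) {
  f <- .genotype_table(spec, "female", offspring = TRUE)
  if (!.sexed_design(spec)) {
    f$sex <- "either"
    return(f)
  }
  m <- .genotype_table(spec, "male", offspring = TRUE)
  f$sex <- "female"; m$sex <- "male"
  rbind(f, m)
}

# drive-locus per-allele outcome case, given the partner allele at the locus
.drive_case <- function(a, partner) {
  ifelse(a == "W" & partner %in% c("G", "H"), "convG",
         ifelse(a == "W" & partner == "S", "convS", paste0("pass_", a)))
}

.build_skeleton <- function(spec) {
  fem <- .genotype_table(spec, "female")
  mal <- .genotype_table(spec, "male")
  off <- .offspring_table(spec)
  gam_f <- .gamete_table(spec, "female")
  gam_m <- .gamete_table(spec, "male")

  da_off <- drive_alphabet(spec, offspring = TRUE)
  # drive gamete allele sets per sex (Y token for X-linked drive in males)
  dga_f <- da_off
  dga_m <- if (drive_chrom(spec) == "X") c(da_off, "Y") else da_off

  cases <- c(paste0("pass_", unique(c(da_off, "Y"))), "convG", "convS")

  parent_cases <- function(tab) {
    cbind(match(.drive_case(tab$d1, tab$d2), cases),
          match(.drive_case(tab$d2, tab$d1), cases))
  }
  case_f <- parent_cases(fem)
  case_m <- parent_cases(mal)

  # sem-locus Mendelian marginals are parameter-free
  sem_marg <- function(tab, sex) {
    if (!has_sem_locus(spec)) return(NULL)
    sg <- .gamete_table(spec, sex)
    sga <- unique(sg$s)
    m <- matrix(0, nrow(tab), length(sga), dimnames = list(NULL, sga))
    for (k in seq_len(nrow(tab))) {
      m[k, tab$s1[k]] <- m[k, tab$s1[k]] + 0.5
      m[k, tab$s2[k]] <- m[k, tab$s2[k]] + 0.5
    }
    m
  }
  sem_f <- sem_marg(fem, "female")
  sem_m <- sem_marg(mal, "male")

  # parent carries >= 1 trans-acting SEM element?
  hasE_f <- if (has_sem_locus(spec)) fem$s1 == "E" | fem$s2 == "E"
            else rep(TRUE, nrow(fem))
  hasE_m <- if (has_sem_locus(spec)) mal$s1 == "E" | mal$s2 == "E"
            else rep(TRUE, nrow(mal))

  # gamete-pair -> offspring index map
  sexed <- .sexed_design(spec)
  omap <- matrix(NA_integer_, nrow(gam_f), nrow(gam_m))
  for (i in seq_len(nrow(gam_f))) {
    for (j in seq_len(nrow(gam_m))) {
      dl <- .locus_label(gam_f$d[i], gam_m$d[j])
      lab <- if (has_sem_locus(spec)) {
        paste(dl, .locus_label(gam_f$s[i], gam_m$s[j]), sep = ":")
      } else dl
      k <- match(lab, off$label)
      if (is.na(k)) stop("internal: unmapped offspring genotype ", lab)
      omap[i, j] <- k
    }
  }

  # gamete-pair groups per offspring genotype (for BLAS cube assembly)
  ogroups <- vector("list", nrow(off))
  pair_o <- as.vector(omap)
  pair_i <- rep(seq_len(nrow(gam_f)), times = nrow(gam_m))
  pair_j <- rep(seq_len(nrow(gam_m)), each = nrow(gam_f))
  for (o in unique(pair_o)) {
    sel <- pair_o == o
    ogroups[[o]] <- list(i = pair_i[sel], j = pair_j[sel])
  }

  # allele-count map over the full alphabet (Y excluded)
  alphabet <- da_off
  if (has_sem_locus(spec)) alphabet <- c(alphabet, sem_alphabet())
  counts <- matrix(0L, nrow(off), length(alphabet),
                   dimnames = list(off$label, alphabet))
  add_allele <- function(counts, al) {
    sel <- al != "Y"
    idx <- cbind(which(sel), match(al[sel], alphabet))
    for (r in seq_len(nrow(idx)))
      counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + 1L
    counts
  }
  counts <- add_allele(counts, off$d1)
  counts <- add_allele(counts, off$d2)
  if (has_sem_locus(spec)) {
    counts <- add_allele(counts, off$s1)
    counts <- add_allele(counts, off$s2)
  }

  viable <- off$d1 != "B0" & off$d2 != "B0"

  list(spec = spec, females = fem, males = mal, offspring = off,
       gam_f = gam_f, gam_m = gam_m, dga_f = dga_f, dga_m = dga_m,
       cases = cases, case_f = case_f, case_m = case_m,
       sem_f = sem_f, sem_m = sem_m, hasE_f = hasE_f, hasE_m = hasE_m,
       omap = omap, ogroups = ogroups, alphabet = alphabet,
       allele_counts = counts, viable = viable)
}

.skeleton <- function(spec) {
  key <- paste(spec$design_id, spec$flavor, spec$sem_resistance, sep = "|")
  sk <- .skel_cache[[key]]
  if (is.null(sk)) {
    sk <- .build_skeleton(spec)
    .skel_cache[[key]] <- sk
  }
  sk
}

#' Enumerate the genotypes of a design
#'
#' Returns the complete, duplicate-free, canonically ordered genotype list
#' for one sex. Within each locus alleles are sorted; loci are joined with
#' `":"` (drive locus first); hemizygous X-linked loci in males carry the
#' `Y` placeholder. Parents are always viable; with `offspring = TRUE` the
#' index is extended by genotypes carrying the unviable SIMPLIFIED-flavor
#' token `B0`.
#'
#' @param spec A [design_spec()].
#' @param sex `"female"` or `"male"`.
#' @param offspring Extend the alphabet with the `B0` token (SIMPLIFIED)?
#' @return Character vector of genotype labels.
#' @export
enumerate_genotypes <- function(spec, sex = c("female", "male"),
                                offspring = FALSE) {
  stopifnot(inherits(spec, "design_spec"))
  sex <- match.arg(sex)
  .genotype_table(spec, sex, offspring = offspring)$label
}

# locate a genotype label; returns list(sex, row) or errors
.find_genotype <- function(spec, g) {
  sk <- .skeleton(spec)
  i <- match(g, sk$females$label)
  if (!is.na(i)) return(list(sex = "female", row = i))
  i <- match(g, sk$males$label)
  if (!is.na(i)) return(list(sex = "male", row = i))
  stop("domain error: genotype ", deparse(g), " is not in the ",
       spec$design_id, "/", spec$flavor, " alphabet", call. = FALSE)
}
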