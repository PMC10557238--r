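# Inheritance cubes: offspring-genotype probability tensors indexed by
# (maternal genotype, paternal genotype), with per-genotype viability.

#' Build an inheritance cube
#'
#' For every (female, male) genotype pair the offspring distribution is the
#' outer product of the parents' final gamete distributions (homing followed
#' by the SEM transform), marginalized onto canonical offspring genotypes.
#' For designs with an X-linked locus, offspring sex is determined by the
#' sex-chromosome content and the offspring index spans both sexes; for
#' all-autosomal designs genotypes are sexless and sex is assigned at adult
#' emergence. Viability is 0 for genotypes carrying the unviable token `B0`
#' (SIMPLIFIED-flavor NHEJ products, removed at the egg stage) and 1
#' otherwise.
#'
#' @param spec [design_spec()].
#' @param dp [drive_params()].
#' @param sp [sem_params()].
#' @param molecule_present Is the small molecule applied during this
#'   gametogenesis?
#' @return An `inheritance_cube`: list with `tau` (array female x male x
#'   offspring), genotype indices, `viability`, `allele_counts`,
#'   `offspring_sex`, and metadata.
#' @export
build_cube <- function(spec, dp, sp, molecule_present = FALSE) {
  stopifnot(inherits(spec, "design_spec"), inherits(dp, "drive_params"),
            inherits(sp, "sem_params"))
  sk <- .skeleton(spec)
  Gf <- .gamete_matrix(sk, "female", dp, sp, molecule_present)
  Gm <- .gamete_matrix(sk, "male", dp, sp, molecule_present)
  .assemble_cube(sk, Gf, Gm, spec, dp, sp, molecule_present)
}

.assemble_cube <- function(sk, Gf, Gm, spec, dp, sp, molecule_present) {
  nF <- nrow(sk$females); nM <- nrow(sk$males); nO <- nrow(sk$offspring)
  # tau[f, m, o] = sum over gamete pairs (i, j) mapping to offspring o of
  # Gf[f, i] * Gm[m, j]; batched per offspring as a single crossproduct
  tau <- array(0, dim = c(nF, nM, nO),
               dimnames = list(sk$females$label, sk$males$label,
                               sk$offspring$label))
  for (o in seq_len(nO)) {
    gr <- sk$ogroups[[o]]
    if (is.null(gr)) next
    tau[, , o] <- tcrossprod(Gf[, gr$i, drop = FALSE],
                             Gm[, gr$j, drop = FALSE])
  }
  viability <- as.numeric(sk$viable)
  names(viability) <- sk$offspring$label
  structure(
    list(tau = tau,
         females = sk$females$label, males = sk$males$label,
         offspring = sk$offspring$label,
         offspring_sex = sk$offspring$sex,
         viability = viability,
         allele_counts = sk$allele_counts,
         alphabet = sk$alphabet,
         spec = spec, drive_params = dp, sem_params = sp,
         molecule = molecule_present),
    class = "inheritance_cube")
}

#' The pure Mendelian cube on a design's alphabet
#'
#' Reference cube with homing and SEM both inert: every allele is
#' transmitted with probability 1/2 per locus and loci assort
#' independently. Identical to [build_cube()] with `p = 0`, `a = 0` and the
#' construct uninduced.
#'
#' @inheritParams build_cube
#' @return An `inheritance_cube`.
#' @export
mendelian_cube <- function(spec) {
  sk <- .skeleton(spec)
  dp <- drive_params(0, 0)
  sp <- sem_params(0, 0, 0)
  Gf <- .gamete_matrix(sk, "female", dp, sp, molecule_present = FALSE)
  Gm <- .gamete_matrix(sk, "male", dp, sp, molecule_present = FALSE)
  # force the SEM step to be skipped regardless of induction flags
  cube <- .assemble_cube(sk, Gf, Gm, spec, dp, sp, FALSE)
  cube
}

#' @export
print.inheritance_cube <- function(x, ...) {
  cat("<inheritance_cube> ", x$spec$design_id, "/", x$spec$flavor,
      if (x$spec$sem_resistance) " +S" else "",
      "  molecule=", if (x$molecule) "on" else "off", "\n", sep = "")
  cat("  ", length(x$females), " female x ", length(x$males),
      " male x ", length(x$offspring), " offspring genotypes\n", sep = "")
  invisible(x)
}

#' Validate an inheritance cube
#'
#' Checks that every (female, male) row sums to 1 within tolerance, that all
#' entries and viabilities lie in `[0, 1]`, and that offspring sex labels
#' are consistent with their sex-chromosome content (a genotype carrying the
#' Y token must be male).
#'
#' @param cube An `inheritance_cube`.
#' @param tol Row-mass tolerance (default `1e-10`).
#' @return A `cube_validation` report: `pass`, `max_row_dev`, offending row
#'   indices, entry-range and sex-consistency violation counts.
#' @export
validate_cube <- function(cube, tol = 1e-10) {
  stopifnot(inherits(cube, "inheritance_cube"))
  d <- dim(cube$tau)
  # row of the cube = fixed (female, male) pair; sum over offspring without
  # reshaping copies
  rs <- matrix(.rowSums(cube$tau, d[1] * d[2], d[3]), d[1], d[2])
  dev <- abs(rs - 1)
  bad <- which(dev > tol, arr.ind = TRUE)
  bad_rows <- if (nrow(bad)) {
    data.frame(female = cube$females[bad[, 1]], male = cube$males[bad[, 2]],
               deviation = dev[bad], stringsAsFactors = FALSE)
  } else {
    data.frame(female = character(0), male = character(0),
               deviation = numeric(0))
  }
  rng <- c(min(cube$tau), max(cube$tau))
  n_neg <- if (rng[1] < 0) sum(cube$tau < 0) else 0L
  n_sup <- if (rng[2] > 1 + tol) sum(cube$tau > 1 + tol) else 0L
  viab_ok <- all(cube$viability >= 0 & cube$viability <= 1)
  has_y <- grepl("Y", cube$offspring, fixed = TRUE)
  sex_viol <- sum((has_y & cube$offspring_sex == "female") |
                  (!has_y & cube$offspring_sex == "male"))
  pass <- nrow(bad_rows) == 0 && n_neg == 0 && n_sup == 0 && viab_ok &&
    sex_viol == 0
  structure(list(pass = pass, max_row_dev = max(dev),
                 bad_rows = bad_rows, n_negative = n_neg,
                 n_above_one = n_sup, viability_ok = viab_ok,
                 sex_violations = sex_viol, tol = tol),
            class = "cube_validation")
}

#' @export
print.cube_validation <- function(x, ...) {
  cat("<cube_validation> ", if (x$pass) "PASS" else "FAIL",
      "  max row deviation ", format(x$max_row_dev, digits = 3), "\n",
      sep = "")
  if (nrow(x$bad_rows)) {
    cat("  rows off mass:\n")
    print(utils::head(x$bad_rows, 10))
  }
  if (x$n_negative) cat("  negative entries:", x$n_negative, "\n")
  if (x$n_above_one) cat("  entries > 1:", x$n_above_one, "\n")
  if (x$sex_violations) cat("  sex violations:", x$sex_violations, "\n")
  invisible(x)
}

#' Genotype-to-allele-count map
#'
#' Integer count of each allele symbol per offspring genotype; Y placeholder
#' tokens are excluded.
#'
#' @param cube An `inheritance_cube`.
#' @return Integer matrix, rows = offspring genotypes, columns = alleles.
#' @export
allele_count_map <- function(cube) {
  stopifnot(inherits(cube, "inheritance_cube"))
  cube$allele_counts
}

#' Export a cube as a plain-text bundle
#'
#' Writes one TSV per female genotype (rows = male genotypes, columns =
#' offspring genotypes, probabilities at 17 significant digits) and a JSON
#' metadata sidecar (design, flavor, parameters, alphabet, viability).
#'
#' @param cube An `inheritance_cube`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_cube <- function(cube, dir) {
  stopifnot(inherits(cube, "inheritance_cube"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  safe <- function(x) gsub(":", "-", x, fixed = TRUE)
  for (i in seq_along(cube$females)) {
    m <- cube$tau[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = length(cube$males))
    df <- as.data.frame(format(m, digits = 17, scientific = TRUE,
                               trim = TRUE), stringsAsFactors = FALSE)
    names(df) <- cube$offspring
    df <- cbind(male = cube$males, df)
    utils::write.table(
      df, file.path(dir, paste0("cube_", safe(cube$females[i]), ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- list(
    design_id = cube$spec$design_id, flavor = cube$spec$flavor,
    sem_resistance = cube$spec$sem_resistance,
    inducible_drive = cube$spec$inducible_drive,
    inducible_sem = cube$spec$inducible_sem,
    molecule = cube$molecule,
    drive_params = unclass(cube$drive_params),
    sem_params = unclass(cube$sem_params),
    females = cube$females, males = cube$males, offspring = cube$offspring,
    offspring_sex = cube$offspring_sex, alphabet = cube$alphabet,
    viability = as.list(cube$viability))
  jsonlite::write_json(meta, file.path(dir, "cube_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Import a cube bundle written by [export_cube()]
#'
#' @param dir Directory containing the TSV files and metadata sidecar.
#' @return An `inheritance_cube`.
#' @export
import_cube <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cube_metadata.json"),
                              simplifyVector = TRUE)
  spec <- design_spec(meta$design_id, meta$flavor, meta$sem_resistance,
                      meta$inducible_drive, meta$inducible_sem)
  dp <- drive_params(meta$drive_params$p, meta$drive_params$q,
                     meta$drive_params$rho)
  sp <- sem_params(meta$sem_params$a, meta$sem_params$b, meta$sem_params$c)
  sk <- .skeleton(spec)
  stopifnot(identical(sk$females$label, meta$females),
            identical(sk$males$label, meta$males),
            identical(sk$offspring$label, meta$offspring))
  tau <- array(0, dim = c(length(meta$females), length(meta$males),
                          length(meta$offspring)),
               dimnames = list(meta$females, meta$males, meta$offspring))
  safe <- function(x) gsub(":", "-", x, fixed = TRUE)
  for (i in seq_along(meta$females)) {
    df <- utils::read.table(
      file.path(dir, paste0("cube_", safe(meta$females[i]), ".tsv")),
      sep = "\t", header = TRUE, check.names = FALSE,
      colClasses = c("character", rep("numeric", length(meta$offspring))))
    stopifnot(identical(df$male, meta$males))
    tau[i, , ] <- as.matrix(df[, -1, drop = FALSE])
  }
  viability <- unlist(meta$viability)
  cube <- structure(
    list(tau = tau, females = meta$females, males = meta$males,
         offspring = meta$offspring, offspring_sex = meta$offspring_sex,
         viability = viability, allele_counts = sk$allele_counts,
         alphabet = meta$alphabet, spec = spec, drive_params = dp,
         sem_params = sp, molecule = meta$molecule),
    class = "inheritance_cube")
  cube
}
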