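#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Allele symbols
##   W  susceptible wild-type
##   G  intact drive construct (homing-active, SEM-capable)
##   H  drive construct whose secondary endonuclease has been activated
##   V  excised cut-resistant wild-type (product of SSA repair)
##   S  construct with an NHEJ-disrupted SEM target site (homing-active,
##      excision-immune); only present when sem_resistance = TRUE
##   R  in-frame drive-resistant allele (REDUCED and COMPLETE flavors)
##   B  out-of-frame drive-resistant allele (COMPLETE flavor)
##   B0 unviable NHEJ product token (SIMPLIFIED flavor); any zygote carrying
##      it has viability 0
##   E/w presence/absence of the trans-acting SEM element at its own locus
##   Y  placeholder for the Y chromosome at X-linked loci in males

SEM_DESIGNS <- c("CIS_AUTO", "CIS_X", "TRANS_AUTO_AUTO", "TRANS_AUTO_X",
                 "TRANS_X_AUTO")
SEM_FLAVORS <- c("COMPLETE", "REDUCED", "SIMPLIFIED")

# sort ranks: alphabetical within each locus alphabet, Y always last
.ALLELE_RANK <- c(B = 1, B0 = 2, G = 3, H = 4, R = 5, S = 6, V = 7, W = 8,
                  E = 1, w = 2, Y = 99)

#' Specify a self-eliminating gene-drive design
#'
#' A design couples a CRISPR homing drive with a self-eliminating mechanism
#' (SEM): a secondary endonuclease encoded within the construct that, once
#' activated by a small molecule, excises the transgene by single-strand
#' annealing and leaves a cut-resistant wild-type allele behind.
#'
#' @param design_id One of `"CIS_AUTO"` (construct and SEM on one autosomal
#'   locus), `"CIS_X"` (one X-linked locus), `"TRANS_AUTO_AUTO"`,
#'   `"TRANS_AUTO_X"`, `"TRANS_X_AUTO"` (drive locus and SEM-element locus on
#'   the chromosomes named in that order).
#' @param flavor Resistance-allele treatment at the drive locus:
#'   `"COMPLETE"` (in-frame `R` and out-of-frame `B` NHEJ products),
#'   `"REDUCED"` (`R` only), `"SIMPLIFIED"` (NHEJ yields the unviable token
#'   `B0`; fastest alphabet).
#' @param sem_resistance Include the SEM-resistant allele `S` (NHEJ at the
#'   SEM target site disrupts it without excising the drive)?
#' @param inducible_drive Homing requires the small molecule?
#' @param inducible_sem Excision requires the small molecule? Both flags
#'   `FALSE` yields an always-on construct (permitted; flagged in metadata).
#' @return A `design_spec` object.
#' @export
design_spec <- function(design_id, flavor = "SIMPLIFIED",
                        sem_resistance = FALSE, inducible_drive = FALSE,
                        inducible_sem = TRUE) {
  if (!is.character(design_id) || length(design_id) != 1L ||
      !design_id %in% SEM_DESIGNS) {
    stop("configuration error in `design_id`: got ", deparse(design_id),
         "; must be one of ", paste(SEM_DESIGNS, collapse = ", "),
         call. = FALSE)
  }
  if (!is.character(flavor) || length(flavor) != 1L ||
      !flavor %in% SEM_FLAVORS) {
    stop("configuration error in `flavor`: got ", deparse(flavor),
         "; must be one of ", paste(SEM_FLAVORS, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(is.logical(sem_resistance), length(sem_resistance) == 1L,
            is.logical(inducible_drive), length(inducible_drive) == 1L,
            is.logical(inducible_sem), length(inducible_sem) == 1L)
  structure(
    list(design_id = design_id, flavor = flavor,
         sem_resistance = sem_resistance,
         inducible_drive = inducible_drive, inducible_sem = inducible_sem,
         always_on = !inducible_drive && !inducible_sem),
    class = "design_spec")
}

#' Drive (homing) parameters
#'
#' @param p Probability that a wild-type allele opposite an active drive
#'   allele is cleaved during gametogenesis.
#' @param q Probability that a cleaved allele is repaired by homologous
#'   recombination, i.e. converted to a copy of the drive.
#' @param rho Fraction of NHEJ repairs that are in-frame (functional
#'   resistant allele `R` rather than broken `B`); used by the COMPLETE
#'   flavor only. Defaults to 1/3 (one reading frame in three restores
#'   function).
#' @return A `drive_params` object.
#' @export
drive_params <- function(p, q, rho = 1 / 3) {
  for (nm in c("p", "q", "rho")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("drive parameter `", nm, "` must be a single number in [0, 1]",
           call. = FALSE)
  }
  structure(list(p = p, q = q, rho = rho), class = "drive_params")
}

#' Self-elimination (SEM) parameters
#'
#' @param a Probability per gametogenesis that an SEM-capable drive allele is
#'   cut by the activated secondary endonuclease while the molecule is
#'   present.
#' @param b Probability a cut construct resolves by single-strand annealing
#'   (otherwise NHEJ).
#' @param c Probability SSA resolution yields the cut-resistant wild-type
#'   allele `V` (otherwise susceptible `W`).
#' @return A `sem_params` object.
#' @export
sem_params <- function(a, b, c) {
  for (nm in c("a", "b", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("SEM parameter `", nm, "` must be a single number in [0, 1]",
           call. = FALSE)
  }
  structure(list(a = a, b = b, c = c), class = "sem_params")
}

# drive-locus parental alphabet for a spec (sorted canonically)
drive_alphabet <- function(spec, offspring = FALSE) {
  al <- c("W", "G", "H", "V")
  if (spec$sem_resistance) al <- c(al, "S")
  if (spec$flavor %in% c("REDUCED", "COMPLETE")) al <- c(al, "R")
  if (spec$flavor == "COMPLETE") al <- c(al, "B")
  if (offspring && spec$flavor == "SIMPLIFIED") al <- c(al, "B0")
  al[order(.ALLELE_RANK[al])]
}

sem_alphabet <- function() c("E", "w")

has_sem_locus <- function(spec) startsWith(spec$design_id, "TRANS")

drive_chrom <- function(spec) {
  switch(spec$design_id,
         CIS_AUTO = "auto", CIS_X = "X", TRANS_AUTO_AUTO = "auto",
         TRANS_AUTO_X = "auto", TRANS_X_AUTO = "X")
}

sem_chrom <- function(spec) {
  switch(spec$design_id,
         TRANS_AUTO_AUTO = "auto", TRANS_AUTO_X = "X", TRANS_X_AUTO = "auto",
         NA_character_)
}
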