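# Ensemble analysis: genotype-resolved trajectories -> allele/genotype time
# series -> long-format summary tables (time, sex, feature, stat, value)
# ready for ggplot2.

#' Allele or genotype time series from a trajectory
#'
#' Counts adults only (aquatic stages excluded by default, matching what a
#' field survey of adults would see). Each living adult contributes its own
#' somatic genotype once; the mate genotypes stored in mated females are
#' excluded by default. Y placeholder tokens are never counted. Proportions
#' divide by the total number of counted alleles (over the full alphabet)
#' at that time for the selected sex set; genotype features are normalized
#' by the total number of counted adults.
#'
#' @param traj A `trajectory` from [simulate_spn()].
#' @param cube The `inheritance_cube` the model was built from (supplies
#'   the genotype-to-allele map).
#' @param features Character vector of allele symbols and/or genotype
#'   labels of interest.
#' @param sex `"both"`, `"female"`, or `"male"`.
#' @param proportions Return proportions instead of counts?
#' @param include_mates Also count the mate genotype stored in mated
#'   females?
#' @param include_aquatic Also count aquatic stages (eggs, larvae, pupae)?
#'   Aquatic individuals have no recorded sex and are only counted when
#'   `sex = "both"`.
#' @return A tibble with columns `time`, `sex`, `feature`, `value`.
#' @export
allele_series <- function(traj, cube, features, sex = c("both", "female",
                                                        "male"),
                          proportions = FALSE, include_mates = FALSE,
                          include_aquatic = FALSE) {
  sex <- match.arg(sex)
  stopifnot(inherits(traj, "trajectory"), inherits(cube, "inheritance_cube"))
  if (length(features) == 0L)
    stop("configuration error: `features` must be nonempty", call. = FALSE)
  valid <- c(cube$alphabet, cube$offspring)
  bad <- setdiff(features, valid)
  if (length(bad))
    stop("configuration error: unknown feature(s) ",
         paste(bad, collapse = ", "), "; valid labels are: ",
         paste(valid, collapse = ", "), call. = FALSE)

  info <- .place_info_from_traj(traj)
  keep_kind <- c("unmated_female", "male", "mated_female")
  if (include_aquatic && sex == "both")
    keep_kind <- c(keep_kind, "egg", "larva", "pupa")
  keep <- info$kind %in% keep_kind
  if (sex != "both") keep <- keep & !is.na(info$sex) & info$sex == sex

  genos <- cube$offspring
  G <- matrix(0, nrow(traj$counts), length(genos),
              dimnames = list(NULL, genos))
  for (j in which(keep)) {
    g <- info$genotype[j]
    G[, g] <- G[, g] + traj$counts[, j]
    if (include_mates && info$kind[j] == "mated_female" &&
        !is.na(info$mate[j]))
      G[, info$mate[j]] <- G[, info$mate[j]] + traj$counts[, j]
  }
  AC <- cube$allele_counts[genos, , drop = FALSE]
  allele_tot <- G %*% AC
  adult_tot <- rowSums(G)

  out <- lapply(features, function(f) {
    if (f %in% cube$alphabet) {
      v <- allele_tot[, f]
      if (proportions) {
        den <- rowSums(allele_tot)
        v <- ifelse(den > 0, v / den, 0)
      }
    } else {
      v <- G[, f]
      if (proportions) v <- ifelse(adult_tot > 0, v / adult_tot, 0)
    }
    tibble::tibble(time = traj$time, sex = sex, feature = f,
                   value = unname(v))
  })
  dplyr::bind_rows(out)
}

# reconstruct place metadata from trajectory place names
.place_info_from_traj <- function(traj) {
  pl <- traj$places
  kind <- rep(NA_character_, length(pl))
  geno <- rep(NA_character_, length(pl))
  mate <- rep(NA_character_, length(pl))
  sexv <- rep(NA_character_, length(pl))
  for (j in seq_along(pl)) {
    p <- pl[j]
    if (grepl("^E[0-9]+_", p)) {
      kind[j] <- "egg"; geno[j] <- sub("^E[0-9]+_", "", p)
    } else if (grepl("^L[0-9]+_", p)) {
      kind[j] <- "larva"; geno[j] <- sub("^L[0-9]+_", "", p)
    } else if (grepl("^P[0-9]+_", p)) {
      kind[j] <- "pupa"; geno[j] <- sub("^P[0-9]+_", "", p)
    } else if (startsWith(p, "U_")) {
      kind[j] <- "unmated_female"; geno[j] <- sub("^U_", "", p)
      sexv[j] <- "female"
    } else if (startsWith(p, "M_")) {
      kind[j] <- "male"; geno[j] <- sub("^M_", "", p)
      sexv[j] <- "male"
    } else if (startsWith(p, "F_")) {
      kind[j] <- "mated_female"
      parts <- strsplit(sub("^F_", "", p), "|", fixed = TRUE)[[1]]
      geno[j] <- parts[1]; mate[j] <- parts[2]
      sexv[j] <- "female"
    } else {
      kind[j] <- "generic"
    }
  }
  data.frame(place = pl, kind = kind, genotype = geno, mate = mate,
             sex = sexv, stringsAsFactors = FALSE)
}

.SUMMARY_STATS <- c("max", "min", "mean", "median", "q2.5", "q97.5")

#' Summarize an ensemble of feature series
#'
#' Per (time, sex, feature): max, min, and mean across repetitions, the
#' median, and the empirical 2.5% / 97.5% order-statistic quantiles (linear
#' interpolation), which together form the central 95% empirical band.
#'
#' @param series_list List of tibbles from [allele_series()], one per
#'   repetition, on identical time grids.
#' @param stats Subset of `c("max", "min", "mean", "median", "q2.5",
#'   "q97.5")`.
#' @return A long-format tibble `time`, `sex`, `feature`, `stat`, `value`,
#'   one row per combination.
#' @export
summarize_ensemble <- function(series_list, stats = .SUMMARY_STATS) {
  stopifnot(length(series_list) >= 1L)
  stats <- match.arg(stats, .SUMMARY_STATS, several.ok = TRUE)
  grid <- series_list[[1]]$time
  for (s in series_list) {
    if (!isTRUE(all.equal(s$time, grid)))
      stop("alignment error: repetitions have mismatched time grids",
           call. = FALSE)
  }
  all <- dplyr::bind_rows(series_list, .id = "rep")
  fns <- list(
    max = max, min = min, mean = mean, median = stats::median,
    q2.5 = function(v) unname(stats::quantile(v, 0.025, type = 7)),
    q97.5 = function(v) unname(stats::quantile(v, 0.975, type = 7)))
  out <- all |>
    dplyr::group_by(.data$time, .data$sex, .data$feature) |>
    dplyr::summarise(dplyr::across("value", fns[stats],
                                   .names = "{.fn}"),
                     .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(stats), names_to = "stat",
                        values_to = "value") |>
    dplyr::arrange(.data$time, .data$sex, .data$feature, .data$stat)
  out
}

#' Write a long-format summary table as CSV
#'
#' UTF-8, header `time,sex,feature,stat,value`, full precision; round-trips
#' losslessly through [read_long_table()].
#'
#' @param table Tibble from [summarize_ensemble()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(table, path) {
  stopifnot(all(c("time", "sex", "feature", "stat", "value") %in%
                  names(table)))
  readr::write_csv(table[, c("time", "sex", "feature", "stat", "value")],
                   path)
  invisible(path)
}

#' Read a long-format summary table written by [write_long_table()]
#'
#' @param path CSV path.
#' @return A tibble `time`, `sex`, `feature`, `stat`, `value`.
#' @export
read_long_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    time = readr::col_double(), sex = readr::col_character(),
    feature = readr::col_character(), stat = readr::col_character(),
    value = readr::col_double()))
}
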