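# Time-split detectors. The record series is split at a cutoff year (by
# default 1912, the last year of the first multi-annual systematic cruise
# era): "historical" records have year <= cutoff, "recent" ones
# year > cutoff. Two detectors work on this split: a first-record screen
# for potential neozoa, and a binomial lower-tail test for declining
# species against the collection-wide recent deposition rate. A gridded
# coverage check guards both against spatio-temporal sampling artefacts.

#' Per-species record counts around a time split
#'
#' @param records curated occurrence tibble; every record must have a year.
#' @param cutoff_year split year; a record collected in the cutoff year
#'   itself is historical ("after" means strictly later).
#' @return tibble with one row per species: `species, n_total, n_after,
#'   first_year, last_year, n_distinct_years, p_decline` (NA until
#'   [decline_test()] runs) and `label` (`"unclassified"`).
#' @export
split_counts <- function(records, cutoff_year = 1912) {
  if (any(is.na(records$year)))
    stop("split_counts requires all records to have a year (curate first)")
  sp <- factor(records$species, levels = sort(unique(records$species)))
  yrs <- split(records$year, sp)
  out <- tibble::tibble(
    species = names(yrs),
    n_total = unname(vapply(yrs, length, integer(1))),
    n_after = unname(vapply(yrs, function(y) sum(y > cutoff_year), integer(1))),
    first_year = unname(vapply(yrs, min, numeric(1))),
    last_year = unname(vapply(yrs, max, numeric(1))),
    n_distinct_years = unname(vapply(yrs, function(y) length(unique(y)),
                                     integer(1))),
    p_decline = NA_real_,
    label = "unclassified"
  )
  attr(out, "cutoff_year") <- cutoff_year
  out
}

#' Collection-wide proportion of records after the cutoff
#'
#' The null success probability of the decline test: the fraction of all
#' curated lots deposited after the cutoff year.
#'
#' @inheritParams split_counts
#' @return object of class `baseline`: list with `p0`, `n_records_total`,
#'   `n_after`, `cutoff_year`.
#' @export
baseline_proportion <- function(records, cutoff_year = 1912) {
  if (any(is.na(records$year)))
    stop("baseline_proportion requires all records to have a year")
  n <- nrow(records)
  k <- sum(records$year > cutoff_year)
  if (k == 0L || k == n)
    stop("all records fall on one side of the cutoff; ",
         "the decline test is undefined")
  structure(list(p0 = k / n, n_records_total = n, n_after = k,
                 cutoff_year = cutoff_year),
            class = "baseline")
}

#' @export
print.baseline <- function(x, ...) {
  cat(sprintf("Baseline: %d of %d lots after %d (p0 = %.4f)\n",
              x$n_after, x$n_records_total, x$cutoff_year, x$p0))
  invisible(x)
}

#' Binomial lower-tail test for declining species
#'
#' For each species, tests whether its proportion of records after the
#' cutoff is significantly below the collection-wide baseline: the
#' p-value is `P(X <= n_after)` for `X ~ Binomial(n_total, p0)`, i.e. the
#' exact lower-tail binomial probability ([stats::pbinom()]); no normal
#' approximation is involved.
#'
#' @param summaries tibble from [split_counts()].
#' @param baseline a [baseline_proportion()] object (or a plain number
#'   giving p0).
#' @param alpha significance level (default 0.05).
#' @param correction multiple-testing correction applied to the p-values
#'   before thresholding: `"none"` (default) or `"benjamini_hochberg"`.
#' @param min_records optional floor: species with fewer total records are
#'   not flagged (default 0 = no floor).
#' @return `summaries` with `p_decline` filled in and `label` set to
#'   `"declining_candidate"` where the (corrected) p-value is at or below
#'   `alpha`; other labels are left untouched.
#' @export
decline_test <- function(summaries, baseline, alpha = 0.05,
                         correction = c("none", "benjamini_hochberg"),
                         min_records = 0) {
  correction <- match.arg(correction)
  p0 <- if (inherits(baseline, "baseline")) baseline$p0 else as.numeric(baseline)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("baseline proportion must lie strictly between 0 and 1")
  p <- stats::pbinom(summaries$n_after, summaries$n_total, p0)
  summaries$p_decline <- p
  p_adj <- if (correction == "benjamini_hochberg") stats::p.adjust(p, "BH") else p
  flag <- p_adj <= alpha & summaries$n_total >= min_records
  summaries$label[flag] <- "declining_candidate"
  summaries
}

#' First-record screen for potential neozoa
#'
#' A species deposited only after the cutoff may be new to the region
#' (introduced or range-expanding). Overall-rare species whose presence
#' merely tracks effort are excluded first: species with fewer than
#' `min_records` lots, collected in a single calendar year only, or
#' collected only during the most intensive survey window.
#'
#' @inheritParams split_counts
#' @param min_records minimum lot count to escape the rarity exclusion
#'   (default 10).
#' @param intensive_window closed year interval `c(start, end)` of the
#'   most intensive collecting effort (default `c(1977, 1990)`).
#' @return tibble as from [split_counts()] with `label` set per species to
#'   `"rare_excluded"`, `"neozoa_candidate"` or `"unclassified"`.
#' @export
neozoa_screen <- function(records, cutoff_year = 1912, min_records = 10,
                          intensive_window = c(1977, 1990)) {
  out <- split_counts(records, cutoff_year)
  yrs <- split(records$year, factor(records$species, levels = out$species))
  all_in_window <- vapply(yrs, function(y)
    all(y >= intensive_window[1L] & y <= intensive_window[2L]), logical(1))
  rare <- out$n_total < min_records | out$n_distinct_years == 1L | all_in_window
  out$label[rare] <- "rare_excluded"
  cand <- !rare & out$first_year > cutoff_year
  out$label[cand] <- "neozoa_candidate"
  out
}

#' Spatio-temporal artefact check for one species
#'
#' A species may appear "new" simply because collectors moved into
#' previously unworked regions. The study area is gridded into
#' `cell_deg` x `cell_deg` lon/lat cells; coverage is the fraction of the
#' species' post-cutoff records that fall in cells holding at least one
#' pre-cutoff record of any species. Low coverage flags the species as a
#' possible spatio-temporal artefact. This quantifies what is otherwise a
#' visual map comparison; grid size and threshold are reported, never
#' silently applied.
#'
#' @inheritParams split_counts
#' @param species species name to check (must occur in `records`).
#' @param cell_deg grid resolution in degrees (default 0.5).
#' @param threshold coverage below which the species is flagged
#'   (default 0.5).
#' @return list with `species`, `coverage` (NA if the species has no
#'   georeferenced post-cutoff records), `flagged`, `n_after_geo`,
#'   `cell_deg`, `threshold`.
#' @export
artefact_coverage <- function(records, species, cutoff_year = 1912,
                              cell_deg = 0.5, threshold = 0.5) {
  if (!species %in% records$species)
    stop("species not present in records: ", species)
  geo <- !is.na(records$lat) & !is.na(records$lon) & !is.na(records$year)
  cell <- paste(floor(records$lon / cell_deg), floor(records$lat / cell_deg))
  pre_cells <- unique(cell[geo & records$year <= cutoff_year])
  sel <- geo & records$species == species & records$year > cutoff_year
  n_after <- sum(sel)
  if (n_after == 0L)
    return(list(species = species, coverage = NA_real_, flagged = FALSE,
                n_after_geo = 0L, cell_deg = cell_deg, threshold = threshold))
  cov <- mean(cell[sel] %in% pre_cells)
  list(species = species, coverage = cov, flagged = cov < threshold,
       n_after_geo = n_after, cell_deg = cell_deg, threshold = threshold)
}
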