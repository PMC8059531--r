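# Relative observation trends: the annual proportion of a species'
# records among all records of a higher taxonomic unit (its class or
# phylum), regressed on calendar year. Working with proportions rather
# than raw counts damps year-to-year swings in collecting effort. A call
# must survive two taxonomic ranks, a sign-concordance rule and an
# exclusion-region sensitivity re-run before it counts.

#' Annual record proportions of a species within a higher rank
#'
#' For each year, the proportion of the rank's records that belong to the
#' species. Years where the rank has fewer than `min_rank_records` records
#' are dropped (the proportion would be too noisy); qualifying years where
#' the species has no records contribute proportion 0 by default (the
#' species was observable at relative frequency zero). A species with
#' fewer than `min_species_records` records overall yields an empty
#' series, i.e. no fit.
#'
#' @param records curated occurrence tibble (years present).
#' @param species species name.
#' @param rank `"class"` or `"phylum"`.
#' @param min_rank_records minimum rank records for a year to qualify
#'   (default 5).
#' @param min_species_records minimum overall records for the species to
#'   be analysed at all (default 10).
#' @param zero_fill materialize qualifying years where the species is
#'   absent as proportion 0 (default `TRUE`); `FALSE` restricts the
#'   series to years with at least one species record, for comparison.
#' @return tibble with columns `year, n_species, n_rank, proportion`
#'   (possibly 0 rows), with attributes `species` and `rank`.
#' @export
annual_proportions <- function(records, species,
                               rank = c("class", "phylum"),
                               min_rank_records = 5,
                               min_species_records = 10,
                               zero_fill = TRUE) {
  rank <- match.arg(rank)
  sel <- records$species == species
  if (!any(sel)) stop("species not present in records: ", species)
  rank_value <- unique(records[[rank]][sel])
  rank_value <- rank_value[!is.na(rank_value)]
  if (length(rank_value) == 0L)
    stop("species has no known ", rank, " membership: ", species)
  rank_value <- rank_value[1L]
  empty <- tibble::tibble(year = integer(0), n_species = integer(0),
                          n_rank = integer(0), proportion = numeric(0))
  attr(empty, "species") <- species; attr(empty, "rank") <- rank
  if (sum(sel) < min_species_records) return(empty)
  in_rank <- !is.na(records[[rank]]) & records[[rank]] == rank_value
  rank_tab <- table(records$year[in_rank])
  years <- as.integer(names(rank_tab))
  n_rank <- as.integer(rank_tab)
  keep <- n_rank >= min_rank_records
  years <- years[keep]; n_rank <- n_rank[keep]
  sp_tab <- table(records$year[sel])
  n_species <- as.integer(sp_tab[as.character(years)])
  n_species[is.na(n_species)] <- 0L
  if (!zero_fill) {
    keep <- n_species > 0L
    years <- years[keep]; n_rank <- n_rank[keep]; n_species <- n_species[keep]
  }
  out <- tibble::tibble(year = years, n_species = n_species, n_rank = n_rank,
                        proportion = n_species / n_rank)
  attr(out, "species") <- species; attr(out, "rank") <- rank
  out
}

#' Ordinary least-squares trend of an annual proportion series
#'
#' Regresses proportion on calendar year with [stats::lm()] (year centred
#' for numerical stability; the slope is unchanged) and reports the
#' two-sided t-test on the slope with `n_years - 2` degrees of freedom.
#' Degenerate fits use fixed conventions: a perfectly linear series with a
#' non-zero slope has p = 0 (maximal evidence under this test, flagged as
#' degenerate); a constant series has slope 0 and p = 1.
#'
#' @param series tibble from [annual_proportions()].
#' @return `NULL` when fewer than 3 usable years exist; otherwise a
#'   one-row tibble `species, rank, slope, stderr, t_stat, p_value,
#'   n_years, degenerate`.
#' @export
ols_trend <- function(series) {
  if (is.null(series) || nrow(series) < 3L) return(NULL)
  if (length(unique(series$year)) < 2L)
    stop("zero variance in year: cannot fit a trend")
  yr <- series$year - mean(series$year)
  fit <- stats::lm(series$proportion ~ yr)
  # summary.lm warns on zero-residual fits; that case is handled by the
  # explicit degenerate convention below, so the warning is moot here.
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(co["yr", "Estimate"])
  se <- unname(co["yr", "Std. Error"])
  degenerate <- sum(stats::residuals(fit)^2) <= 1e-24 * max(1, sum(series$proportion^2))
  if (degenerate) {
    p <- if (abs(slope) <= 1e-15) 1 else 0
    tval <- if (abs(slope) <= 1e-15) 0 else Inf
    se <- 0
  } else {
    tval <- unname(co["yr", "t value"])
    p <- unname(co["yr", "Pr(>|t|)"])
  }
  tibble::tibble(species = attr(series, "species") %||% NA_character_,
                 rank = attr(series, "rank") %||% NA_character_,
                 slope = slope, stderr = se, t_stat = tval, p_value = p,
                 n_years = nrow(series), degenerate = degenerate)
}

#' Classify a species' trend from its four rank/variant fits
#'
#' Within each dataset variant, the provisional direction is the sign
#' shared by all significant fits (class and/or phylum); significant fits
#' of opposite sign exclude the species as discordant. The final call
#' requires the same provisional direction in both the full dataset and
#' the exclusion-region variant; otherwise the species is called `none`.
#'
#' @param fits tibble of [ols_trend()] rows for one species, with an
#'   added `variant` column (`"full"` / `"excl_region"`); missing fits
#'   are simply absent rows.
#' @param alpha significance level (default 0.05).
#' @return one-row tibble `species, direction, reason` where `direction`
#'   is one of `increasing, declining, none, discordant_excluded`.
#' @export
classify_trend <- function(fits, alpha = 0.05) {
  species <- if (nrow(fits) > 0L) fits$species[1L] else NA_character_
  dir_in_variant <- function(v) {
    f <- fits[fits$variant == v & !is.na(fits$p_value), , drop = FALSE]
    sig <- f[f$p_value <= alpha & f$slope != 0, , drop = FALSE]
    if (nrow(sig) == 0L) return("none")
    signs <- unique(sign(sig$slope))
    if (length(signs) > 1L) return("discordant")
    if (signs > 0) "increasing" else "declining"
  }
  d_full <- dir_in_variant("full")
  d_excl <- dir_in_variant("excl_region")
  if (d_full == "discordant" || d_excl == "discordant") {
    direction <- "discordant_excluded"; reason <- "opposite significant signs"
  } else if (d_full != "none" && d_full == d_excl) {
    direction <- d_full; reason <- "significant in both variants"
  } else if (d_full != "none" || d_excl != "none") {
    direction <- "none"; reason <- "not recovered in both variants"
  } else {
    direction <- "none"; reason <- "no significant fit"
  }
  tibble::tibble(species = species, direction = direction, reason = reason)
}

#' Relative-trend analysis over a curated dataset
#'
#' Runs [annual_proportions()] and [ols_trend()] for every species against
#' both its class and its phylum, on the full dataset and on a variant
#' with records inside an exclusion region removed (guarding against a
#' heavily resampled sub-region mimicking increases), then classifies each
#' species with [classify_trend()].
#'
#' @param records curated occurrence tibble.
#' @param exclusion_polygon [polygon_set()] of the region whose records
#'   are dropped in the sensitivity variant, or `NULL` (variants then
#'   coincide).
#' @param alpha significance level (default 0.05).
#' @inheritParams annual_proportions
#' @return list with `calls` (tibble: species, direction, reason) and
#'   `fits` (tibble of all per-rank, per-variant fits).
#' @export
run_trend_analysis <- function(records, exclusion_polygon = NULL,
                               alpha = 0.05, min_rank_records = 5,
                               min_species_records = 10, zero_fill = TRUE) {
  variants <- list(full = records)
  if (!is.null(exclusion_polygon) && length(exclusion_polygon) > 0L) {
    inside <- in_polygon_set(records$lon, records$lat, exclusion_polygon)
    excl <- records[!inside, , drop = FALSE]
    if (nrow(excl) == 0L)
      stop("exclusion polygon removes all records")
    variants$excl_region <- excl
  } else {
    variants$excl_region <- records
  }
  species <- sort(unique(records$species))
  all_fits <- list()
  for (v in names(variants)) {
    recs <- variants[[v]]
    for (rk in c("class", "phylum")) {
      for (sp in species) {
        if (!sp %in% recs$species) next
        ser <- annual_proportions(recs, sp, rank = rk,
                                  min_rank_records = min_rank_records,
                                  min_species_records = min_species_records,
                                  zero_fill = zero_fill)
        f <- ols_trend(ser)
        if (!is.null(f)) {
          f$variant <- v
          all_fits[[length(all_fits) + 1L]] <- f
        }
      }
    }
  }
  fits <- if (length(all_fits)) do.call(rbind, all_fits)
    else tibble::tibble(species = character(0), rank = character(0),
                        slope = numeric(0), stderr = numeric(0),
                        t_stat = numeric(0), p_value = numeric(0),
                        n_years = integer(0), degenerate = logical(0),
                        variant = character(0))
  calls <- do.call(rbind, lapply(species, function(sp) {
    f <- fits[fits$species == sp, , drop = FALSE]
    if (nrow(f) == 0L)
      return(tibble::tibble(species = sp, direction = "none",
                            reason = "no usable series"))
    classify_trend(f, alpha = alpha)
  }))
  list(calls = calls, fits = fits)
}
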