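# Lot-level occurrence records: ingestion, georeferencing against an
# in-dataset gazetteer, synonym resolution and the staged curation cascade.
#
# A record is one LOT: all specimens of one species from one sampling
# event, stored and catalogued together. Counting lots instead of
# individuals damps the bias from selective deposition of common species.

#' Default Darwin-Core-style column dialect
#'
#' Maps the roles the pipeline needs to the column names commonly used in
#' Darwin-Core-flavoured exports. Override individual entries to match a
#' particular export.
#'
#' @return named character vector: role -> column name.
#' @export
dwc_dialect <- function() {
  c(species     = "scientificName",
    genus       = "genus",
    class       = "class",
    phylum      = "phylum",
    year        = "year",
    eventDate   = "eventDate",
    lat         = "decimalLatitude",
    lon         = "decimalLongitude",
    locality    = "locality",
    institution = "institutionCode",
    catalogue   = "catalogNumber")
}

#' Extract a collection year from a date or year string
#'
#' Takes the first 4-digit substring in \[1750, 2100\]; a range such as
#' "1902-1912" therefore yields the first year. Anything else is `NA`.
#'
#' @param x character vector of dates, years or free-form ranges.
#' @return integer vector of years (NA where unparseable).
#' @export
extract_year <- function(x) {
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  m <- gregexpr("[0-9]{4}", x)
  for (i in seq_along(x)) {
    if (is.na(x[i])) next
    starts <- m[[i]]
    if (starts[1L] == -1L) next
    for (j in seq_along(starts)) {
      y <- as.integer(substr(x[i], starts[j], starts[j] + 3L))
      if (!is.na(y) && y >= 1750L && y <= 2100L) { out[i] <- y; break }
    }
  }
  out
}

.std_cols <- c("record_id", "species", "genus", "class", "phylum", "year",
               "lat", "lon", "locality", "institution", "catalogue_no")

#' Read lot-level occurrence records from delimited text
#'
#' Reads a CSV/TSV export with a header row and maps its columns onto the
#' standard record layout via a dialect (see [dwc_dialect()]). Years are
#' taken from the year column when present, otherwise extracted from the
#' event-date column. Unparseable coordinates or years become `NA`; a row
#' is never dropped at this stage. Row order is preserved.
#'
#' @param path path to a delimited text file (UTF-8). The separator is
#'   sniffed from the header line (tab if it contains tabs, else comma)
#'   unless `sep` is given.
#' @param dialect named character vector mapping roles to column names;
#'   entries absent from the file are filled with `NA`. The `species`
#'   role is mandatory.
#' @param sep optional field separator.
#' @return a tibble of occurrence records with columns
#'   `record_id, species, genus, class, phylum, year, lat, lon, locality,
#'   institution, catalogue_no`.
#' @export
read_occurrences <- function(path, dialect = dwc_dialect(), sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("empty occurrence file: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           encoding = "UTF-8")
  if (nrow(raw) == 0L) stop("occurrence file has a header but no rows: ", path)
  dialect <- c(dialect, dwc_dialect()[setdiff(names(dwc_dialect()), names(dialect))])
  col <- function(role) {
    nm <- dialect[[role]]
    if (!is.null(nm) && !is.na(nm) && nm %in% names(raw)) raw[[nm]]
    else rep(NA_character_, nrow(raw))
  }
  if (is.null(dialect[["species"]]) || !dialect[["species"]] %in% names(raw))
    stop("occurrence file lacks the species column '",
         dialect[["species"]] %||% "scientificName", "'")
  num <- function(x) suppressWarnings(as.numeric(x))
  year <- extract_year(col("year"))
  year[is.na(year)] <- extract_year(col("eventDate"))[is.na(year)]
  lat <- num(col("lat")); lon <- num(col("lon"))
  bad <- !is.na(lat) & !is.na(lon) &
    (abs(lat) > 90 | abs(lon) > 180)
  lat[bad] <- NA_real_; lon[bad] <- NA_real_
  # a lone coordinate is useless: treat the pair as missing
  half <- xor(is.na(lat), is.na(lon))
  lat[half] <- NA_real_; lon[half] <- NA_real_
  sp <- trimws(col("species"))
  sp[sp == ""] <- NA_character_
  tibble::tibble(
    record_id    = sprintf("rec%06d", seq_len(nrow(raw))),
    species      = sp,
    genus        = trimws(col("genus")),
    class        = trimws(col("class")),
    phylum       = trimws(col("phylum")),
    year         = year,
    lat          = lat,
    lon          = lon,
    locality     = col("locality"),
    institution  = col("institution"),
    catalogue_no = col("catalogue")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a locality string
#'
#' Case-folds, trims and collapses internal whitespace. Idempotent.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_locality <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Build a gazetteer from locality/coordinate pairs
#'
#' A gazetteer maps normalized locality strings to coordinates. It is
#' typically derived from the georeferenced records of the same dataset
#' (`gazetteer_from_records()`), mirroring within-dataset locality
#' matching; a user-supplied coordinates file can extend it.
#'
#' @param locality character vector of locality descriptions.
#' @param lat,lon numeric coordinate vectors.
#' @return named list of `c(lat, lon)` pairs keyed by normalized locality,
#'   class `gazetteer`. Duplicate keys keep the first entry.
#' @export
make_gazetteer <- function(locality, lat, lon) {
  stopifnot(length(locality) == length(lat), length(lat) == length(lon))
  key <- normalize_locality(locality)
  ok <- !is.na(key) & key != "" & !is.na(lat) & !is.na(lon) &
    abs(lat) <= 90 & abs(lon) <= 180
  key <- key[ok]; lat <- lat[ok]; lon <- lon[ok]
  keep <- !duplicated(key)
  gaz <- Map(function(a, b) c(lat = a, lon = b), lat[keep], lon[keep])
  names(gaz) <- key[keep]
  structure(gaz, class = "gazetteer")
}

#' @rdname make_gazetteer
#' @param records an occurrence tibble.
#' @export
gazetteer_from_records <- function(records) {
  make_gazetteer(records$locality, records$lat, records$lon)
}

#' Resolve missing coordinates against a gazetteer
#'
#' Records lacking coordinates whose normalized locality matches a
#' gazetteer key receive that key's coordinates. Records that already have
#' coordinates are never overwritten. The number of records is unchanged.
#'
#' @param records occurrence tibble.
#' @param gazetteer a [make_gazetteer()] object (or empty list).
#' @return list with elements `records` (same row count, coordinates
#'   filled where matched), `n_resolved`, `n_unresolved` (coordinate-less
#'   records with a locality that did not match).
#' @export
resolve_georeferences <- function(records, gazetteer) {
  needs <- is.na(records$lat) & !is.na(records$locality) &
    normalize_locality(records$locality) != ""
  key <- normalize_locality(records$locality)
  hit <- needs & key %in% names(gazetteer)
  if (any(hit)) {
    coords <- do.call(rbind, gazetteer[key[hit]])
    records$lat[hit] <- coords[, "lat"]
    records$lon[hit] <- coords[, "lon"]
  }
  list(records = records,
       n_resolved = sum(hit),
       n_unresolved = sum(needs) - sum(hit))
}

#' Replace outdated species names by their accepted names
#'
#' Applies a synonym table (old name -> accepted name), following chains
#' (a -> b, b -> c resolves a to c) to their terminal name. Idempotent.
#' An offline table plays the role of a live taxonomic-authority lookup.
#'
#' @param records occurrence tibble.
#' @param synonyms named character vector: `names()` are outdated names,
#'   values the accepted replacement.
#' @return records with `species` rewritten.
#' @export
apply_synonyms <- function(records, synonyms) {
  if (length(synonyms) == 0L) return(records)
  resolved <- resolve_synonym_table(synonyms)
  idx <- match(records$species, names(resolved))
  repl <- !is.na(idx)
  records$species[repl] <- unname(resolved[idx[repl]])
  records
}

# Collapse a synonym table to terminal accepted names; error on cycles.
resolve_synonym_table <- function(synonyms) {
  out <- synonyms
  for (i in seq_along(out)) {
    seen <- names(out)[i]
    cur <- out[[i]]
    while (cur %in% names(synonyms)) {
      if (cur %in% seen)
        stop("synonym cycle: ", paste(c(seen, cur), collapse = " -> "))
      seen <- c(seen, cur)
      cur <- synonyms[[cur]]
    }
    out[[i]] <- cur
  }
  out
}

#' Is a name identified to species level?
#'
#' A name counts as species-level when it has at least two
#' whitespace-separated tokens and the second token is not a placeholder
#' ("sp.", "spec.", "indet.").
#'
#' @param x character vector of taxon names.
#' @return logical vector.
#' @export
is_species_level <- function(x) {
  toks <- strsplit(trimws(as.character(x)), "[[:space:]]+")
  vapply(toks, function(t) {
    length(t) >= 2L && !(tolower(t[2L]) %in% c("sp.", "spec.", "indet."))
  }, logical(1))
}

#' Curate occurrence records
#'
#' Applies the staged curation cascade and records each stage in a
#' curation report. Stages, in order:
#' 1. drop records without resolvable coordinates;
#' 2. drop records outside the study region;
#' 3. drop records without a collection year;
#' 4. drop records whose higher taxon (class) is not whitelisted;
#' 5. drop records not identified to species level;
#' 6. drop infaunal species and species at or below the size floor;
#' 7. drop records inside excluded (undersampled border) regions.
#'
#' Containment is boundary-inclusive: a record exactly on the study-region
#' boundary is kept at stage 2 (and, symmetrically, one on an excluded
#' region's boundary is dropped at stage 7).
#'
#' @param records occurrence tibble (after georeference resolution and
#'   synonym application).
#' @param study_polygon [polygon_set()] delimiting the study region.
#' @param excluded_polygons [polygon_set()] of regions to drop, or `NULL`.
#' @param taxon_whitelist character vector of admitted higher-taxon
#'   (class) names; `NULL` skips stage 4.
#' @param trait_table data frame with columns `species`, `is_infauna`
#'   (logical) and `mean_size_cm` (numeric, NA allowed); `NULL` skips
#'   stage 6. Species absent from the table are kept.
#' @param min_size_cm size floor in centimetres; species with mean size at
#'   or below it are dropped (default 1).
#' @return list with `records` (curated tibble, original row order, plus a
#'   `curation_pass` column set to `TRUE`) and `report` (a
#'   `curation_report` data frame of `stage`, `n_removed`, `n_remaining`).
#' @export
curate_records <- function(records, study_polygon,
                           excluded_polygons = NULL,
                           taxon_whitelist = NULL,
                           trait_table = NULL,
                           min_size_cm = 1) {
  n_in <- nrow(records)
  stages <- character(0); removed <- integer(0); remaining <- integer(0)
  drop_stage <- function(df, stage, drop) {
    drop[is.na(drop)] <- FALSE
    stages <<- c(stages, stage)
    removed <<- c(removed, sum(drop))
    df <- df[!drop, , drop = FALSE]
    remaining <<- c(remaining, nrow(df))
    df
  }
  records <- drop_stage(records, "missing_coordinates",
                        is.na(records$lat) | is.na(records$lon))
  records <- drop_stage(records, "outside_study_region",
                        !in_polygon_set(records$lon, records$lat, study_polygon))
  records <- drop_stage(records, "missing_year", is.na(records$year))
  records <- drop_stage(records, "taxon_not_whitelisted",
                        if (is.null(taxon_whitelist)) rep(FALSE, nrow(records))
                        else !(records$class %in% taxon_whitelist))
  records <- drop_stage(records, "not_species_level",
                        is.na(records$species) | !is_species_level(records$species))
  if (!is.null(trait_table)) {
    idx <- match(records$species, trait_table$species)
    infauna <- !is.na(idx) & isTRUE_vec(trait_table$is_infauna[idx])
    small <- !is.na(idx) & !is.na(trait_table$mean_size_cm[idx]) &
      trait_table$mean_size_cm[idx] <= min_size_cm
    records <- drop_stage(records, "infauna_or_small", infauna | small)
  } else {
    records <- drop_stage(records, "infauna_or_small", rep(FALSE, nrow(records)))
  }
  records <- drop_stage(records, "excluded_region",
                        if (is.null(excluded_polygons) || length(excluded_polygons) == 0L)
                          rep(FALSE, nrow(records))
                        else in_polygon_set(records$lon, records$lat, excluded_polygons))
  if (nrow(records) == 0L) stop("no records survive curation")
  records$curation_pass <- TRUE
  report <- structure(
    data.frame(stage = stages, n_removed = removed, n_remaining = remaining,
               stringsAsFactors = FALSE),
    class = c("curation_report", "data.frame"), n_input = n_in)
  list(records = records, report = report)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation cascade:", attr(x, "n_input"), "records in\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-25s -%6d  => %6d remaining\n",
                x$stage[i], x$n_removed[i], x$n_remaining[i]))
  invisible(x)
}

#' Write curated records and their curation report
#'
#' @param curated the list returned by [curate_records()].
#' @param records_path,report_path output CSV paths.
#' @return `records_path`, invisibly.
#' @export
write_curated <- function(curated, records_path, report_path) {
  utils::write.csv(curated$records, records_path, row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(curated$report), report_path, row.names = FALSE)
  invisible(records_path)
}
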