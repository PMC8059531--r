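# End-to-end orchestration: configuration, the curation -> validation ->
# detectors -> trends -> cross-validation chain, bookkeeping outputs and
# the cross-validation set arithmetic.

#' Read a trait table (infauna flag, mean size)
#'
#' @param path CSV with columns `species, is_infauna, mean_size_cm`.
#' @return data frame; `is_infauna` coerced to logical, sizes numeric.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "is_infauna", "mean_size_cm")
  if (!all(need %in% names(df)))
    stop("trait table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$species))
    stop("duplicate species in trait table")
  df$is_infauna <- as.logical(df$is_infauna)
  df$mean_size_cm <- suppressWarnings(as.numeric(df$mean_size_cm))
  df
}

#' Read a synonym table
#'
#' @param path CSV with columns `old_name, accepted_name`.
#' @return named character vector usable with [apply_synonyms()].
#' @export
read_synonym_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("old_name", "accepted_name") %in% names(df)))
    stop("synonym table needs columns old_name, accepted_name")
  stats::setNames(df$accepted_name, df$old_name)
}

#' Read an abundance-category table
#'
#' @param path CSV with columns `species, category`.
#' @return data frame with those columns.
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "category") %in% names(df)))
    stop("abundance table needs columns species, category")
  df
}

#' Read reference species lists for cross-validation
#'
#' @param endangered_path,neozoa_path optional one-column CSVs
#'   (`species`) listing externally assessed endangered species and known
#'   neozoa.
#' @param trends_path optional CSV `species, direction` with external
#'   trend directions (`increasing` / `declining`).
#' @param synonyms optional synonym table applied to all names so they
#'   match the curated records.
#' @return list of class `reference_lists` with `endangered`,
#'   `known_neozoa` (character vectors) and `external_trends` (named
#'   character vector, possibly empty).
#' @export
read_reference_lists <- function(endangered_path = NULL, neozoa_path = NULL,
                                 trends_path = NULL, synonyms = NULL) {
  norm <- function(x) {
    x <- trimws(x)
    if (!is.null(synonyms) && length(synonyms)) {
      res <- resolve_synonym_table(synonyms)
      idx <- match(x, names(res))
      x[!is.na(idx)] <- unname(res[idx[!is.na(idx)]])
    }
    unique(x[x != ""])
  }
  one_col <- function(p) {
    if (is.null(p)) return(character(0))
    norm(utils::read.csv(p, stringsAsFactors = FALSE)$species)
  }
  tr <- stats::setNames(character(0), character(0))
  if (!is.null(trends_path)) {
    df <- utils::read.csv(trends_path, stringsAsFactors = FALSE)
    tr <- stats::setNames(df$direction, norm(df$species)[seq_len(nrow(df))])
    tr <- tr[names(tr) != ""]
  }
  structure(list(endangered = one_col(endangered_path),
                 known_neozoa = one_col(neozoa_path),
                 external_trends = tr),
            class = "reference_lists")
}

#' Cross-validate detected species against reference lists
#'
#' Exact set arithmetic on the detected species: a detected declining
#' species on the endangered list is corroborated, a detected neozoon on
#' the known-neozoa list is corroborated, and an external trend direction
#' opposite to the detected direction contradicts it. The three
#' percentages (corroborated, contradicted, no independent evidence) are
#' computed on the detected set and sum to 100 up to rounding;
#' corroboration wins when both apply.
#'
#' @param detections named list of character vectors of detected species,
#'   with any of the names `declining`, `neozoa`, `trend_increasing`,
#'   `trend_declining`.
#' @param refs a [read_reference_lists()] object.
#' @return object of class `venn_summary`: tibble with one row per
#'   detector (`detector, n_detected, pct_corroborated,
#'   pct_contradicted, pct_no_evidence`) plus a `species` attribute
#'   holding the underlying lists.
#' @export
crossvalidate <- function(detections, refs) {
  corroborators <- list(declining = refs$endangered,
                        trend_declining = refs$endangered,
                        neozoa = refs$known_neozoa,
                        trend_increasing = refs$known_neozoa)
  contra_dir <- c(declining = "increasing", trend_declining = "increasing",
                  neozoa = "declining", trend_increasing = "declining")
  rows <- list(); lists <- list()
  for (det in names(detections)) {
    sp <- unique(detections[[det]])
    if (length(sp) == 0L) {
      warning("empty detected set for ", det)
      rows[[det]] <- tibble::tibble(detector = det, n_detected = 0L,
                                    pct_corroborated = NA_real_,
                                    pct_contradicted = NA_real_,
                                    pct_no_evidence = NA_real_)
      next
    }
    corr <- sp %in% (corroborators[[det]] %||% character(0))
    ext <- refs$external_trends[sp]
    contra <- !is.na(ext) & ext == contra_dir[[det]] & !corr
    rows[[det]] <- tibble::tibble(
      detector = det, n_detected = length(sp),
      pct_corroborated = 100 * mean(corr),
      pct_contradicted = 100 * mean(contra),
      pct_no_evidence = 100 * mean(!corr & !contra))
    lists[[det]] <- list(corroborated = sp[corr], contradicted = sp[contra],
                         no_evidence = sp[!corr & !contra])
  }
  out <- do.call(rbind, rows)
  attr(out, "species") <- lists
  class(out) <- c("venn_summary", class(out))
  out
}

#' Default pipeline configuration
#'
#' All thresholds default to the package's standard constants: cutoff
#' year 1912, minimum 10 records per species, minimum 5 rank records per
#' qualifying year, intensive survey window 1977-1990, alpha 0.05.
#'
#' @param ... overrides of the defaults (same names as the returned
#'   list).
#' @return named list.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    cutoff_year = 1912,
    alpha = 0.05,
    min_records = 10,
    min_rank_records = 5,
    min_species_records = 10,
    intensive_window = c(1977, 1990),
    correction = "none",
    min_size_cm = 1,
    cell_deg = 0.5,
    artefact_threshold = 0.5,
    zero_fill = TRUE,
    taxon_whitelist = NULL,
    category_order = NULL,
    input = list(),       # records, gazetteer, synonyms, traits, redlist,
                          # endangered, known_neozoa, external_trends
    polygons = list(),    # study, excluded, exclusion_region (paths)
    synthetic = NULL,     # list(seed = ..., <scenario_config overrides>)
    output_dir = NULL
  )
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [default_pipeline_config()].
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  do.call(default_pipeline_config, yaml::read_yaml(path))
}

#' Run the full faunal-change pipeline
#'
#' Executes, in order: input loading (or simulation), synonym
#' application, gazetteer georeference resolution, the curation cascade,
#' the abundance-concordance validation (when an abundance table is
#' given), the time-split detectors (baseline, binomial decline test,
#' neozoa screen, artefact coverage for neozoa candidates), the
#' relative-trend analysis and the cross-validation bookkeeping. A module
#' failure aborts with the stage name. When `config$output_dir` is set,
#' all tables, a run log and a JSON report are written there.
#'
#' @param config a configuration list ([default_pipeline_config()]), or a
#'   path to a YAML file.
#' @return list of class `report_bundle` with elements `records`
#'   (curated), `curation_report`, `validation`, `baseline`, `summaries`
#'   (per-species window summaries with decline/neozoa labels and
#'   artefact coverage), `trends`, `crossvalidation`, `intersection`
#'   (one row per curated species with the labels of all three
#'   detectors) and `truth` (synthetic runs only).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  note("lotshift pipeline, package version %s",
       as.character(utils::packageVersion("lotshift")))
  truth <- NULL

  ## -- inputs ---------------------------------------------------------
  if (!is.null(config$synthetic)) {
    records <- stage("simulate", {
      sc_args <- config$synthetic
      sc <- do.call(scenario_config, sc_args)
      sim <- simulate_collections(sc)
      truth <- sim$truth
      note("simulated %d records for %d species (seed %d)",
           nrow(sim$records), nrow(sim$truth), sc$seed)
      if (is.null(config$polygons$study))
        config$polygons$study <- scenario_polygon(sc, "study")
      if (is.null(config$polygons$exclusion_region))
        config$polygons$exclusion_region <- scenario_polygon(sc, "focus")
      sim$records
    })
  } else {
    records <- stage("read", {
      if (is.null(config$input$records)) stop("no input records configured")
      read_occurrences(config$input$records)
    })
    note("read %d records from %s", nrow(records), config$input$records)
  }
  load_poly <- function(p) {
    if (is.null(p)) NULL
    else if (inherits(p, "polygon_set")) p
    else read_polygons_geojson(p)
  }
  study_poly <- stage("polygons", {
    p <- load_poly(config$polygons$study)
    if (is.null(p)) stop("a study polygon is required")
    p
  })
  excluded_poly <- stage("polygons", load_poly(config$polygons$excluded))
  exclusion_region <- stage("polygons", load_poly(config$polygons$exclusion_region))

  ## -- curation -------------------------------------------------------
  synonyms <- if (!is.null(config$input$synonyms))
    stage("synonyms", read_synonym_table(config$input$synonyms)) else NULL
  if (!is.null(synonyms)) {
    records <- stage("synonyms", apply_synonyms(records, synonyms))
    note("applied %d synonym mappings", length(synonyms))
  }
  gaz <- stage("georeference", {
    g <- gazetteer_from_records(records)
    if (!is.null(config$input$gazetteer)) {
      extra <- utils::read.csv(config$input$gazetteer, stringsAsFactors = FALSE)
      g2 <- make_gazetteer(extra$locality, extra$lat, extra$lon)
      g <- structure(c(g, g2[setdiff(names(g2), names(g))]),
                     class = "gazetteer")
    }
    g
  })
  res <- stage("georeference", resolve_georeferences(records, gaz))
  records <- res$records
  note("georeferencing: %d resolved, %d unresolved", res$n_resolved,
       res$n_unresolved)
  traits <- if (!is.null(config$input$traits))
    stage("traits", read_trait_table(config$input$traits)) else NULL
  cur <- stage("curate", curate_records(
    records, study_poly, excluded_polygons = excluded_poly,
    taxon_whitelist = config$taxon_whitelist, trait_table = traits,
    min_size_cm = config$min_size_cm))
  records <- cur$records
  for (i in seq_len(nrow(cur$report)))
    note("curation %-25s removed %6d remaining %6d",
         cur$report$stage[i], cur$report$n_removed[i],
         cur$report$n_remaining[i])

  ## -- validation -----------------------------------------------------
  validation <- NULL
  if (!is.null(config$input$redlist)) {
    validation <- stage("validate", {
      ab <- read_abundance_table(config$input$redlist)
      counts <- table(records$species)
      abundance_concordance(stats::setNames(as.numeric(counts), names(counts)),
                            ab, category_order = config$category_order)
    })
    note("abundance concordance: %d shared species, LRT p = %.3g",
         validation$n_species_shared, validation$fit$p_value)
  }

  ## -- window detectors -----------------------------------------------
  baseline <- stage("baseline", baseline_proportion(records, config$cutoff_year))
  note("baseline p0 = %.4f (%d of %d lots after %d)", baseline$p0,
       baseline$n_after, baseline$n_records_total, config$cutoff_year)
  summaries <- stage("neozoa", neozoa_screen(
    records, cutoff_year = config$cutoff_year,
    min_records = config$min_records,
    intensive_window = config$intensive_window))
  summaries <- stage("decline", decline_test(
    summaries, baseline, alpha = config$alpha,
    correction = config$correction))
  cand <- summaries$species[summaries$label == "neozoa_candidate"]
  summaries$coverage <- NA_real_
  summaries$artefact_flagged <- FALSE
  for (sp in cand) {
    ac <- stage("artefact", artefact_coverage(
      records, sp, cutoff_year = config$cutoff_year,
      cell_deg = config$cell_deg, threshold = config$artefact_threshold))
    i <- summaries$species == sp
    summaries$coverage[i] <- ac$coverage
    summaries$artefact_flagged[i] <- ac$flagged
  }
  note("detectors: %d declining candidates, %d neozoa candidates (%d artefact-flagged)",
       sum(summaries$label == "declining_candidate"),
       sum(summaries$label == "neozoa_candidate"),
       sum(summaries$artefact_flagged))

  ## -- relative trends ------------------------------------------------
  trends <- stage("trends", run_trend_analysis(
    records, exclusion_polygon = exclusion_region, alpha = config$alpha,
    min_rank_records = config$min_rank_records,
    min_species_records = config$min_species_records,
    zero_fill = config$zero_fill))
  note("trends: %d increasing, %d declining, %d discordant",
       sum(trends$calls$direction == "increasing"),
       sum(trends$calls$direction == "declining"),
       sum(trends$calls$direction == "discordant_excluded"))

  ## -- intersection table ---------------------------------------------
  intersection <- tibble::tibble(
    species = summaries$species,
    window_label = summaries$label,
    artefact_flagged = summaries$artefact_flagged,
    p_decline = summaries$p_decline,
    trend_direction = trends$calls$direction[
      match(summaries$species, trends$calls$species)]
  )
  intersection$trend_direction[is.na(intersection$trend_direction)] <- "none"

  ## -- cross-validation -----------------------------------------------
  crossval <- NULL
  refs <- NULL
  if (!is.null(config$input$endangered) || !is.null(config$input$known_neozoa) ||
      !is.null(config$input$external_trends)) {
    refs <- stage("crossvalidate", read_reference_lists(
      config$input$endangered, config$input$known_neozoa,
      config$input$external_trends, synonyms = synonyms))
  }
  if (!is.null(refs)) {
    crossval <- stage("crossvalidate", crossvalidate(list(
      declining = summaries$species[summaries$label == "declining_candidate"],
      neozoa = summaries$species[summaries$label == "neozoa_candidate"],
      trend_increasing = trends$calls$species[trends$calls$direction == "increasing"],
      trend_declining = trends$calls$species[trends$calls$direction == "declining"]
    ), refs))
  }

  bundle <- structure(list(
    records = records, curation_report = cur$report,
    validation = validation, baseline = baseline, summaries = summaries,
    trends = trends, crossvalidation = crossval,
    intersection = intersection, truth = truth, log = log_lines,
    config = config
  ), class = "report_bundle")
  if (!is.null(config$output_dir)) write_report_bundle(bundle, config$output_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat(" ", nrow(x$records), "curated records,",
      nrow(x$summaries), "species\n")
  cat(sprintf("  baseline p0 = %.4f\n", x$baseline$p0))
  cat("  declining candidates:",
      sum(x$summaries$label == "declining_candidate"), "\n")
  cat("  neozoa candidates:",
      sum(x$summaries$label == "neozoa_candidate"), "\n")
  cat("  trend calls:",
      sum(x$trends$calls$direction %in% c("increasing", "declining")), "\n")
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Writes curated records, the curation report, per-species summaries,
#' trend fits and calls, the intersection table, the cross-validation
#' summary, a JSON report of headline numbers and the run log.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(as.data.frame(df), file.path(dir, name),
                     row.names = FALSE, na = "")
  wcsv(bundle$records, "curated_records.csv")
  wcsv(bundle$curation_report, "curation_report.csv")
  wcsv(bundle$summaries, "species_summaries.csv")
  wcsv(bundle$trends$fits, "trend_fits.csv")
  wcsv(bundle$trends$calls, "trend_calls.csv")
  wcsv(bundle$intersection, "intersection.csv")
  if (!is.null(bundle$crossvalidation))
    wcsv(bundle$crossvalidation, "crossvalidation.csv")
  if (!is.null(bundle$truth)) wcsv(bundle$truth, "truth.csv")
  report <- list(
    n_records = nrow(bundle$records),
    n_species = nrow(bundle$summaries),
    baseline_p0 = bundle$baseline$p0,
    n_declining = sum(bundle$summaries$label == "declining_candidate"),
    n_neozoa = sum(bundle$summaries$label == "neozoa_candidate"),
    n_trend_increasing = sum(bundle$trends$calls$direction == "increasing"),
    n_trend_declining = sum(bundle$trends$calls$direction == "declining")
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
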