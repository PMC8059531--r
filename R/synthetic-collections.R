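# Generative model of the museum collecting and deposition process.
# Collecting effort is pulsed in time (expedition eras) and uneven in
# space (a late focus region), and each deposited lot is one record of
# one species from one sampling event. Species carry planted dynamics
# (stable, declining, introduced, increasing) recorded in a truth table,
# so every detector can be scored against known answers.

#' Scenario configuration for the collection-process simulator
#'
#' The default configuration is the package's benchmark collection: 240
#' species in three phyla (two classes each) observed 1830-2015 on a
#' 6 x 6 one-degree grid, with effort pulses emulating the historical
#' collecting eras of a North-Sea-style collection — early systematic
#' cruises (1868-1888, x2), an intense multi-annual survey era
#' (1902-1912, x5), a late intensive cruise program (1977-1990, x30) and
#' a post-1991 era with moderately elevated effort everywhere (x4),
#' concentrated on a small heavily resampled bank (a further x10 on six
#' central cells). With these pulses roughly 83% of all expected lots
#' fall after 1912, matching the strong recency skew typical of
#' digitized collections. 15 species are planted as declining, 10 as
#' introduced and 10 as increasing.
#'
#' @param seed integer random seed (mandatory; the simulation is fully
#'   reproducible from it).
#' @param n_stable,n_declining,n_introduced,n_increasing species counts
#'   per planted scenario.
#' @param years inclusive year range of the simulated collection.
#' @param grid list with `nx, ny, lon0, lat0, cell_deg` defining the
#'   spatial grid.
#' @param baseline_effort expected lots per year summed over the whole
#'   grid, per unit encounter rate, outside all pulses.
#' @param pulses list of effort pulses, each `list(start, end,
#'   multiplier, cells)` with `cells = NULL` meaning the whole grid;
#'   multipliers of overlapping pulses multiply.
#' @param focus_cells integer cell indices of the late focus region
#'   (used by the default post-1991 pulse and reported so analyses can
#'   exclude the region).
#' @param stable_q,declining_q,introduced_q,increasing_q length-2 ranges
#'   of per-species encounter rates (expected lots per unit effort;
#'   abundance times detectability). For increasing species the range is
#'   the rate reached in the final year.
#' @param decline_years,decline_rate year range of decline onsets and
#'   range of annual geometric survival after onset.
#' @param arrival_years year range of introduction arrivals.
#' @param introduction_halfyears years after arrival at which the
#'   logistic establishment curve reaches half its asymptote.
#' @param growth_rate range of annual geometric growth for increasing
#'   species.
#' @param war_loss `NULL` (default) or `list(interval = c(start, end),
#'   fraction = f)`: during the interval, each already-deposited lot
#'   (collection year at or before the interval end) is destroyed with
#'   probability `f`, emulating catastrophic collection losses.
#' @param species_table optional explicit species table overriding the
#'   random draws (columns `species, genus, class, phylum, scenario, q,
#'   change_year, rate, arrival_year`); used for hand-built fixtures.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(seed,
                            n_stable = 205, n_declining = 15,
                            n_introduced = 10, n_increasing = 10,
                            years = c(1830, 2015),
                            grid = list(nx = 6, ny = 6, lon0 = 2,
                                        lat0 = 53, cell_deg = 1),
                            baseline_effort = 1,
                            pulses = NULL,
                            focus_cells = NULL,
                            stable_q = c(0.06, 0.18),
                            declining_q = c(0.15, 0.25),
                            introduced_q = c(0.2, 0.35),
                            increasing_q = c(0.15, 0.3),
                            decline_years = c(1913, 1945),
                            decline_rate = c(0.90, 0.97),
                            arrival_years = c(1920, 1985),
                            introduction_halfyears = 8,
                            growth_rate = c(1.012, 1.018),
                            war_loss = NULL,
                            species_table = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  ncell <- grid$nx * grid$ny
  if (is.null(focus_cells)) {
    # central block of the grid (the heavily resampled bank)
    ix <- rep(seq_len(grid$nx), times = grid$ny)
    iy <- rep(seq_len(grid$ny), each = grid$nx)
    focus_cells <- which(ix %in% c(3, 4) & iy %in% c(3, 4, 5))
    if (length(focus_cells) == 0L) focus_cells <- 1L
  }
  if (is.null(pulses)) {
    pulses <- list(
      list(start = 1868, end = 1888, multiplier = 2,  cells = NULL),
      list(start = 1902, end = 1912, multiplier = 5,  cells = NULL),
      list(start = 1977, end = 1990, multiplier = 30, cells = NULL),
      list(start = 1991, end = 2015, multiplier = 4,  cells = NULL),
      list(start = 1991, end = 2015, multiplier = 10, cells = focus_cells)
    )
  }
  for (p in pulses) {
    if (p$start > p$end || p$start < years[1] || p$end > years[2])
      stop("pulse window outside the simulated year range")
    if (!is.null(p$cells) && (any(p$cells < 1) || any(p$cells > ncell)))
      stop("pulse focus cells outside the grid")
  }
  chk <- function(r, lo, hi, what) {
    if (any(r < lo) || any(r > hi) || r[1] > r[2])
      stop("invalid range for ", what)
  }
  if (n_declining > 0) {
    chk(decline_rate, 0, 1, "decline_rate")
    chk(decline_years, years[1], years[2], "decline_years")
  }
  if (n_increasing > 0) chk(growth_rate, 1, 1.2, "growth_rate")
  if (n_introduced > 0) chk(arrival_years, years[1], years[2], "arrival_years")
  structure(list(
    seed = as.integer(seed),
    n_stable = n_stable, n_declining = n_declining,
    n_introduced = n_introduced, n_increasing = n_increasing,
    years = years, grid = grid, baseline_effort = baseline_effort,
    pulses = pulses, focus_cells = focus_cells,
    stable_q = stable_q, declining_q = declining_q,
    introduced_q = introduced_q, increasing_q = increasing_q,
    decline_years = decline_years, decline_rate = decline_rate,
    arrival_years = arrival_years,
    introduction_halfyears = introduction_halfyears,
    growth_rate = growth_rate, war_loss = war_loss,
    species_table = species_table
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  %d species (%d stable, %d declining, %d introduced, %d increasing)\n",
              x$n_stable + x$n_declining + x$n_introduced + x$n_increasing,
              x$n_stable, x$n_declining, x$n_introduced, x$n_increasing))
  cat(sprintf("  years %d-%d, grid %dx%d @ %g deg, seed %d\n",
              x$years[1], x$years[2], x$grid$nx, x$grid$ny,
              x$grid$cell_deg, x$seed))
  for (p in x$pulses)
    cat(sprintf("  pulse %d-%d x%g%s\n", p$start, p$end, p$multiplier,
                if (is.null(p$cells)) "" else
                  sprintf(" (%d focus cells)", length(p$cells))))
  invisible(x)
}

#' Grid cell table of a scenario
#'
#' @param config a [scenario_config()].
#' @return tibble with `cell, ix, iy, lon_min, lat_min, lon_mid, lat_mid`.
#' @export
scenario_cells <- function(config) {
  g <- config$grid
  ix <- rep(seq_len(g$nx), times = g$ny)
  iy <- rep(seq_len(g$ny), each = g$nx)
  tibble::tibble(
    cell = seq_len(g$nx * g$ny), ix = ix, iy = iy,
    lon_min = g$lon0 + (ix - 1) * g$cell_deg,
    lat_min = g$lat0 + (iy - 1) * g$cell_deg,
    lon_mid = g$lon0 + (ix - 0.5) * g$cell_deg,
    lat_mid = g$lat0 + (iy - 0.5) * g$cell_deg
  )
}

#' Bounding polygon of the simulated grid
#'
#' Convenience study-region polygon covering the whole grid, and the
#' focus-region polygon covering the focus cells' bounding box.
#'
#' @param config a [scenario_config()].
#' @param which `"study"` (whole grid) or `"focus"` (focus-cell bounding
#'   box).
#' @return a [polygon_set()].
#' @export
scenario_polygon <- function(config, which = c("study", "focus")) {
  which <- match.arg(which)
  cells <- scenario_cells(config)
  if (which == "focus") cells <- cells[cells$cell %in% config$focus_cells, ]
  x0 <- min(cells$lon_min); x1 <- max(cells$lon_min) + config$grid$cell_deg
  y0 <- min(cells$lat_min); y1 <- max(cells$lat_min) + config$grid$cell_deg
  polygon_set(list(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))))
}

#' Expected collecting effort per year and cell
#'
#' `effort(year, cell)` is the baseline effort share of the cell times
#' the product of the multipliers of all pulses active in that year whose
#' focus includes the cell. Deterministic in the configuration.
#'
#' @param config a [scenario_config()].
#' @return numeric matrix, years (rows, dimnames = calendar years) by
#'   cells (columns).
#' @export
effort_series <- function(config) {
  yrs <- seq(config$years[1], config$years[2])
  ncell <- config$grid$nx * config$grid$ny
  eff <- matrix(config$baseline_effort / ncell, nrow = length(yrs),
                ncol = ncell, dimnames = list(yrs, seq_len(ncell)))
  for (p in config$pulses) {
    ry <- yrs >= p$start & yrs <= p$end
    cols <- if (is.null(p$cells)) seq_len(ncell) else p$cells
    eff[ry, cols] <- eff[ry, cols] * p$multiplier
  }
  eff
}

# Per-year encounter-rate trajectory of one species-table row.
abundance_trajectory <- function(row, years) {
  yrs <- seq(years[1], years[2])
  switch(row$scenario,
    stable = rep(row$q, length(yrs)),
    declining = ifelse(yrs <= row$change_year, row$q,
                       row$q * row$rate^(yrs - row$change_year)),
    introduced = ifelse(yrs < row$arrival_year, 0,
                        row$q / (1 + exp(-0.5 * (yrs - row$arrival_year -
                                                 row$halfyears)))),
    increasing = row$q * row$rate^(yrs - years[2]),
    stop("unknown scenario: ", row$scenario)
  )
}

# Draw the per-species scenario parameters (truth table). Consumes RNG.
draw_species_table <- function(config) {
  taxa <- data.frame(
    phylum = c("Arthropoda", "Arthropoda", "Mollusca", "Mollusca",
               "Echinodermata", "Echinodermata"),
    class = c("Malacostraca", "Thecostraca", "Gastropoda", "Bivalvia",
              "Asteroidea", "Ophiuroidea"),
    genus = c("Carcinops", "Balanodes", "Littorinops", "Mytilodes",
              "Asteriops", "Ophiurodes"),
    stringsAsFactors = FALSE)
  scen <- c(rep("stable", config$n_stable),
            rep("declining", config$n_declining),
            rep("introduced", config$n_introduced),
            rep("increasing", config$n_increasing))
  n <- length(scen)
  if (n < 1L) stop("empty species pool")
  tax <- taxa[rep_len(seq_len(nrow(taxa)), n), , drop = FALSE]
  ru <- function(r, k) stats::runif(k, r[1], r[2])
  tab <- tibble::tibble(
    species = paste0(tax$genus, " syntheticus", seq_len(n)),
    genus = tax$genus, class = tax$class, phylum = tax$phylum,
    scenario = scen,
    q = NA_real_, change_year = NA_integer_, rate = NA_real_,
    arrival_year = NA_integer_, halfyears = config$introduction_halfyears
  )
  i <- tab$scenario == "stable"
  tab$q[i] <- ru(config$stable_q, sum(i))
  i <- tab$scenario == "declining"
  tab$q[i] <- ru(config$declining_q, sum(i))
  tab$change_year[i] <- sample(seq(config$decline_years[1],
                                   config$decline_years[2]), sum(i), TRUE)
  tab$rate[i] <- ru(config$decline_rate, sum(i))
  i <- tab$scenario == "introduced"
  tab$q[i] <- ru(config$introduced_q, sum(i))
  tab$arrival_year[i] <- sample(seq(config$arrival_years[1],
                                    config$arrival_years[2]), sum(i), TRUE)
  i <- tab$scenario == "increasing"
  tab$q[i] <- ru(config$increasing_q, sum(i))
  tab$rate[i] <- ru(config$growth_rate, sum(i))
  tab
}

#' Simulate a lot-level collection with planted dynamics
#'
#' For every (species, year, cell) the lot count is drawn
#' `Poisson(effort(year, cell) * a_s(year))`, where `a_s` is the species'
#' encounter-rate trajectory (abundance times detectability) under its
#' planted scenario. Each lot becomes one occurrence record at a position
#' jittered uniformly within its cell. Fully reproducible from the seed.
#'
#' @param config a [scenario_config()].
#' @return list with `records` (occurrence tibble in the standard
#'   layout), `truth` (tibble: species, scenario and effect parameters)
#'   and `species_table` (truth including taxonomy and encounter rates).
#' @export
simulate_collections <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  tab <- config$species_table
  if (is.null(tab)) tab <- draw_species_table(config)
  eff <- effort_series(config)
  yrs <- as.integer(rownames(eff))
  cells <- scenario_cells(config)
  ncell <- nrow(cells)
  chunks <- vector("list", nrow(tab))
  for (s in seq_len(nrow(tab))) {
    row <- tab[s, ]
    a <- abundance_trajectory(row, config$years)
    lambda <- eff * a  # recycles a down rows (years)
    counts <- stats::rpois(length(lambda), lambda)
    nz <- which(counts > 0L)
    if (length(nz) == 0L) next
    yr_i <- ((nz - 1L) %% length(yrs)) + 1L
    cl_i <- ((nz - 1L) %/% length(yrs)) + 1L
    k <- counts[nz]
    year <- rep(yrs[yr_i], k)
    cell <- rep(cl_i, k)
    n <- length(year)
    chunks[[s]] <- data.frame(
      species = row$species, genus = row$genus, class = row$class,
      phylum = row$phylum, year = year,
      lat = cells$lat_min[cell] + stats::runif(n) * config$grid$cell_deg,
      lon = cells$lon_min[cell] + stats::runif(n) * config$grid$cell_deg,
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, chunks[!vapply(chunks, is.null, logical(1))])
  if (is.null(rec) || nrow(rec) == 0L)
    stop("simulation produced no records; increase effort or encounter rates")
  if (!is.null(config$war_loss)) {
    wl <- config$war_loss
    at_risk <- rec$year <= wl$interval[2]
    destroyed <- at_risk & stats::runif(nrow(rec)) < wl$fraction
    rec <- rec[!destroyed, , drop = FALSE]
  }
  # stable deposition order: by species then year then position
  ord <- order(rec$species, rec$year, rec$lon, rec$lat)
  rec <- rec[ord, , drop = FALSE]
  records <- tibble::tibble(
    record_id = sprintf("syn%06d", seq_len(nrow(rec))),
    species = rec$species, genus = rec$genus, class = rec$class,
    phylum = rec$phylum, year = as.integer(rec$year),
    lat = rec$lat, lon = rec$lon,
    locality = NA_character_, institution = "SYNTH",
    catalogue_no = sprintf("SYN-%06d", seq_len(nrow(rec)))
  )
  truth <- tab[, c("species", "scenario", "change_year", "rate",
                   "arrival_year", "q")]
  list(records = records, truth = truth, species_table = tab)
}

#' Expected record counts per year under a scenario
#'
#' Analytic expectation (no sampling): the sum over species and cells of
#' effort times the encounter-rate trajectory. Useful for
#' goodness-of-fit checks of the generator.
#'
#' @param config a [scenario_config()].
#' @param species_table species table (e.g. from a simulation's output);
#'   defaults to a freshly drawn one using the config seed.
#' @return named numeric vector of expected lot counts per year.
#' @export
expected_records_per_year <- function(config, species_table = NULL) {
  if (is.null(species_table)) {
    set.seed(config$seed)
    species_table <- draw_species_table(config)
  }
  eff_year <- rowSums(effort_series(config))
  tot <- numeric(length(eff_year))
  for (s in seq_len(nrow(species_table)))
    tot <- tot + abundance_trajectory(species_table[s, ], config$years) * eff_year
  names(tot) <- names(eff_year)
  tot
}

#' Score detector output against the planted truth
#'
#' @param detections data frame with columns `species` and `label`, or a
#'   named character vector of labels. Labels counting as detections per
#'   scenario: `declining_candidate` for planted declines,
#'   `neozoa_candidate` for planted introductions, `increasing` for
#'   planted increases. The species set must match the truth table.
#' @param truth truth tibble from [simulate_collections()] (columns
#'   `species`, `scenario`). Species that produced no records may be
#'   absent from the detections only if absent from `truth` too.
#' @return tibble, one row per planted scenario class present in the
#'   truth: `scenario, label, n_true, tp, fn, fp, n_nontarget,
#'   sensitivity, fpr`.
#' @export
evaluate_detections <- function(detections, truth) {
  if (is.character(detections) && !is.null(names(detections)))
    detections <- tibble::tibble(species = names(detections),
                                 label = unname(detections))
  if (!all(c("species", "label") %in% names(detections)))
    stop("detections need 'species' and 'label'")
  if (anyDuplicated(detections$species))
    stop("duplicate species in detections")
  if (!setequal(detections$species, truth$species))
    stop("species sets of detections and truth differ")
  lab <- detections$label[match(truth$species, detections$species)]
  map <- c(declining = "declining_candidate",
           introduced = "neozoa_candidate",
           increasing = "increasing")
  out <- lapply(intersect(names(map), unique(truth$scenario)), function(sc) {
    pos <- truth$scenario == sc
    det <- lab == map[[sc]]
    tibble::tibble(scenario = sc, label = map[[sc]],
                   n_true = sum(pos), tp = sum(pos & det),
                   fn = sum(pos & !det), fp = sum(!pos & det),
                   n_nontarget = sum(!pos),
                   sensitivity = if (sum(pos)) sum(pos & det) / sum(pos) else NA_real_,
                   fpr = if (sum(!pos)) sum(!pos & det) / sum(!pos) else NA_real_)
  })
  do.call(rbind, out)
}
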