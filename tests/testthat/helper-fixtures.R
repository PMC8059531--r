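# In-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

extdata <- function(name) system.file("extdata", name, package = "lotshift")

# Minimal occurrence tibble builder.
toy_records <- function(species, year, lat = 54, lon = 6,
                        class = "Malacostraca", phylum = "Arthropoda",
                        genus = NA_character_, locality = NA_character_) {
  n <- max(lengths(list(species, year, lat, lon, locality)))
  tibble::tibble(
    record_id = sprintf("t%04d", seq_len(n)),
    species = rep_len(species, n), genus = rep_len(genus, n),
    class = rep_len(class, n), phylum = rep_len(phylum, n),
    year = rep_len(as.integer(year), n),
    lat = rep_len(lat, n), lon = rep_len(lon, n),
    locality = rep_len(locality, n),
    institution = "TEST", catalogue_no = sprintf("c%04d", seq_len(n))
  )
}

unit_square <- function() polygon_set(list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))

# A small scenario used when a test needs a full synthetic collection
# quickly: 30 stable + a few planted species over a short record.
small_scenario <- function(seed, n_stable = 30, n_declining = 3,
                           n_introduced = 2, n_increasing = 2) {
  scenario_config(
    seed = seed, n_stable = n_stable, n_declining = n_declining,
    n_introduced = n_introduced, n_increasing = n_increasing,
    years = c(1880, 2000),
    grid = list(nx = 3, ny = 3, lon0 = 2, lat0 = 53, cell_deg = 1),
    pulses = list(
      list(start = 1902, end = 1912, multiplier = 5, cells = NULL),
      list(start = 1977, end = 1990, multiplier = 20, cells = NULL),
      list(start = 1991, end = 2000, multiplier = 6, cells = NULL)
    ),
    decline_years = c(1913, 1940), arrival_years = c(1920, 1985),
    growth_rate = c(1.015, 1.025)
  )
}
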