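series_from <- function(year, prop, species = "X x", rank = "class") {
  s <- tibble::tibble(year = year, n_species = NA_integer_,
                      n_rank = NA_integer_, proportion = prop)
  attr(s, "species") <- species; attr(s, "rank") <- rank
  s
}

test_that("annual proportions divide species counts by rank totals", {
  rec <- rbind(
    toy_records("A a", c(rep(2000, 1), rep(2001, 2), rep(2002, 3), rep(2000, 9))),
    toy_records("B b", c(rep(2000, 0), rep(2001, 8), rep(2002, 7))))
  # year 2000: A a has 10 of 10; 2001: 2 of 10; 2002: 3 of 10
  s <- annual_proportions(rec, "A a", rank = "class", min_rank_records = 5,
                          min_species_records = 10)
  expect_equal(s$proportion, c(1, 0.2, 0.3))
  expect_equal(s$n_rank, c(10L, 10L, 10L))
})

test_that("rank-years below the record threshold are dropped and zeros filled", {
  rec <- rbind(
    toy_records("A a", c(rep(2000, 2), rep(2001, 3), rep(2002, 5))),
    toy_records("B b", c(rep(2000, 2), rep(2001, 3), rep(2002, 4))))
  s <- annual_proportions(rec, "A a", min_rank_records = 5,
                          min_species_records = 10)
  # 2000 has 4 rank records -> dropped; 2001 has 6, 2002 has 9
  expect_equal(s$year, c(2001L, 2002L))
  # B b has too few records overall for a series of its own
  expect_equal(nrow(annual_proportions(rec, "B b", min_species_records = 10)), 0L)
  # zero-filling: a qualifying year without the species contributes 0
  rec2 <- rbind(toy_records("A a", rep(2000, 10)),
                toy_records("C c", c(rep(2000, 2), rep(2001, 6))))
  s2 <- annual_proportions(rec2, "A a", min_rank_records = 5,
                           min_species_records = 10)
  expect_equal(s2$year, c(2000L, 2001L))
  expect_equal(s2$proportion[2], 0)
  s3 <- annual_proportions(rec2, "A a", min_rank_records = 5,
                           min_species_records = 10, zero_fill = FALSE)
  expect_equal(s3$year, 2000L)
})

test_that("proportions within a rank-year sum to one across species", {
  sim <- simulate_collections(small_scenario(seed = 31))
  rec <- sim$records
  cls <- rec$class[1]
  sp_in_class <- unique(rec$species[rec$class == cls])
  series <- lapply(sp_in_class, function(sp)
    annual_proportions(rec, sp, rank = "class", min_rank_records = 5,
                       min_species_records = 0))
  all_years <- sort(unique(unlist(lapply(series, function(s) s$year))))
  tot <- sapply(all_years, function(y)
    sum(vapply(series, function(s) {
      i <- match(y, s$year)
      if (is.na(i)) 0 else s$proportion[i]
    }, numeric(1))))
  expect_equal(unname(tot), rep(1, length(all_years)), tolerance = 1e-12)
})

test_that("OLS trend reproduces the hand-worked slope and handles degeneracy", {
  s <- series_from(2000:2004, c(0.1, 0.2, 0.15, 0.3, 0.25))
  f <- ols_trend(s)
  expect_equal(f$slope, 0.04, tolerance = 1e-12)  # Sxy/Sxx = 0.4/10
  expect_false(f$degenerate)
  # constant series: slope 0, p 1
  fc <- ols_trend(series_from(2000:2004, rep(0.2, 5)))
  expect_equal(fc$slope, 0)
  expect_equal(fc$p_value, 1)
  # perfectly linear: exact slope, p reported as 0, flagged
  fl <- ols_trend(series_from(2000:2004, 0.1 + 0.02 * (0:4)))
  expect_equal(fl$slope, 0.02, tolerance = 1e-12)
  expect_equal(fl$p_value, 0)
  expect_true(fl$degenerate)
  # fewer than three usable years: no fit
  expect_null(ols_trend(series_from(2000:2001, c(0.1, 0.2))))
})

test_that("OLS trend agrees with a from-scratch least-squares oracle", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    yr <- sort(sample(1900:2015, n))
    prop <- pmin(1, pmax(0, 0.2 + 0.001 * (yr - 1950) + rnorm(n, 0, 0.05)))
    f <- ols_trend(series_from(yr, prop))
    o <- ols_oracle(yr, prop)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$stderr, o$stderr, tolerance = 1e-10)
    expect_equal(f$p_value, o$p_value, tolerance = 1e-10)
  }
})

test_that("trend classification follows the two-rank, two-variant rules", {
  mk <- function(rank, variant, slope, p)
    tibble::tibble(species = "X x", rank = rank, slope = slope, stderr = 1,
                   t_stat = 1, p_value = p, n_years = 10L,
                   degenerate = FALSE, variant = variant)
  # class significant + in both variants, phylum n.s. -> increasing
  f <- rbind(mk("class", "full", 0.01, 0.01), mk("phylum", "full", 0.01, 0.5),
             mk("class", "excl_region", 0.01, 0.01),
             mk("phylum", "excl_region", 0.01, 0.5))
  expect_identical(classify_trend(f)$direction, "increasing")
  # class + and phylum - both significant -> discordant
  f2 <- rbind(mk("class", "full", 0.01, 0.01), mk("phylum", "full", -0.01, 0.01),
              mk("class", "excl_region", 0.01, 0.01),
              mk("phylum", "excl_region", -0.01, 0.01))
  expect_identical(classify_trend(f2)$direction, "discordant_excluded")
  # significant in full only -> none (sensitivity rule)
  f3 <- rbind(mk("class", "full", 0.01, 0.01),
              mk("class", "excl_region", 0.01, 0.5))
  expect_identical(classify_trend(f3)$direction, "none")
})

test_that("trend analysis handles absent or endemic-to-excluded-region species", {
  sim <- simulate_collections(small_scenario(seed = 41))
  rec <- sim$records
  # no exclusion polygon: variants coincide, calls identical by construction
  r1 <- run_trend_analysis(rec, exclusion_polygon = NULL)
  full <- r1$fits[r1$fits$variant == "full", setdiff(names(r1$fits), "variant")]
  excl <- r1$fits[r1$fits$variant == "excl_region",
                  setdiff(names(r1$fits), "variant")]
  expect_equal(as.data.frame(full), as.data.frame(excl))
  # a species endemic to the excluded region gets no call
  box <- polygon_set(list(cbind(c(2, 3, 3, 2), c(53, 53, 54, 54))))
  endemic <- toy_records("Endemic sp", rep(1950:1979, 2), lat = 53.5, lon = 2.5,
                         class = "Malacostraca", phylum = "Arthropoda")
  r2 <- run_trend_analysis(rbind(rec, endemic), exclusion_polygon = box)
  call <- r2$calls[r2$calls$species == "Endemic sp", ]
  expect_identical(call$direction, "none")
  # removing every record is an error
  all_box <- polygon_set(list(cbind(c(0, 10, 10, 0), c(50, 50, 60, 60))))
  expect_error(run_trend_analysis(rec, exclusion_polygon = all_box),
               "removes all records")
})
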