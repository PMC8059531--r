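test_that("split_counts tallies lots around the cutoff with 1912 historical", {
  rec <- toy_records(c("A a", "A a", "A a", "B b", "C c"),
                     c(1905, 1905, 1950, 1900, 1912))
  s <- split_counts(rec, 1912)
  a <- s[s$species == "A a", ]
  expect_equal(a$n_total, 3L)
  expect_equal(a$n_after, 1L)
  expect_equal(a$n_distinct_years, 2L)
  expect_equal(s$n_after[s$species == "B b"], 0L)
  # a record collected in the cutoff year itself is historical
  expect_equal(s$n_after[s$species == "C c"], 0L)
  expect_true(all(s$first_year <= s$last_year))
  expect_error(split_counts(toy_records("A a", NA)), "year")
})

test_that("baseline proportion is the exact post-cutoff lot share", {
  rec <- toy_records("A a", c(rep(2000, 9), 1900))
  b <- baseline_proportion(rec, 1912)
  expect_equal(b$p0, 0.9)
  expect_error(baseline_proportion(toy_records("A a", rep(1900, 5)), 1912),
               "one side")
  expect_error(baseline_proportion(toy_records("A a", rep(2000, 5)), 1912),
               "one side")
})

test_that("decline test matches the exact pmf-summation oracle", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(1:50, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    s <- tibble::tibble(species = "X x", n_total = n, n_after = k,
                        p_decline = NA_real_, label = "unclassified")
    out <- decline_test(s, p0)
    expect_equal(out$p_decline, binom_lower_tail_oracle(k, n, p0),
                 tolerance = 1e-12)
  }
})

test_that("worked decline example: five lots, none recent, baseline 0.832", {
  s <- tibble::tibble(species = "X x", n_total = 5L, n_after = 0L,
                      p_decline = NA_real_, label = "unclassified")
  out <- decline_test(s, 0.832, alpha = 0.05)
  expect_equal(out$p_decline, 0.168^5, tolerance = 1e-12)
  expect_identical(out$label, "declining_candidate")
  # all lots recent: lower tail at its maximum
  s2 <- tibble::tibble(species = "X x", n_total = 10L, n_after = 10L,
                       p_decline = NA_real_, label = "unclassified")
  expect_equal(decline_test(s2, 0.5)$p_decline, 1)
})

test_that("decline p-value is monotone in n_after and in n_total", {
  p0 <- 0.832
  mk <- function(n, k) tibble::tibble(species = "X x", n_total = n,
                                      n_after = k, p_decline = NA_real_,
                                      label = "unclassified")
  p_by_k <- vapply(0:20, function(k) decline_test(mk(20L, k), p0)$p_decline,
                   numeric(1))
  expect_true(all(diff(p_by_k) >= 0))
  p_at_zero <- vapply(1:30, function(n) decline_test(mk(n, 0L), p0)$p_decline,
                      numeric(1))
  expect_true(all(diff(p_at_zero) <= 0))
})

test_that("Benjamini-Hochberg correction and the record floor gate the labels", {
  s <- tibble::tibble(species = c("A a", "B b", "C c"),
                      n_total = c(5L, 5L, 3L), n_after = c(0L, 0L, 0L),
                      p_decline = NA_real_, label = "unclassified")
  raw <- decline_test(s, 0.832, alpha = 1e-4)
  expect_identical(raw$label, rep("unclassified", 3))
  bh <- decline_test(s, 0.832, alpha = 0.05, correction = "benjamini_hochberg")
  expect_equal(bh$p_decline[1], 0.168^5)
  expect_identical(bh$label[1:2], rep("declining_candidate", 2))
  floor <- decline_test(s, 0.832, alpha = 0.05, min_records = 4)
  expect_identical(floor$label[3], "unclassified")
})

test_that("neozoa screen applies the rarity exclusions and the first-year rule", {
  rec <- rbind(
    toy_records("New sp1", c(rep(1950, 5), rep(1960, 4), rep(1980, 3))),
    toy_records("Old sp2", c(1905, rep(1950, 11))),
    toy_records("Rare sp3", rep(1950, 5)),                # < 10 records
    toy_records("Oneyear sp4", rep(1955, 12)),            # single year
    toy_records("Window sp5", c(rep(1978, 6), rep(1985, 6))),  # all 1977-1990
    toy_records("Common sp6", c(rep(1900, 6), rep(1950, 6))))
  s <- neozoa_screen(rec, cutoff_year = 1912, min_records = 10,
                     intensive_window = c(1977, 1990))
  lab <- stats::setNames(s$label, s$species)
  expect_identical(unname(lab["New sp1"]), "neozoa_candidate")
  expect_identical(unname(lab["Old sp2"]), "unclassified")  # first year 1905
  expect_identical(unname(lab["Rare sp3"]), "rare_excluded")
  expect_identical(unname(lab["Oneyear sp4"]), "rare_excluded")
  expect_identical(unname(lab["Window sp5"]), "rare_excluded")
  expect_identical(unname(lab["Common sp6"]), "unclassified")
})

test_that("neozoa and decline labels are mutually exclusive", {
  rec <- rbind(
    toy_records("New sp1", c(rep(1950, 5), rep(1960, 4), rep(1980, 3))),
    toy_records("Old sp2", c(rep(1900, 30), rep(1950, 2))),
    toy_records("Fill sp3", c(rep(1900, 5), rep(1980, 45))))
  b <- baseline_proportion(rec, 1912)
  s <- decline_test(neozoa_screen(rec), b)
  # a post-cutoff-only species has n_after = n_total, so p_decline = 1
  expect_identical(s$label[s$species == "New sp1"], "neozoa_candidate")
  expect_equal(s$p_decline[s$species == "New sp1"], 1)
  expect_identical(s$label[s$species == "Old sp2"], "declining_candidate")
})

test_that("artefact coverage flags species found only in newly worked cells", {
  # pre-cutoff sampling in cell around (0.25, 0.25) only
  rec <- rbind(
    toy_records("Back sp1", rep(1900, 3), lat = 0.25, lon = 0.25),
    toy_records("Good sp2", rep(1950, 4), lat = 0.3, lon = 0.3),
    toy_records("Art sp3", rep(1950, 4), lat = 3.2, lon = 3.2))
  g <- artefact_coverage(rec, "Good sp2", cutoff_year = 1912, cell_deg = 0.5)
  expect_equal(g$coverage, 1)
  expect_false(g$flagged)
  a <- artefact_coverage(rec, "Art sp3", cutoff_year = 1912, cell_deg = 0.5)
  expect_equal(a$coverage, 0)
  expect_true(a$flagged)
  expect_error(artefact_coverage(rec, "Ghost sp", 1912), "not present")
  # species with no post-cutoff records has nothing to explain
  h <- artefact_coverage(rec, "Back sp1", cutoff_year = 1912)
  expect_true(is.na(h$coverage))
  expect_false(h$flagged)
})

test_that("introduced species seeded in historically sampled cells are not flagged", {
  sc <- small_scenario(seed = 21)
  sim <- simulate_collections(sc)
  intro <- sim$truth$species[sim$truth$scenario == "introduced"]
  for (sp in intro) {
    ac <- artefact_coverage(sim$records, sp, cutoff_year = 1912, cell_deg = 1)
    expect_false(ac$flagged)
  }
})
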