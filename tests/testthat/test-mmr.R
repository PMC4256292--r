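make_pair <- function() {
  minus <- counts_dataset(n_sub = 131, n_indel = 130, n_complex = 3,
                          n_isolates = 259, overall_rate = 2236,
                          strain = "double", mmr_deficient = TRUE,
                          pool_imbalanced = TRUE)
  plus <- counts_dataset(n_sub = 72, n_indel = 101, n_isolates = 173,
                         overall_rate = 57, strain = "single",
                         pool_imbalanced = TRUE)
  list(minus = minus, plus = plus)
}

test_that("class correction factor is the ratio of isolate-normalised rates", {
  p <- make_pair()
  cf <- correction_factor(p$minus, p$plus, klass = "single_base_indel")
  expect_equal(cf$cf, (130 / 259 * 2236) / (101 / 173 * 57), tolerance = 1e-12)
  expect_equal(round(cf$cf, 1), 33.7)
  expect_equal(cf$bound, "exact")
  # equal rates give cf = 1
  twin <- p$minus
  twin$background$mmr_deficient <- FALSE
  expect_equal(correction_factor(p$minus, twin, klass = "single_base_indel")$cf, 1)
})

test_that("zero-event sides become one-event bounds with the right flag", {
  p <- make_pair()
  # MMR+ side without complex events: denominator bound (1/173)*57
  cf <- correction_factor(p$minus, p$plus, klass = "complex")
  expect_equal(cf$bound, "lower_bound")
  expect_equal(cf$denominator_rate, 57 / 173)
  # MMR- side empty: upper bound
  cf2 <- correction_factor(
    counts_dataset(n_sub = 10, n_isolates = 50, overall_rate = 100,
                   mmr_deficient = TRUE),
    counts_dataset(n_sub = 5, n_indel = 3, n_isolates = 50, overall_rate = 10),
    klass = "single_base_indel")
  expect_equal(cf2$bound, "upper_bound")
  # both empty: indeterminate, no number invented
  cf3 <- correction_factor(
    counts_dataset(n_sub = 10, n_isolates = 50, overall_rate = 100,
                   mmr_deficient = TRUE),
    counts_dataset(n_sub = 5, n_isolates = 50, overall_rate = 10),
    klass = "single_base_indel")
  expect_equal(cf3$bound, "indeterminate")
  expect_true(is.na(cf3$cf))
})

test_that("cf is invariant under common rescaling of both overall rates", {
  p <- make_pair()
  cf <- correction_factor(p$minus, p$plus, klass = "substitution")
  p$minus$overall_rate <- p$minus$overall_rate * 7
  p$plus$overall_rate <- p$plus$overall_rate * 7
  cf_scaled <- correction_factor(p$minus, p$plus, klass = "substitution")
  expect_equal(cf$cf, cf_scaled$cf)
})

test_that("ratios of correction factors carry the weaker bound", {
  p <- make_pair()
  exact <- correction_factor(p$minus, p$plus, klass = "substitution")
  lower <- correction_factor(p$minus, p$plus, klass = "complex")
  expect_equal(cf_ratio(exact, exact)$bound, "exact")
  expect_equal(cf_ratio(lower, exact)$bound, "lower_bound")
  expect_equal(cf_ratio(exact, lower)$bound, "upper_bound")
})

test_that("site-level correction factors align with per-site lookup", {
  loc <- toy_locus()
  minus <- spectrum_dataset("m", loc, events_df(rep(4L, 20), rep("C", 20),
                                                rep("A", 20)), 100, 1000,
                            mmr_deficient = TRUE)
  plus <- spectrum_dataset("p", loc, events_df(rep(4L, 2), rep("C", 2),
                                               rep("A", 2)), 100, 50)
  tab <- site_correction_factors(minus, plus)
  expect_equal(tab$cf[tab$site == "4:C>A"],
               (20 / 100 * 1000) / (2 / 100 * 50))
  one <- correction_factor(minus, plus, site = "4:C>A")
  expect_equal(one$cf, tab$cf[tab$site == "4:C>A"])
})

test_that("hotspot origin classification follows single-mutant presence", {
  expect_equal(classify_hotspot_origin(TRUE, TRUE, TRUE), "synergistic")
  expect_equal(classify_hotspot_origin(FALSE, TRUE, TRUE), "pool_driven")
  expect_equal(classify_hotspot_origin(TRUE, FALSE, TRUE), "mmr_driven")
  expect_true(is.na(classify_hotspot_origin(FALSE, FALSE, TRUE)))  # neither single
  expect_true(is.na(classify_hotspot_origin(TRUE, TRUE, FALSE)))   # excluded
  hot <- function(sites) data.frame(site = sites, stringsAsFactors = FALSE)
  tab <- hotspot_origin_table(hot(c("a", "c")), hot(c("b", "c")),
                              hot(c("a", "b", "c", "d")))
  expect_equal(tab$origin, c("mmr_driven", "pool_driven", "synergistic", NA))
})

test_that("planted repair efficiencies are recovered from simulated spectra", {
  loc <- fixture_locus(2000, 11)
  cfg <- sim_config(seed = 1, n_isolates = 4000, true_rate = 2236e-7)
  sim <- simulate_spectrum(loc, dntp_pools(), cfg)
  for (k in c("indel_AT", "indel_GC")) {
    cf <- correction_factor(sim$mmr_minus, sim$mmr_plus, klass = k)
    truth <- 1 / cfg$mmr_retention[[k]]
    sd_log <- sqrt(1 / cf$numerator_count + 1 / cf$denominator_count)
    expect_lt(abs(log(cf$cf / truth)), 3 * sd_log)
  }
  # no repair: the two spectra are statistically identical, cf ~ 1
  cfg1 <- sim_config(seed = 2, n_isolates = 3000,
                     mmr_retention = c(substitution = 1, indel_AT = 1,
                                       indel_GC = 1, complex = 1))
  sim1 <- simulate_spectrum(loc, dntp_pools(), cfg1)
  expect_equal(sim1$diagnostics$realised_retention, 1)
  cf1 <- correction_factor(sim1$mmr_minus, sim1$mmr_plus,
                           klass = "single_base_indel")
  expect_lt(abs(log(cf1$cf)), 3 * sqrt(1 / cf1$numerator_count +
                                         1 / cf1$denominator_count))
})
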