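test_that("event classification follows the class/subtype definitions", {
  expect_equal(classify_event("C", "A"), list(klass = "substitution",
                                              subtype = "transversion"))
  expect_equal(classify_event("G", "A"), list(klass = "substitution",
                                              subtype = "transition"))
  expect_equal(classify_event("T", "C")$subtype, "transition")
  expect_equal(classify_event("A", "")$subtype, "deletion")
  expect_equal(classify_event("", "G")$subtype, "insertion")
  expect_equal(classify_event("AT", "")$klass, "complex")   # 2-base deletion
  expect_equal(classify_event("A", "GG")$klass, "complex")
  expect_error(classify_event("A", "A"), "not a mutation")
  expect_error(classify_event("X", "A"), "ACGT")
})

test_that("class rates reproduce the published worked values", {
  wt <- counts_dataset(n_sub = 65, n_indel = 11, n_complex = 17,
                       n_isolates = 93, overall_rate = 4.2)
  expect_equal(round(class_rate(wt, "single_base_indel"), 1), 0.5)

  or1 <- counts_dataset(n_sub = 72, n_indel = 101, n_isolates = 173,
                        overall_rate = 57)
  expect_equal(class_rate(or1, "single_base_indel"), 101 / 173 * 57)
  expect_equal(round(class_rate(or1, "single_base_indel")), 33)

  expect_equal(class_rate(or1, "complex"), 0)   # zero events of a class
})

test_that("class counts conserve the total and scale with the overall rate", {
  ds <- counts_dataset(n_sub = 5, n_indel = 7, n_complex = 2,
                       n_isolates = 20, overall_rate = 10)
  classes <- c("substitution", "single_base_indel", "complex")
  total <- sum(vapply(classes, function(k) sum(ds$events$klass == k), numeric(1)))
  expect_equal(total, nrow(ds$events))
  # homogeneity of degree 1 in overall_rate
  ds2 <- ds; ds2$overall_rate <- ds$overall_rate * 3
  for (k in classes) expect_equal(class_rate(ds2, k), 3 * class_rate(ds, k))
  expect_equal(sum(site_rates(ds2)$rate), 3 * sum(site_rates(ds)$rate))
})

test_that("site rates use the isolate denominator and pool run indels", {
  loc <- toy_locus()
  # 12 substitution events at one site, 173 isolates, rate 57
  ev <- events_df(rep(4L, 12), rep("C", 12), rep("A", 12))
  ds <- spectrum_dataset("s", loc, ev, 173, 57)
  sr <- site_rates(ds)
  expect_equal(nrow(sr), 1L)
  expect_equal(sr$rate, 12 / 173 * 57)
  expect_equal(round(sr$rate, 2), 3.95)

  # deletions at different positions of the same A-run pool to the run span
  ev2 <- events_df(c(9L, 10L, 12L), rep("A", 3), rep("", 3))
  sr2 <- site_rates(spectrum_dataset("s", loc, ev2, 50, 10))
  expect_equal(nrow(sr2), 1L)
  expect_equal(sr2$site, "9-12:-A")
  expect_equal(sr2$count, 3L)
  expect_equal(c(sr2$start, sr2$end), c(9L, 12L))

  # insertions and deletions in the same run are distinct sites
  ev3 <- events_df(c(9L, 10L), c("A", ""), c("", "A"))
  expect_equal(sort(site_rates(spectrum_dataset("s", loc, ev3, 50, 10))$site),
               c("9-12:+A", "9-12:-A"))

  # substitutions are never pooled, even inside a run
  ev4 <- events_df(c(9L, 10L), c("A", "A"), c("T", "T"))
  expect_equal(nrow(site_rates(spectrum_dataset("s", loc, ev4, 50, 10))), 2L)

  # all-distinct sites: one row per event; site rates sum to the event total
  ev5 <- events_df(c(1L, 2L, 4L), c("A", "T", "C"), c("G", "C", "G"))
  ds5 <- spectrum_dataset("s", loc, ev5, 50, 10)
  sr5 <- site_rates(ds5)
  expect_equal(nrow(sr5), 3L)
  expect_equal(sum(sr5$rate), nrow(ev5) / 50 * 10)
})

test_that("hotspot detection applies the 10-fold rule with wt bounds", {
  loc <- toy_locus()
  # mutant: 12 events at site 4 (C>A), 173 isolates, rate 57
  mut <- spectrum_dataset("mut", loc, events_df(rep(4L, 12), rep("C", 12),
                                                rep("A", 12)), 173, 57)
  # wt: no events at that site -> one-event bound denominator
  wt <- spectrum_dataset("wt", loc, events_df(1L, "A", "G"), 93, 4.2)
  hs <- detect_hotspots(mut, wt)
  expect_equal(nrow(hs), 1L)
  expect_true(hs$wt_is_bound)
  expect_equal(hs$wt_rate, 4.2 / 93)
  expect_equal(hs$fold_over_wt, (12 / 173 * 57) / (4.2 / 93), tolerance = 1e-12)
  expect_equal(round(hs$fold_over_wt), 88)

  # identical datasets: fold 1 everywhere, no hotspots
  expect_equal(nrow(detect_hotspots(mut, mut)), 0L)

  # fold of exactly 10 is included (>= rule)
  wt10 <- spectrum_dataset("wt", loc, events_df(4L, "C", "A"), 100, 4)
  mut10 <- spectrum_dataset("m", loc, events_df(4L, "C", "A"), 100, 40)
  hs10 <- detect_hotspots(mut10, wt10)
  expect_equal(hs10$fold_over_wt, 10)
  expect_equal(nrow(hs10), 1L)
})

test_that("orientation comparison reports bounds as one-sided folds", {
  or1 <- toy_locus("OR1"); or2 <- toy_locus("OR2")
  a <- spectrum_dataset("a", or1, events_df(c(4L, 4L), c("C", "C"), c("A", "A")),
                        100, 50)
  b <- spectrum_dataset("b", or2, events_df(c(4L, 4L, 2L, 2L),
                                            c("C", "C", "T", "T"),
                                            c("A", "A", "G", "G")), 100, 50)
  cmp <- compare_orientations(a, b)
  # site 2:T>G present only in OR2: OR1 side is a bound, fold is a ">=" value
  row <- cmp[cmp$site == "2:T>G", ]
  expect_true(row$bound_or1)
  expect_false(row$bound_or2)
  expect_equal(row$fold_cmp, "ge")
  expect_equal(row$higher, "OR2")
  expect_equal(row$fold, (2 / 100 * 50) / (50 / 100))
  # symmetric counts: fold 1, exact
  row2 <- cmp[cmp$site == "4:C>A", ]
  expect_equal(row2$fold, 1)
  expect_equal(row2$fold_cmp, "eq")

  # empty OR2 dataset: every OR1 site paired with an OR2 bound
  empty <- spectrum_dataset("e", or2, events_df(integer(0), character(0),
                                                character(0)), 100, 50)
  cmp2 <- compare_orientations(a, empty)
  expect_true(all(cmp2$bound_or2))
  expect_true(all(cmp2$fold_cmp == "ge"))

  expect_error(compare_orientations(a, a), "same orientation")
})
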