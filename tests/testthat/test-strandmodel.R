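pyr_pools <- dntp_pools()                      # excess {dCTP, dTTP}
pur_pools <- dntp_pools(dATP = 26, dCTP = 1, dGTP = 14, dTTP = 2)
all_pools <- dntp_pools(10, 10, 10, 10)        # everything in excess
none_pools <- dntp_pools(1, 1, 1, 1)           # nothing in excess

test_that("template roles derive from orientation and fork entry", {
  or1 <- toy_locus("OR1")
  expect_equal(template_roles(or1)$coding, "lagging_template")
  expect_equal(template_roles(or1)$noncoding, "leading_template")
  or2 <- toy_locus("OR2")
  expect_equal(template_roles(or2)$coding, "leading_template")
  # flipping orientation flips both roles (involution)
  expect_equal(template_roles(flip_orientation(or2)), template_roles(or1))
  # origin on the 3' side is equivalent to reversing the gene
  or1_3p <- reporter_locus("t", toy_seq, "OR1", "3prime")
  expect_equal(template_roles(or1_3p), template_roles(or2))
})

test_that("substitution candidates follow complement algebra", {
  ca <- substitution_candidates("C", "A")
  expect_equal(ca$template_base, c("C", "G"))
  expect_equal(ca$misinserted, c("T", "A"))
  gt <- substitution_candidates("G", "T")
  expect_equal(gt$misinserted, c("A", "T"))
  ag <- substitution_candidates("A", "G")
  expect_equal(ag$template_base, c("A", "T"))
  expect_equal(ag$misinserted, c("C", "G"))
  expect_error(substitution_candidates("A", "A"), "substitution")
})

test_that("the worked example: C>A is lagging in OR1 and leading in OR2", {
  call_or1 <- assign_substitution("C", "A", toy_locus("OR1"), pyr_pools)
  expect_equal(call_or1$call, "lagging")
  expect_equal(call_or1$template_strand, "coding")
  expect_equal(call_or1$implicated_dNTP, "T")    # dTTP opposite template C
  call_or2 <- assign_substitution("C", "A", toy_locus("OR2"), pyr_pools)
  expect_equal(call_or2$call, "leading")
  expect_equal(call_or2$template_strand, "coding")
  expect_equal(call_or2$implicated_dNTP, "T")
})

test_that("zero or two surviving candidates give unassigned", {
  expect_equal(assign_substitution("C", "A", toy_locus(), all_pools)$call,
               "unassigned")
  expect_equal(assign_substitution("C", "A", toy_locus(), none_pools)$call,
               "unassigned")
})

test_that("assignment table matches the mismatch-resolution oracle", {
  for (pools in list(pyr_pools, pur_pools, all_pools, none_pools)) {
    E <- excess_set(pools)
    tab <- assignment_table(pools)
    expect_equal(nrow(tab), 12L)
    for (i in seq_len(nrow(tab))) {
      hits <- oracle_templates(tab$ref[i], tab$alt[i], E)
      if (length(hits) == 1L) {
        expect_true(tab$assigned[i])
        expect_equal(tab$template_strand[i], hits)
      } else {
        expect_false(tab$assigned[i])
      }
    }
  }
  # strictly pyrimidine excess: all 12 types uniquely assigned
  expect_true(all(assignment_table(pyr_pools)$assigned))
  # strictly purine excess: all 12 assigned, on the complementary template
  t_pyr <- assignment_table(pyr_pools); t_pur <- assignment_table(pur_pools)
  expect_true(all(t_pur$assigned))
  expect_true(all(t_pyr$template_strand != t_pur$template_strand))
  # empty / full excess sets: nothing assignable
  expect_true(all(!assignment_table(none_pools)$assigned))
  expect_true(all(!assignment_table(all_pools)$assigned))
})

test_that("orientation flip swaps every call and preserves assignability", {
  or1 <- toy_locus("OR1"); or2 <- toy_locus("OR2")
  bases <- c("A", "C", "G", "T")
  swap <- c(leading = "lagging", lagging = "leading", unassigned = "unassigned")
  for (pools in list(pyr_pools, pur_pools, none_pools)) {
    for (r in bases) for (a in setdiff(bases, r)) {
      c1 <- assign_substitution(r, a, or1, pools)
      c2 <- assign_substitution(r, a, or2, pools)
      expect_equal(c2$call, unname(swap[c1$call]))
    }
  }
})

test_that("run indels are assigned by the next-incorporated nucleotide", {
  # G-run with a 5' flanking A: copying the coding template, the polymerase
  # next incorporates dTTP (excess) opposite that A -> coding template
  # qualifies; the non-coding path needs dATP (not in excess).
  loc <- reporter_locus("r1", "TAGGGATCAT", "OR1", "5prime")
  call <- assign_run_indel(4L, "G", "", loc, pyr_pools)
  expect_equal(call$template_strand, "coding")
  expect_equal(call$implicated_dNTP, "T")
  expect_equal(call$call, "lagging")            # coding = lagging template in OR1
  expect_equal(assign_run_indel(4L, "G", "", flip_orientation(loc),
                                pyr_pools)$call, "leading")

  # both flanks feed excess dNTPs -> unassigned (no strand bias)
  loc2 <- reporter_locus("r2", "TAGGGCATTG", "OR1", "5prime")
  expect_equal(assign_run_indel(4L, "G", "", loc2, pyr_pools)$call, "unassigned")

  # neither flank -> unassigned
  loc3 <- reporter_locus("r3", "TTGGGAATTG", "OR1", "5prime")
  expect_equal(assign_run_indel(4L, "G", "", loc3, pyr_pools)$call, "unassigned")

  # indel outside any run: unassigned with explicit rationale
  loc4 <- reporter_locus("r4", "ACGTACGTAC", "OR1", "5prime")
  out <- assign_run_indel(2L, "C", "", loc4, pyr_pools)
  expect_equal(out$call, "unassigned")
  expect_match(out$rationale, "no run context")
})

test_that("assign_strand covers all events and complex events stay unassigned", {
  loc <- toy_locus()
  ev <- events_df(c(4L, 9L, 1L), c("C", "A", "AT"), c("A", "", ""))
  ds <- spectrum_dataset("s", loc, ev, 10, 5)
  calls <- assign_strand(ds, pyr_pools)
  expect_equal(nrow(calls), 3L)
  expect_equal(calls$call[calls$klass == "complex"], "unassigned")
  smry <- strand_summary(calls)
  expect_equal(smry$leading + smry$lagging + smry$unassigned, 3L)
})
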