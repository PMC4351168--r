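mk_calls <- function(rsid, on_chip, traits = rep(list("BMI"), length(rsid))) {
  tibble::tibble(rsid = rsid, chrom = "1",
                 pos = seq_along(rsid) * 10L, traits = traits,
                 on_chip = on_chip,
                 matched_probes = purrr::map2(rsid, on_chip,
                                              ~ if (.y) .x else character(0)))
}

mk_claims <- function(rsid, present, ref = "HapMap3") {
  tibble::tibble(rsid = rsid, array_name = "chip",
                 claimed_present = present,
                 warning = ifelse(present, "none", "not_in_reference"),
                 reference = ref)
}

test_that("classification is the four-way truth table", {
  expect_equal(classify_status(TRUE, TRUE), "TP")
  expect_equal(classify_status(TRUE, FALSE), "FN")
  expect_equal(classify_status(FALSE, TRUE), "FP")
  expect_equal(classify_status(FALSE, FALSE), "TN")
  # total and single-valued over all boolean pairs, vectorised
  g <- expand.grid(m = c(TRUE, FALSE), t = c(TRUE, FALSE))
  expect_setequal(classify_status(g$m, g$t), c("TP", "FN", "FP", "TN"))
})

test_that("join pairs each call with exactly one claim and classifies", {
  calls <- mk_calls(c("rs1", "rs2", "rs3"), c(TRUE, TRUE, FALSE))
  claims <- mk_claims(c("rs1", "rs2", "rs3"), c(TRUE, FALSE, FALSE))
  rec <- join_and_classify(calls, claims, "HapMap3")
  expect_equal(rec$status, c("TP", "FN", "TN"))
  expect_equal(rec$reference, rep("HapMap3", 3))

  expect_error(
    join_and_classify(calls, claims[-2, ], "HapMap3"), "rs2",
    class = "chipconcord_validation_error")
  expect_error(
    join_and_classify(calls, rbind(claims, claims[1, ]), "HapMap3"), "rs1",
    class = "chipconcord_validation_error")
  # claims for another reference are invisible to this join
  other <- rbind(claims, mk_claims("rs1", FALSE, ref = "1000Genomes"))
  expect_equal(join_and_classify(calls, other, "HapMap3")$status[1], "TP")
})

test_that("tabulation counts pleiotropic SNPs per trait but once overall", {
  calls <- mk_calls(c("rs1", "rs2", "rs3"), c(TRUE, TRUE, FALSE),
                    traits = list(c("BMI", "Lipids"), "BMI", "Lipids"))
  claims <- mk_claims(c("rs1", "rs2", "rs3"), c(TRUE, TRUE, FALSE))
  rec <- join_and_classify(calls, claims, "HapMap3")
  all_tab <- tabulate_records(rec, "ALL")
  bmi <- tabulate_records(rec, "BMI")
  lip <- tabulate_records(rec, "Lipids")
  expect_equal(c(all_tab$tp, all_tab$tn), c(2L, 1L))
  expect_equal(bmi$tp, 2L)               # rs1 contributes to BMI...
  expect_equal(c(lip$tp, lip$tn), c(1L, 1L))  # ...and to Lipids
  # per-trait n exceeds pooled n by the extra trait memberships
  expect_equal((bmi$tp + bmi$fn + bmi$fp + bmi$tn) +
                 (lip$tp + lip$fn + lip$fp + lip$tn),
               (all_tab$tp + all_tab$fn + all_tab$fp + all_tab$tn) + 1L)

  empty <- tabulate_records(rec[0, ], "ALL")
  expect_equal(empty$tp + empty$fn + empty$fp + empty$tn, 0L)
})

test_that("fixture bookkeeping: 421 trait memberships, 415 SNPs, known dup statuses", {
  fx <- metabochip_fixture()
  idx <- build_position_index(fx$manifest)
  calls <- suppressMessages(check_batch(fx$queries, idx))
  rec <- join_and_classify(calls, fx$claims$HapMap3, "HapMap3")

  traits <- c("Blood pressure", "Fasting glucose", "BMI", "Lipids")
  per_trait <- lapply(traits, tabulate_records, records = rec)
  names(per_trait) <- traits
  n_of <- function(t) t$tp + t$fn + t$fp + t$tn
  expect_equal(vapply(per_trait, n_of, integer(1)),
               c(`Blood pressure` = 37L, `Fasting glucose` = 39L,
                 BMI = 69L, Lipids = 276L))
  all_tab <- tabulate_records(rec, "ALL")
  expect_equal(sum(vapply(per_trait, n_of, integer(1))), 421L)
  expect_equal(n_of(all_tab), 415L)

  # cell-wise: per-trait sums minus the 6 pleiotropic duplicates (3 TP,
  # 2 TN, 1 FN under the HapMap3-like claims) give the pooled cells
  cell_sum <- function(cell) sum(vapply(per_trait, `[[`, integer(1), cell))
  expect_equal(cell_sum("tp") - all_tab$tp, 3L)
  expect_equal(cell_sum("tn") - all_tab$tn, 2L)
  expect_equal(cell_sum("fn") - all_tab$fn, 1L)
  expect_equal(cell_sum("fp") - all_tab$fp, 0L)
})

test_that("contingency tables reject malformed cells", {
  expect_error(contingency_table(-1, 0, 0, 0),
               class = "chipconcord_validation_error")
  expect_error(contingency_table(1.5, 0, 0, 0),
               class = "chipconcord_validation_error")
  tab <- contingency_table(2, 1, 0, 3)
  expect_s3_class(tab, "contingency_table")
  expect_output(print(tab), "concordances=5")
})
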