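# Simulations here use a scaled-down manifest (a few thousand probes
# instead of ~196,725): membership and miss-rate behaviour only depend on
# the query/claim structure, and the small manifest keeps the suite fast.
small_cfg <- function(...) {
  synthetic_config(n_probes = 2000, ...)
}

test_that("generation is reproducible under a fixed seed", {
  a <- simulate_audit(small_cfg(seed = 5))
  b <- simulate_audit(small_cfg(seed = 5))
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$queries, b$queries)
  expect_identical(a$claims, b$claims)
  c_ <- simulate_audit(small_cfg(seed = 6))
  expect_false(identical(a$queries$pos, c_$queries$pos))
})

test_that("config validation rejects impossible worlds", {
  expect_error(synthetic_config(frac_on_chip = 1.2),
               class = "chipconcord_config_error")
  expect_error(synthetic_config(fp_rate = -0.1),
               class = "chipconcord_config_error")
  expect_error(synthetic_config(miss_rates = c(0.5, 0.1)),
               class = "chipconcord_config_error")
})

test_that("simulated truth matches what the pipeline recovers", {
  sim <- simulate_audit(small_cfg(n_queries = 300, seed = 21))
  res <- suppressMessages(
    run_validate(sim$queries, sim$manifest, sim$claims))
  expect_equal(res$calls$on_chip, sim$truth$on_chip)
  for (ref in names(sim$claims)) {
    rec <- res$records[[ref]]
    expect_equal(rec$status,
                 classify_status(sim$truth$on_chip,
                                 sim$truth[[paste0("claimed_", ref)]]))
  }
})

test_that("fp_rate = 0 yields zero false positives; no noise yields kappa 1", {
  sim <- simulate_audit(small_cfg(n_queries = 415, seed = 31))
  res <- suppressMessages(run_validate(sim$queries, sim$manifest, sim$claims))
  for (ref in names(res$records)) {
    expect_equal(sum(res$records[[ref]]$status == "FP"), 0L)
  }
  clean <- simulate_audit(small_cfg(
    n_queries = 200, miss_rates = c(HapMap3 = 0), fp_rate = 0, seed = 32))
  res2 <- suppressMessages(
    run_validate(clean$queries, clean$manifest, clean$claims))
  expect_equal(res2$summaries$HapMap3$kappa,
               rep(1, nrow(res2$summaries$HapMap3)))
})

test_that("default-world FN counts sit in the binomial sampling range", {
  sim <- simulate_audit(small_cfg(seed = 41))
  res <- suppressMessages(run_validate(sim$queries, sim$manifest, sim$claims))
  n_on <- sum(sim$truth$on_chip)
  expected_on <- 415 * 366 / 415
  expect_lt(abs(n_on - expected_on), 5 * sqrt(415 * (366 / 415) * (49 / 415)))
  for (ref in c("HapMap3", "1000Genomes")) {
    m <- synthetic_config()$miss_rates[[ref]]
    fn <- sum(res$records[[ref]]$status == "FN")
    expect_lt(abs(fn - n_on * m), 5 * sqrt(n_on * m * (1 - m)))
  }
})

test_that("expected-table kappa is approached as the query count grows", {
  # closed form on the expected table n * (q(1-m), qm, 0, 1-q)
  q <- 366 / 415; m <- 152 / 366
  expected <- cohen_kappa(contingency_table(
    round(1e4 * q * (1 - m)), round(1e4 * q * m), 0, round(1e4 * (1 - q))))
  sim <- simulate_audit(synthetic_config(
    n_probes = 8000, n_queries = 6000,
    miss_rates = c(HapMap3 = m), pleiotropy_count = 0, seed = 51))
  res <- suppressMessages(run_validate(sim$queries, sim$manifest, sim$claims))
  tab <- tabulate_records(res$records$HapMap3, "ALL")
  expect_lt(abs(cohen_kappa(tab) - expected), 0.05)
})

test_that("the deterministic fixture classifies to the exact target tables", {
  fx <- metabochip_fixture()
  expect_equal(nrow(fx$queries), 415L)
  expect_equal(sum(lengths(fx$queries$traits)), 421L)
  expect_equal(sum(lengths(fx$queries$traits) == 2L), 6L)
  calls <- suppressMessages(
    check_batch(fx$queries, build_position_index(fx$manifest)))
  expected <- list(
    HapMap3 = list(`Blood pressure` = c(21, 9, 0, 7),
                   `Fasting glucose` = c(20, 19, 0, 0),
                   BMI = c(26, 34, 0, 9), Lipids = c(150, 91, 0, 35),
                   ALL = c(214, 152, 0, 49)),
    `1000Genomes` = list(`Blood pressure` = c(28, 2, 0, 7),
                         `Fasting glucose` = c(39, 0, 0, 0),
                         BMI = c(33, 27, 0, 9), Lipids = c(196, 45, 0, 35),
                         ALL = c(293, 73, 0, 49)))
  for (ref in names(expected)) {
    rec <- join_and_classify(calls, fx$claims[[ref]], ref)
    for (g in names(expected[[ref]])) {
      tab <- tabulate_records(rec, g)
      expect_equal(c(tab$tp, tab$fn, tab$fp, tab$tn),
                   expected[[ref]][[g]],
                   info = paste(ref, g))
    }
  }
  expect_identical(metabochip_fixture(), fx)  # no hidden randomness
})
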