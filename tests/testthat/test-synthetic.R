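test_that("the default spec encodes the reference marginals exactly", {
  spec <- default_cohort_spec()
  expect_equal(spec$n_ems, 119)
  expect_equal(spec$n_no_ems, 109)
  prev <- spec$item_prev
  expect_equal(prev$p_ems[prev$item_id == "adj_cramping"], 97 / 119)
  expect_equal(prev$p_no_ems[prev$item_id == "loc_gluteal"], 0)
  expect_equal(prev$p_ems[prev$item_id == "dysuria"], 42 / 119)
  expect_equal(prev$p_no_ems[prev$item_id == "dysuria"], 1 / 109)
  # band probabilities per group sum to one
  expect_equal(sum(spec$paindetect_bands$EMS), 1)
  expect_equal(sum(spec$paindetect_bands$NO_EMS), 1)
  expect_equal(sum(spec$timing$EMS), 1)
  expect_equal(sum(spec$timing$NO_EMS), 1)
})

test_that("generation is reproducible from the seed, byte-for-byte", {
  spec <- default_cohort_spec(seed = 99)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, f1)
  write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different cohort
  c3 <- generate_cohort(default_cohort_spec(seed = 100))
  expect_false(identical(c1, c3))
})

test_that("generated cohorts satisfy every record invariant", {
  coh <- generate_cohort(default_cohort_spec(seed = 3))
  expect_equal(nrow(coh), 228)
  expect_equal(nrow(validate_cohort(coh)), 0)
  expect_equal(sum(coh$label == "EMS"), 119)
})

test_that("empty groups yield an empty cohort and empty marginal report", {
  coh <- generate_cohort(default_cohort_spec(n_ems = 0, n_no_ems = 0,
                                             seed = 1))
  expect_equal(nrow(coh), 0)
  expect_equal(nrow(recover_marginals(coh)), 0)
})

test_that("recover_marginals returns exact fractions on a hand-built cohort", {
  coh <- empty_cohort(4)
  coh$patient_id <- letters[1:4]
  coh$label <- c("EMS", "EMS", "NO_EMS", "NO_EMS")
  coh$dysuria <- c(TRUE, FALSE, FALSE, FALSE)
  rec <- recover_marginals(coh)
  expect_equal(rec$frac[rec$item_id == "dysuria" & rec$group == "EMS" &
                          rec$source == "item"], 0.5)
  expect_equal(rec$frac[rec$item_id == "dysuria" & rec$group == "NO_EMS" &
                          rec$source == "item"], 0)
})

test_that("directly sampled marginals are recovered within 3 binomial SEs", {
  spec <- default_cohort_spec(n_ems = 11900, n_no_ems = 10900, seed = 17)
  coh <- generate_cohort(spec)
  rec <- recover_marginals(coh, spec)
  # raw generator items (all directly sampled)
  items <- rec[rec$source == "item", ]
  se <- pmax(sqrt(items$target * (1 - items$target) /
                    ifelse(items$group == "EMS", 11900, 10900)), 1e-9)
  expect_true(all(abs(items$diff) <= pmax(3 * se, 0.004)))
  # SP rules that are one-to-one with a sampled quantity
  derived <- c("dysmenorrhea_nrs_gt3", "sum_vas_gt8.5")
  sp <- rec[rec$source == "sp" & !rec$item_id %in% derived, ]
  se <- pmax(sqrt(sp$target * (1 - sp$target) /
                    ifelse(sp$group == "EMS", 11900, 10900)), 1e-9)
  expect_true(all(abs(sp$diff) <= pmax(3 * se, 0.004)))
})

test_that("prevalence-0 or -1 items give constant columns", {
  spec <- default_cohort_spec(n_ems = 200, n_no_ems = 200, seed = 2)
  spec$item_prev$p_ems[spec$item_prev$item_id == "dysuria"] <- 1
  spec$item_prev$p_no_ems[spec$item_prev$item_id == "dysuria"] <- 0
  coh <- generate_cohort(spec)
  expect_true(all(coh$dysuria[coh$label == "EMS"]))
  expect_false(any(coh$dysuria[coh$label == "NO_EMS"]))
})

test_that("the mean SP count is invariant to the copula correlation", {
  big <- function(rho, seed) {
    spec <- default_cohort_spec(n_ems = 15000, n_no_ems = 15000,
                                copula_rho = rho, seed = seed)
    sc <- score_cohort(generate_cohort(spec))
    tapply(sc$sum_sp, sc$label, mean)
  }
  m0 <- big(0, 21)
  m6 <- big(0.6, 22)
  expect_lt(abs(m0[["EMS"]] - m6[["EMS"]]), 0.15)
  expect_lt(abs(m0[["NO_EMS"]] - m6[["NO_EMS"]]), 0.15)
})

test_that("group SP-count means track the sum of the registry prevalences", {
  reg <- default_sp_registry()
  sc <- score_cohort(generate_cohort(default_cohort_spec(
    n_ems = 5950, n_no_ems = 5450, seed = 23)))
  # expectation identity, allowing for the two model-derived rules
  expect_lt(abs(mean(sc$sum_sp[sc$label == "EMS"]) - sum(reg$ems_yes) / 119),
            0.6)
  expect_lt(abs(mean(sc$sum_sp[sc$label == "NO_EMS"]) -
                  sum(reg$no_ems_yes) / 109), 0.6)
})
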