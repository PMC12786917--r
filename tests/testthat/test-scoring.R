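test_that("the neuropathic-pain score spans 0-38 and bands partition it", {
  coh <- empty_cohort(2)
  coh$patient_id <- c("lo", "hi")
  coh[1, sens_cols] <- 0L
  coh$course_pattern[1] <- "PERSISTENT_SLIGHT_FLUCT"
  coh$radiating_pain[1] <- FALSE
  coh[2, sens_cols] <- 5L
  coh$course_pattern[2] <- "ATTACKS_WITH_PAIN_BETWEEN"
  coh$radiating_pain[2] <- TRUE
  pd <- paindetect_score(coh)
  expect_equal(pd$paindetect_final, c(0L, 38L))
  expect_equal(as.character(pd$paindetect_band), c("NEGATIVE", "POSITIVE"))

  # band edges at 12/13 and 18/19
  expect_equal(as.character(paindetect_band(c(12L, 13L, 18L, 19L))),
               c("NEGATIVE", "UNCLEAR", "UNCLEAR", "POSITIVE"))
  # partition: every score in 0-38 maps to exactly one band
  bands <- paindetect_band(0:38)
  expect_false(anyNA(bands))
  expect_equal(as.vector(table(bands)), c(13, 6, 20))
})

test_that("pattern adjustment is clamped at zero and missingness is explicit", {
  coh <- empty_cohort(2)
  coh$patient_id <- c("neg", "blank")
  coh[1, sens_cols] <- 0L
  coh$course_pattern[1] <- "PERSISTENT_WITH_ATTACKS"  # adjustment -1
  pd <- paindetect_score(coh)
  expect_equal(pd$paindetect_final[1], 0L)            # clamped, not -1
  expect_true(is.na(pd$paindetect_final[2]))          # nothing answered
  expect_true(is.na(pd$paindetect_band[2]))
})

test_that("the pain-intensity sum follows its item list under both variants", {
  coh <- empty_cohort(1)
  coh$patient_id <- "x"
  expect_equal(sum_vas(coh), 0)
  expect_equal(sum_vas(coh, "five_item"), 0)

  coh[c("dysmenorrhea", "dyspareunia", "dysuria", "dyschezia", "cpp")] <- TRUE
  coh[c("dysmenorrhea_nrs", "dyspareunia_nrs", "dysuria_nrs",
        "dyschezia_nrs", "cpp_nrs")] <- c(6L, 4L, 2L, 3L, 4L)
  coh[c("pain_now_nrs", "strongest_4wks_nrs", "average_4wks_nrs")] <-
    c(3L, 8L, 5L)
  expect_equal(sum_vas(coh), 35)
  expect_equal(sum_vas(coh, "five_item"), 19)
})

test_that("the registry holds 34 rules, 33 of them record-level", {
  reg <- default_sp_registry()
  expect_equal(nrow(reg), 34)
  expect_false(anyDuplicated(reg$sp_id) > 0)
  expect_equal(sum(reg$kind != "sum_vas_gt"), 33)
  expect_equal(reg$kind[34], "sum_vas_gt")
  f <- withr::local_tempfile(fileext = ".json")
  write_sp_registry(reg, f)
  expect_equal(read_sp_registry(f), reg)
})

test_that("indicator examples: all-missing, adjectives-only, presence plus threshold", {
  coh <- empty_cohort(1)
  coh$patient_id <- "m"
  ind <- sp_indicators(coh)
  expect_equal(sum(ind), 0)
  expect_equal(ncol(ind), 34)

  adj <- empty_cohort(1)
  adj$patient_id <- "adj"
  adj[paste0("adj_", c("cramping", "tearing", "pulling", "stinging",
                       "pulsatile", "touch_sensitive", "pressing",
                       "cold_warmth", "flashing"))] <- TRUE
  ind <- sp_indicators(adj)
  expect_equal(sum(ind), 9)
  expect_true(all(ind[, paste0("adj_", c("cramping", "tearing", "pulling",
                                         "stinging", "pulsatile",
                                         "touch_sensitive", "pressing",
                                         "cold_warmth", "flashing"))]))

  dm <- empty_cohort(1)
  dm$patient_id <- "dm"
  dm$dysmenorrhea <- TRUE
  dm$dysmenorrhea_nrs <- 4L
  ind <- sp_indicators(dm)
  expect_true(ind[, "dysmenorrhea"])       # presence
  expect_true(ind[, "dysmenorrhea_nrs_gt3"])  # separate threshold rule
  expect_equal(sum(ind), 2)
})

test_that("the SP count equals an independent re-evaluation of all 34 rules", {
  set.seed(202)
  coh <- random_cohort(1000)
  sv <- sum_vas(coh)
  pd <- paindetect_score(coh)
  ind <- sp_indicators(coh, sum_vas_value = sv,
                       paindetect_final = pd$paindetect_final)
  got <- sum_sp(ind)

  # oracle: literal per-rule evaluation, written out independently
  t_ <- function(x) !is.na(x) & x
  oracle <- t_(coh$analgesic_use) + t_(coh$dysmenorrhea) +
    t_(coh$dysmenorrhea_nrs > 3) +
    (t_(coh$pain_before_menses) & t_(coh$pain_during_menses) &
       !t_(coh$pain_after_menses)) +
    t_(coh$cpp) + t_(coh$dysuria) + t_(coh$dyschezia) + t_(coh$dyspareunia) +
    t_(coh$obstipation) + t_(coh$diarrhea) +
    t_(coh$adj_cramping) + t_(coh$adj_tearing) + t_(coh$adj_pulling) +
    t_(coh$adj_stinging) + t_(coh$adj_pulsatile) +
    t_(coh$adj_touch_sensitive) + t_(coh$adj_pressing) +
    t_(coh$adj_cold_warmth) + t_(coh$adj_flashing) +
    t_(coh$pain_now_nrs > 0) + t_(coh$strongest_4wks_nrs > 0) +
    t_(coh$average_4wks_nrs > 0) +
    t_(coh$loc_lower_abdomen) + t_(coh$loc_lumbar_spine) +
    t_(coh$loc_thighs_legs) + t_(coh$loc_hips_groins) +
    t_(coh$loc_upper_abdomen) + t_(coh$loc_vagina_mons) +
    t_(coh$loc_gluteal) +
    t_(coh$course_pattern == "PERSISTENT_WITH_ATTACKS") +
    t_(coh$course_pattern == "ATTACKS_NO_PAIN_BETWEEN") +
    t_(coh$course_pattern == "ATTACKS_WITH_PAIN_BETWEEN") +
    t_(pd$paindetect_final > 3) + (sv > 8.5)
  expect_equal(got, as.integer(oracle))
  expect_true(all(got >= 0 & got <= 34))
})

test_that("making an answer more symptomatic never lowers SP count or pain sum", {
  set.seed(303)
  coh <- random_cohort(200)
  base_sc <- score_cohort(coh)
  cb <- default_codebook()
  # monotone directions: symptom/adjective/location booleans to TRUE,
  # any NRS or sensory item up (symptom flags raised alongside their NRS
  # so records stay valid); the exclusive menstrual-timing answers are a
  # single categorical question and are left alone.
  bool_items <- setdiff(cb$item_id[cb$value_kind == "BOOLEAN"],
                        c("pain_before_menses", "pain_during_menses",
                          "pain_after_menses", "smoker", "allergies"))
  nrs_items <- cb$item_id[cb$value_kind %in% c("NRS_0_10", "SENSORY_0_5")]
  for (i in 1:150) {
    coh2 <- coh
    row <- sample(nrow(coh), 1)
    if (stats::runif(1) < 0.5) {
      col <- sample(bool_items, 1)
      coh2[[col]][row] <- TRUE
    } else {
      col <- sample(nrs_items, 1)
      hi <- if (grepl("^sens_", col)) 5L else 10L
      cur <- coh2[[col]][row]
      coh2[[col]][row] <- if (is.na(cur)) hi else min(cur + 1L, hi)
      sym <- c(dysmenorrhea_nrs = "dysmenorrhea", cpp_nrs = "cpp",
               dysuria_nrs = "dysuria", dyschezia_nrs = "dyschezia",
               dyspareunia_nrs = "dyspareunia")[col]
      if (!is.na(sym)) coh2[[sym]][row] <- TRUE
    }
    sc2 <- score_cohort(coh2)
    expect_gte(sc2$sum_sp[row], base_sc$sum_sp[row])
    expect_gte(sc2$sum_vas[row], base_sc$sum_vas[row])
  }
})

test_that("sum_sp rejects indicator matrices that do not match the registry", {
  coh <- empty_cohort(2)
  coh$patient_id <- c("a", "b")
  ind <- sp_indicators(coh)
  expect_error(sum_sp(ind[, 1:10]), "registry")
})
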