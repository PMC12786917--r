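# Random-record builder used by the I/O and scoring property tests.
# Deliberately independent of the calibrated generator: fields are filled
# with unstructured draws (including missingness) that respect the record
# invariants, so round-trip and scoring checks exercise the full schema.
random_cohort <- function(n, missing_prob = 0.2) {
  cb <- default_codebook()
  coh <- empty_cohort(n, cb)
  coh$patient_id <- sprintf("P%05d", seq_len(n))
  lv <- codebook_levels()
  maybe_na <- function(x) {
    x[stats::runif(length(x)) < missing_prob] <- NA
    x
  }
  coh$label <- maybe_na(sample(lv$label, n, replace = TRUE))
  coh$contraceptive <- maybe_na(sample(lv$contraceptive, n, replace = TRUE))
  coh$course_pattern <- maybe_na(sample(lv$course_pattern, n, replace = TRUE))
  for (col in cb$item_id[cb$value_kind == "REAL"]) {
    coh[[col]] <- maybe_na(round(stats::runif(n, 10, 40), 1))
  }
  bool_cols <- cb$item_id[cb$value_kind == "BOOLEAN"]
  for (col in bool_cols) {
    coh[[col]] <- maybe_na(sample(c(TRUE, FALSE), n, replace = TRUE))
  }
  for (col in cb$item_id[cb$value_kind == "SENSORY_0_5"]) {
    coh[[col]] <- maybe_na(sample(0:5, n, replace = TRUE))
  }
  # NRS fields: keep the symptom-absent => NRS 0 invariant
  pairs <- list(dysmenorrhea_nrs = "dysmenorrhea", cpp_nrs = "cpp",
                dysuria_nrs = "dysuria", dyschezia_nrs = "dyschezia",
                dyspareunia_nrs = "dyspareunia")
  for (col in cb$item_id[cb$value_kind == "NRS_0_10"]) {
    v <- maybe_na(sample(0:10, n, replace = TRUE))
    sym <- pairs[[col]]
    if (!is.null(sym)) {
      absent <- !is.na(coh[[sym]]) & !coh[[sym]]
      v[absent] <- 0L
    }
    coh[[col]] <- v
  }
  coh
}

sens_cols <- paste0("sens_", c("burning", "tingling", "allodynia",
                               "attacks", "thermal", "numbness", "pressure"))
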