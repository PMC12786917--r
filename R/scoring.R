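#' PainDETECT final score and band
#'
#' The neuropathic-pain final score is the sum of the seven 0--5 sensory
#' items (0--35), plus a pain-course-pattern adjustment (persistent with
#' slight fluctuations 0, persistent with pain attacks -1, attacks without
#' pain between them +1, attacks with pain between them +1), plus 2 if the
#' pain radiates, clamped to 0--38. Missing components contribute 0. A
#' record with *every* PainDETECT input missing (all seven sensory items,
#' the course pattern, and the radiating-pain flag) is not scorable and
#' gets `NA` rather than a silent 0.
#'
#' Bands partition the score range: negative 0--12, unclear 13--18,
#' positive 19--38.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @return Data frame with columns `paindetect_final` (integer or `NA` when
#'   not scorable) and `paindetect_band` (factor
#'   `NEGATIVE`/`UNCLEAR`/`POSITIVE`, `NA` when not scorable).
#' @export
#' @examples
#' coh <- empty_cohort(1)
#' coh[paste0("sens_", c("burning", "tingling", "allodynia", "attacks",
#'                       "thermal", "numbness", "pressure"))] <- 5L
#' coh$course_pattern <- "ATTACKS_WITH_PAIN_BETWEEN"
#' coh$radiating_pain <- TRUE
#' paindetect_score(coh)   # 38, POSITIVE
paindetect_score <- function(cohort) {
  sens_cols <- paste0("sens_", c("burning", "tingling", "allodynia",
                                 "attacks", "thermal", "numbness",
                                 "pressure"))
  sens <- as.matrix(cohort[sens_cols])
  pattern_adj <- c(PERSISTENT_SLIGHT_FLUCT = 0, PERSISTENT_WITH_ATTACKS = -1,
                   ATTACKS_NO_PAIN_BETWEEN = 1, ATTACKS_WITH_PAIN_BETWEEN = 1)
  adj <- pattern_adj[cohort$course_pattern]
  adj[is.na(adj)] <- 0
  rad <- ifelse(!is.na(cohort$radiating_pain) & cohort$radiating_pain, 2, 0)
  total <- rowSums(sens, na.rm = TRUE) + adj + rad
  final <- as.integer(pmin(pmax(total, 0), 38))
  scorable <- rowSums(!is.na(sens)) > 0 | !is.na(cohort$course_pattern) |
    !is.na(cohort$radiating_pain)
  final[!scorable] <- NA_integer_
  band <- paindetect_band(final)
  data.frame(paindetect_final = final, paindetect_band = band,
             stringsAsFactors = FALSE)
}

#' @rdname paindetect_score
#' @param final Integer vector of final scores in 0--38 (`NA` allowed).
#' @export
paindetect_band <- function(final) {
  cut(final, breaks = c(-0.5, 12.5, 18.5, 38.5),
      labels = c("NEGATIVE", "UNCLEAR", "POSITIVE"))
}

#' Pain-intensity sum (sum of NRS/VAS items)
#'
#' The composite pain-intensity score per patient. The `"eight_item"`
#' variant (default) sums the numeric rating scales for dysmenorrhea,
#' dyspareunia, dysuria, dyschezia, chronic pelvic pain, pain now,
#' strongest pain in the last 4 weeks, and average pain; the
#' `"five_item"` variant restricts to the five "classical" symptom scales
#' (dysmenorrhea, dyspareunia, dysuria, dyschezia, chronic pelvic pain).
#' Both variants are provided because the reference report's per-item
#' means are arithmetically consistent only with the five-item sum while
#' its methods describe the eight-item list; see the methods vignette.
#' Missing values count as 0, so the score is always defined.
#'
#' @inheritParams paindetect_score
#' @param variant `"eight_item"` or `"five_item"`.
#' @return Numeric vector in 0--80 (eight-item) or 0--50 (five-item).
#' @export
sum_vas <- function(cohort, variant = c("eight_item", "five_item")) {
  variant <- match.arg(variant)
  cols <- c("dysmenorrhea_nrs", "dyspareunia_nrs", "dysuria_nrs",
            "dyschezia_nrs", "cpp_nrs")
  if (variant == "eight_item") {
    cols <- c(cols, "pain_now_nrs", "strongest_4wks_nrs", "average_4wks_nrs")
  }
  rowSums(as.matrix(cohort[cols]), na.rm = TRUE)
}

#' Evaluate the significant-parameter indicators
#'
#' Applies every rule of an SP registry to each record. Missing underlying
#' answers evaluate to `FALSE` (a single missing answer is never decisive).
#'
#' @inheritParams paindetect_score
#' @param registry SP registry (see [default_sp_registry()]).
#' @param sum_vas_value Numeric vector of pain-intensity sums, needed for
#'   score-level rules; computed from `cohort` with the default variant
#'   when omitted.
#' @param paindetect_final Integer vector of PainDETECT final scores;
#'   computed from `cohort` when omitted.
#' @return Logical matrix, one row per record, one column per `sp_id`.
#' @export
sp_indicators <- function(cohort, registry = default_sp_registry(),
                          sum_vas_value = NULL, paindetect_final = NULL) {
  check_registry(registry)
  if (is.null(sum_vas_value)) sum_vas_value <- sum_vas(cohort)
  if (is.null(paindetect_final)) {
    paindetect_final <- paindetect_score(cohort)$paindetect_final
  }
  n <- nrow(cohort)
  as_true <- function(x) !is.na(x) & x
  ind <- vapply(seq_len(nrow(registry)), function(i) {
    rule <- registry[i, ]
    switch(rule$kind,
           bool_item = as_true(cohort[[rule$item_id]]),
           nrs_gt = as_true(cohort[[rule$item_id]] > rule$threshold),
           timing_before_during =
             as_true(cohort$pain_before_menses) &
             as_true(cohort$pain_during_menses) &
             !as_true(cohort$pain_after_menses),
           pattern_eq = as_true(cohort$course_pattern == rule$pattern),
           pd_final_gt = as_true(paindetect_final > rule$threshold),
           sum_vas_gt = as_true(sum_vas_value > rule$threshold))
  }, logical(n))
  ind <- matrix(ind, nrow = n,
                dimnames = list(NULL, registry$sp_id))
  ind
}

#' Count the significant parameters
#'
#' @param indicators Logical matrix from [sp_indicators()] (34 columns for
#'   the default registry).
#' @param registry Registry the indicators were computed from; used to
#'   check the column set.
#' @return Integer vector of per-patient SP counts.
#' @export
sum_sp <- function(indicators, registry = default_sp_registry()) {
  if (!identical(colnames(indicators), registry$sp_id)) {
    stop("indicator columns do not match the registry sp_ids")
  }
  as.integer(rowSums(indicators))
}

#' Score a cohort
#'
#' Convenience wrapper computing every derived per-patient quantity:
#' pain-intensity sum, PainDETECT final score and band, the SP indicator
#' vector, and the SP count.
#'
#' @inheritParams sp_indicators
#' @inheritParams sum_vas
#' @return Data frame with `patient_id`, `label`, `sum_vas`,
#'   `sum_vas_variant`, `paindetect_final`, `paindetect_band`, `sum_sp`,
#'   and one logical column `sp.<sp_id>` per registry rule.
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_spec(seed = 1))
#' sc <- score_cohort(coh)
#' tapply(sc$sum_sp, sc$label, mean)
score_cohort <- function(cohort, registry = default_sp_registry(),
                         variant = c("eight_item", "five_item")) {
  variant <- match.arg(variant)
  sv <- sum_vas(cohort, variant)
  pd <- paindetect_score(cohort)
  ind <- sp_indicators(cohort, registry, sum_vas_value = sv,
                       paindetect_final = pd$paindetect_final)
  out <- data.frame(patient_id = cohort$patient_id,
                    label = cohort$label,
                    sum_vas = sv,
                    sum_vas_variant = variant,
                    paindetect_final = pd$paindetect_final,
                    paindetect_band = pd$paindetect_band,
                    sum_sp = sum_sp(ind, registry),
                    stringsAsFactors = FALSE)
  colnames(ind) <- paste0("sp.", colnames(ind))
  cbind(out, as.data.frame(ind))
}
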