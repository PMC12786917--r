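#' The default significant-parameter (SP) registry
#'
#' The SP count is the number of group-discriminating binary indicators a
#' patient triggers. The default registry holds the 34 rules of the
#' reference analysis: 33 record-level dichotomisations (symptom booleans,
#' NRS thresholds, a menstrual-timing category, pain adjectives, pain
#' locations, pain-course patterns, and a PainDETECT final-score threshold)
#' plus one score-level rule on the pain-intensity sum (rule 34,
#' `sum_vas > 8.5`; a printed cut-off of 8.5 means "greater than 8.5",
#' i.e. at least 9 for integer scores). Missing answers never trigger a
#' rule.
#'
#' Rule kinds:
#' \describe{
#'   \item{bool_item}{`item_id` is `TRUE`.}
#'   \item{nrs_gt}{`item_id` strictly greater than `threshold`.}
#'   \item{timing_before_during}{period pain before and during (but not
#'     after) menses — the menstrual-timing category of the timing
#'     question, reconstructed from the three timing booleans.}
#'   \item{pattern_eq}{`course_pattern` equals `pattern`.}
#'   \item{pd_final_gt}{PainDETECT final score strictly greater than
#'     `threshold`.}
#'   \item{sum_vas_gt}{pain-intensity sum strictly greater than
#'     `threshold` (the only score-level rule).}
#' }
#'
#' `ems_yes` / `no_ems_yes` store the per-group counts of rule-positive
#' patients in the reference cohort (n = 119 with endometriosis, n = 109
#' without); they calibrate the synthetic generator and support the
#' expectation identity `E[SP count] = sum of rule prevalences`.
#'
#' @return Data frame with 34 rows and columns `sp_id`, `kind`, `item_id`,
#'   `threshold`, `pattern`, `ems_yes`, `no_ems_yes`.
#' @export
#' @examples
#' reg <- default_sp_registry()
#' sum(reg$ems_yes) / 119   # expected SP count in the disease group
default_sp_registry <- function() {
  r <- function(sp_id, kind, item = NA_character_, thr = NA_real_,
                pat = NA_character_, ems, no_ems) {
    data.frame(sp_id = sp_id, kind = kind, item_id = item, threshold = thr,
               pattern = pat, ems_yes = ems, no_ems_yes = no_ems,
               stringsAsFactors = FALSE)
  }
  reg <- rbind(
    r("analgesic_use", "bool_item", "analgesic_use", ems = 102, no_ems = 40),
    r("dysmenorrhea", "bool_item", "dysmenorrhea", ems = 89, no_ems = 48),
    r("dysmenorrhea_nrs_gt3", "nrs_gt", "dysmenorrhea_nrs", thr = 3,
      ems = 88, no_ems = 37),
    r("menses_before_during", "timing_before_during", ems = 43, no_ems = 16),
    r("cpp", "bool_item", "cpp", ems = 84, no_ems = 15),
    r("dysuria", "bool_item", "dysuria", ems = 42, no_ems = 1),
    r("dyschezia", "bool_item", "dyschezia", ems = 68, no_ems = 14),
    r("dyspareunia", "bool_item", "dyspareunia", ems = 92, no_ems = 31),
    r("obstipation", "bool_item", "obstipation", ems = 51, no_ems = 11),
    r("diarrhea", "bool_item", "diarrhea", ems = 66, no_ems = 26),
    r("adj_cramping", "bool_item", "adj_cramping", ems = 97, no_ems = 43),
    r("adj_tearing", "bool_item", "adj_tearing", ems = 54, no_ems = 14),
    r("adj_pulling", "bool_item", "adj_pulling", ems = 87, no_ems = 35),
    r("adj_stinging", "bool_item", "adj_stinging", ems = 73, no_ems = 29),
    r("adj_pulsatile", "bool_item", "adj_pulsatile", ems = 37, no_ems = 10),
    r("adj_touch_sensitive", "bool_item", "adj_touch_sensitive",
      ems = 55, no_ems = 22),
    r("adj_pressing", "bool_item", "adj_pressing", ems = 58, no_ems = 14),
    r("adj_cold_warmth", "bool_item", "adj_cold_warmth", ems = 19, no_ems = 1),
    r("adj_flashing", "bool_item", "adj_flashing", ems = 67, no_ems = 7),
    r("pain_now", "nrs_gt", "pain_now_nrs", thr = 0, ems = 85, no_ems = 15),
    r("strongest_pain", "nrs_gt", "strongest_4wks_nrs", thr = 0,
      ems = 116, no_ems = 35),
    r("average_pain", "nrs_gt", "average_4wks_nrs", thr = 0,
      ems = 115, no_ems = 28),
    r("loc_lower_abdomen", "bool_item", "loc_lower_abdomen",
      ems = 112, no_ems = 33),
    r("loc_lumbar_spine", "bool_item", "loc_lumbar_spine",
      ems = 75, no_ems = 26),
    r("loc_thighs_legs", "bool_item", "loc_thighs_legs", ems = 52, no_ems = 6),
    r("loc_hips_groins", "bool_item", "loc_hips_groins", ems = 53, no_ems = 8),
    r("loc_upper_abdomen", "bool_item", "loc_upper_abdomen",
      ems = 18, no_ems = 5),
    r("loc_vagina_mons", "bool_item", "loc_vagina_mons", ems = 24, no_ems = 3),
    r("loc_gluteal", "bool_item", "loc_gluteal", ems = 7, no_ems = 0),
    r("pattern_persistent_attacks", "pattern_eq",
      pat = "PERSISTENT_WITH_ATTACKS", ems = 46, no_ems = 8),
    r("pattern_attacks_no_pain", "pattern_eq",
      pat = "ATTACKS_NO_PAIN_BETWEEN", ems = 33, no_ems = 13),
    r("pattern_attacks_with_pain", "pattern_eq",
      pat = "ATTACKS_WITH_PAIN_BETWEEN", ems = 22, no_ems = 5),
    r("paindetect_gt3", "pd_final_gt", thr = 3, ems = 105, no_ems = 26),
    r("sum_vas_gt8.5", "sum_vas_gt", thr = 8.5, ems = 102, no_ems = 23)
  )
  rownames(reg) <- NULL
  reg
}

# internal: sanity checks on a registry object
check_registry <- function(registry) {
  stopifnot(is.data.frame(registry))
  need <- c("sp_id", "kind", "item_id", "threshold", "pattern")
  missing_cols <- setdiff(need, names(registry))
  if (length(missing_cols) > 0) {
    stop("registry is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(registry$sp_id)) stop("registry sp_ids are not unique")
  known <- c("bool_item", "nrs_gt", "timing_before_during", "pattern_eq",
             "pd_final_gt", "sum_vas_gt")
  bad <- setdiff(registry$kind, known)
  if (length(bad) > 0) stop("unknown registry rule kind(s): ",
                            paste(bad, collapse = ", "))
  invisible(registry)
}

#' Read or write an SP registry as JSON
#'
#' @param path File path.
#' @return `read_sp_registry()` returns a registry data frame;
#'   `write_sp_registry()` returns `path` invisibly.
#' @export
read_sp_registry <- function(path) {
  reg <- jsonlite::fromJSON(path)
  for (col in c("ems_yes", "no_ems_yes")) {
    if (!col %in% names(reg)) reg[[col]] <- NA_real_
  }
  check_registry(reg)
  reg
}

#' @rdname read_sp_registry
#' @param registry Registry data frame, see [default_sp_registry()].
#' @export
write_sp_registry <- function(registry, path) {
  check_registry(registry)
  jsonlite::write_json(registry, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
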