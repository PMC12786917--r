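#' Item codebook for the two pain questionnaires
#'
#' The codebook defines every column a cohort file may contain: its
#' identifier, human-readable label, value kind, the summary table it
#' originates from in the reference cohort report, and whether the item
#' feeds at least one significant-parameter (SP) rule of the default
#' registry (see [default_sp_registry()]).
#'
#' Value kinds:
#' \describe{
#'   \item{ID}{opaque string identifier (`patient_id`).}
#'   \item{LABEL}{disease group, one of `EMS` / `NO_EMS`.}
#'   \item{BOOLEAN}{serialised as `0`/`1`; empty cell = missing.}
#'   \item{NRS_0_10}{integer pain numeric rating scale in 0--10.}
#'   \item{SENSORY_0_5}{integer PainDETECT sensory item in 0--5.}
#'   \item{CATEGORICAL}{uppercase token from the item's level set.}
#'   \item{REAL}{non-negative real (demographics).}
#' }
#'
#' @return A data frame with one row per item: `item_id`, `label`,
#'   `value_kind`, `source_table`, `is_significant_parameter`,
#'   `dichotomizer_id` (the SP rule id the item primarily feeds, or `NA`).
#' @export
#' @examples
#' cb <- default_codebook()
#' table(cb$value_kind)
default_codebook <- function() {
  it <- function(id, label, kind, src, sp = NA_character_) {
    data.frame(item_id = id, label = label, value_kind = kind,
               source_table = src,
               is_significant_parameter = !is.na(sp),
               dichotomizer_id = sp,
               stringsAsFactors = FALSE)
  }
  adj <- function(id, label, sp = NA_character_) {
    it(paste0("adj_", id), paste0("Pain described as ", label),
       "BOOLEAN", "sensations", sp)
  }
  loc <- function(id, label, sp) {
    it(paste0("loc_", id), paste0("Pain located at ", label),
       "BOOLEAN", "localization", sp)
  }
  sens <- function(id, label) {
    it(paste0("sens_", id), paste0("Sensory item: ", label),
       "SENSORY_0_5", "paindetect")
  }
  cb <- rbind(
    it("patient_id", "Patient identifier", "ID", "none"),
    it("label", "Disease group (EMS / NO_EMS)", "LABEL", "none"),
    it("age_yrs", "Age in years", "REAL", "demographics"),
    it("bmi", "Body mass index", "REAL", "demographics"),
    it("age_menarche_yrs", "Age at menarche in years", "REAL", "demographics"),
    it("smoker", "Current smoker", "BOOLEAN", "demographics"),
    it("allergies", "Any allergies", "BOOLEAN", "demographics"),
    it("analgesic_use", "Uses analgesics during menstruation", "BOOLEAN",
       "demographics", "analgesic_use"),
    it("contraceptive", "Hormonal contraceptive class", "CATEGORICAL",
       "demographics"),
    it("dysmenorrhea", "Dysmenorrhea (period pain)", "BOOLEAN",
       "classical", "dysmenorrhea"),
    it("dysmenorrhea_nrs", "Dysmenorrhea intensity (NRS)", "NRS_0_10",
       "classical", "dysmenorrhea_nrs_gt3"),
    it("pain_before_menses", "Period pain before menses", "BOOLEAN",
       "classical", "menses_before_during"),
    it("pain_during_menses", "Period pain during menses", "BOOLEAN",
       "classical", "menses_before_during"),
    it("pain_after_menses", "Period pain after menses", "BOOLEAN",
       "classical", "menses_before_during"),
    it("cpp", "Chronic pelvic pain", "BOOLEAN", "classical", "cpp"),
    it("cpp_nrs", "Chronic pelvic pain intensity (NRS)", "NRS_0_10",
       "classical"),
    it("dysuria", "Dysuria (painful urination)", "BOOLEAN", "classical",
       "dysuria"),
    it("dysuria_nrs", "Dysuria intensity (NRS)", "NRS_0_10", "classical"),
    it("dyschezia", "Dyschezia (painful defecation)", "BOOLEAN",
       "classical", "dyschezia"),
    it("dyschezia_nrs", "Dyschezia intensity (NRS)", "NRS_0_10", "classical"),
    it("dyspareunia", "Dyspareunia (painful intercourse)", "BOOLEAN",
       "classical", "dyspareunia"),
    it("dyspareunia_nrs", "Dyspareunia intensity (NRS)", "NRS_0_10",
       "classical"),
    it("obstipation", "Constipation", "BOOLEAN", "classical", "obstipation"),
    it("diarrhea", "Diarrhea", "BOOLEAN", "classical", "diarrhea"),
    adj("cramping", "cramping", "adj_cramping"),
    adj("tearing", "tearing", "adj_tearing"),
    adj("pulling", "pulling", "adj_pulling"),
    adj("stinging", "stinging/stabbing", "adj_stinging"),
    adj("pulsatile", "pulsatile/throbbing", "adj_pulsatile"),
    adj("touch_sensitive", "sensitive to touch", "adj_touch_sensitive"),
    adj("burning", "burning"),
    adj("pressing", "pressing", "adj_pressing"),
    adj("diffuse", "diffuse"),
    adj("cold_warmth", "cold/warmth", "adj_cold_warmth"),
    adj("flashing", "flashing/lightning-like", "adj_flashing"),
    it("pain_now_nrs", "Pain right now (NRS)", "NRS_0_10", "paindetect",
       "pain_now"),
    it("strongest_4wks_nrs", "Strongest pain in last 4 weeks (NRS)",
       "NRS_0_10", "paindetect", "strongest_pain"),
    it("average_4wks_nrs", "Average pain in last 4 weeks (NRS)",
       "NRS_0_10", "paindetect", "average_pain"),
    loc("lower_abdomen", "lower abdomen", "loc_lower_abdomen"),
    loc("lumbar_spine", "lumbar spine / lower back", "loc_lumbar_spine"),
    loc("thighs_legs", "thighs / legs", "loc_thighs_legs"),
    loc("hips_groins", "hips / groins", "loc_hips_groins"),
    loc("upper_abdomen", "upper abdomen", "loc_upper_abdomen"),
    loc("vagina_mons", "vagina / mons pubis", "loc_vagina_mons"),
    loc("gluteal", "gluteal region", "loc_gluteal"),
    it("course_pattern", "Pain course pattern", "CATEGORICAL", "paindetect",
       "pattern_persistent_attacks"),
    it("radiating_pain", "Pain radiating to other body regions", "BOOLEAN",
       "paindetect"),
    sens("burning", "burning sensation"),
    sens("tingling", "tingling or prickling"),
    sens("allodynia", "pain on light touch"),
    sens("attacks", "sudden pain attacks"),
    sens("thermal", "pain on cold or heat"),
    sens("numbness", "numbness"),
    sens("pressure", "pain on slight pressure")
  )
  rownames(cb) <- NULL
  cb
}

#' Level sets for the categorical items
#' @return Named list of character vectors of allowed tokens.
#' @export
codebook_levels <- function() {
  list(
    label = c("EMS", "NO_EMS"),
    contraceptive = c("DNG", "LNG", "DSG", "E_OTHER", "OTHER"),
    course_pattern = c("PERSISTENT_SLIGHT_FLUCT", "PERSISTENT_WITH_ATTACKS",
                       "ATTACKS_NO_PAIN_BETWEEN", "ATTACKS_WITH_PAIN_BETWEEN")
  )
}

#' Read or write a codebook as JSON
#'
#' @param path File path.
#' @return `read_codebook()` returns a codebook data frame;
#'   `write_codebook()` returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  cb <- jsonlite::fromJSON(path)
  required <- c("item_id", "label", "value_kind", "source_table",
                "is_significant_parameter", "dichotomizer_id")
  missing_cols <- setdiff(required, names(cb))
  if (length(missing_cols) > 0) {
    stop("codebook is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cb$item_id)) {
    stop("codebook item_ids are not unique: ",
         paste(unique(cb$item_id[duplicated(cb$item_id)]), collapse = ", "))
  }
  cb[required]
}

#' @rdname read_codebook
#' @param codebook A codebook data frame as returned by [default_codebook()].
#' @export
write_codebook <- function(codebook, path) {
  jsonlite::write_json(codebook, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# internal: item ids by value kind
items_of_kind <- function(codebook, kind) {
  codebook$item_id[codebook$value_kind %in% kind]
}
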