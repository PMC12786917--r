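#' Simulate a cohort and write it to disk
#'
#' Wraps [generate_cohort()] and [write_cohort()]; alongside the cohort
#' file a JSON manifest is written (seed, group sizes, copula
#' correlation, package version) so the run can be reproduced exactly.
#'
#' @param path Output cohort file.
#' @param n_ems,n_no_ems,copula_rho,seed Passed to [default_cohort_spec()].
#' @param sep Field delimiter (`","` or `"\t"`).
#' @return The generated cohort, invisibly.
#' @export
cmd_simulate <- function(path, n_ems = 119, n_no_ems = 109,
                         copula_rho = 0.3, seed = 1, sep = ",") {
  spec <- default_cohort_spec(n_ems = n_ems, n_no_ems = n_no_ems,
                              copula_rho = copula_rho, seed = seed)
  coh <- generate_cohort(spec)
  write_cohort(coh, path, sep = sep)
  write_manifest(paste0(path, ".manifest.json"),
                 list(command = "simulate", n_ems = n_ems,
                      n_no_ems = n_no_ems, copula_rho = copula_rho,
                      seed = seed, rows = nrow(coh)))
  invisible(coh)
}

write_manifest <- function(path, config) {
  config$package <- "endoscreen"
  config$version <- as.character(utils::packageVersion("endoscreen"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Score a cohort file
#'
#' Reads a cohort, computes all derived scores, and writes them as CSV.
#'
#' @param input Cohort file path.
#' @param output Output CSV path.
#' @inheritParams score_cohort
#' @param sep Field delimiter of the input file.
#' @return The score data frame, invisibly.
#' @export
cmd_score <- function(input, output, registry = default_sp_registry(),
                      variant = "eight_item", sep = ",") {
  coh <- read_cohort(input, sep = sep)
  sc <- score_cohort(coh, registry, variant)
  utils::write.csv(sc, output, row.names = FALSE, quote = FALSE, na = "")
  invisible(sc)
}

#' Per-item analysis tables for a labeled cohort
#'
#' Reproduces the layout of a case-control questionnaire analysis: one
#' row per SP rule with the group-wise negative/positive counts, the
#' observed fractions, missing-data counts, and Fisher's exact p-value;
#' one row per NRS item with group means/SDs and the Mann-Whitney
#' p-value; and a score summary block (pain-intensity sum and SP count:
#' group means/SDs, cut-off contingency rows, and the full accuracy
#' panel at the registry cut-offs).
#'
#' @param cohort Labeled cohort data frame.
#' @inheritParams score_cohort
#' @param out_dir Optional directory; when given, `items.csv`,
#'   `nrs.csv`, `summary.csv` and a field-identical `tables.json` plus a
#'   manifest are written there.
#' @param seed Seed recorded in the manifest (no randomness is used).
#' @return List with data frames `items`, `nrs`, and `summary`.
#' @export
cmd_tables <- function(cohort, registry = default_sp_registry(),
                       variant = "eight_item", out_dir = NULL, seed = NULL) {
  if (anyNA(cohort$label)) stop("cohort must be fully labeled")
  sc <- score_cohort(cohort, registry, variant)

  items <- do.call(rbind, lapply(registry$sp_id, function(id) {
    ct <- contingency_from_indicator(cohort, id, registry)
    tb <- ct$table
    p <- fisher_exact(tb)$p_value
    data.frame(item_id = id,
               no_ems_no = tb[["tn"]], no_ems_yes = tb[["fp"]],
               ems_no = tb[["fn"]], ems_yes = tb[["tp"]],
               no_ems_missing = ct$missing[["NO_EMS"]],
               ems_missing = ct$missing[["EMS"]],
               fisher_p = p, stringsAsFactors = FALSE)
  }))

  nrs_cols <- c("dysmenorrhea_nrs", "cpp_nrs", "dysuria_nrs",
                "dyschezia_nrs", "dyspareunia_nrs", "pain_now_nrs",
                "strongest_4wks_nrs", "average_4wks_nrs")
  ems_sel <- cohort$label == "EMS"
  nrs <- do.call(rbind, lapply(nrs_cols, function(col) {
    a <- cohort[[col]][ems_sel]
    b <- cohort[[col]][!ems_sel]
    a0 <- ifelse(is.na(a), 0, a)
    b0 <- ifelse(is.na(b), 0, b)
    p <- if (length(a0) > 0 && length(b0) > 0) {
      mann_whitney(a0, b0)$p_value
    } else NA_real_
    data.frame(item_id = col,
               ems_mean = mean(a0), ems_sd = stats::sd(a0),
               no_ems_mean = mean(b0), no_ems_sd = stats::sd(b0),
               mann_whitney_p = p, stringsAsFactors = FALSE)
  }))

  score_block <- function(score, cutoff, name) {
    pos <- score > cutoff
    tb <- contingency_table(tn = sum(!ems_sel & !pos),
                            fp = sum(!ems_sel & pos),
                            fn = sum(ems_sel & !pos),
                            tp = sum(ems_sel & pos))
    panel <- as.data.frame(diagnostic_summary(tb))
    cbind(data.frame(score = name, cutoff = cutoff,
                     ems_mean = mean(score[ems_sel]),
                     ems_sd = stats::sd(score[ems_sel]),
                     no_ems_mean = mean(score[!ems_sel]),
                     no_ems_sd = stats::sd(score[!ems_sel]),
                     fisher_p = fisher_exact(tb)$p_value,
                     stringsAsFactors = FALSE),
          panel)
  }
  summary <- rbind(score_block(sc$sum_vas, 8.5, "sum_vas"),
                   score_block(sc$sum_sp, 8.5, "sum_sp"))

  out <- list(items = items, nrs = nrs, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(items, file.path(out_dir, "items.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    utils::write.csv(nrs, file.path(out_dir, "nrs.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    jsonlite::write_json(out, file.path(out_dir, "tables.json"),
                         dataframe = "rows", na = "null", digits = NA,
                         pretty = TRUE)
    write_manifest(file.path(out_dir, "manifest.json"),
                   list(command = "tables", variant = variant,
                        rows = nrow(cohort), seed = seed))
  }
  out
}

#' Classify a labeled cohort and report the accuracy panel
#'
#' @param cohort Labeled cohort data frame.
#' @inheritParams classify
#' @param out_dir Optional output directory (`predictions.csv`,
#'   `panel.csv`, manifest).
#' @param seed Seed recorded in the manifest (no randomness is used).
#' @return List with `predictions` (patient_id, label, predicted),
#'   `table` (the confusion [contingency_table()]), and `summary`
#'   (the [diagnostic_summary()]).
#' @export
cmd_classify <- function(cohort, tree = default_tree(),
                         registry = default_sp_registry(),
                         variant = "eight_item", out_dir = NULL,
                         seed = NULL) {
  scores <- score_cohort(cohort, registry, variant)
  pred <- classify(cohort, tree, registry, variant, scores = scores)
  tb <- evaluate_tree(cohort, tree, registry, variant, scores = scores)
  summ <- diagnostic_summary(tb)
  predictions <- data.frame(patient_id = cohort$patient_id,
                            label = cohort$label, predicted = pred,
                            sum_sp = scores$sum_sp,
                            sum_vas = scores$sum_vas,
                            stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    utils::write.csv(as.data.frame(summ), file.path(out_dir, "panel.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    write_manifest(file.path(out_dir, "manifest.json"),
                   list(command = "classify", variant = variant,
                        rows = nrow(cohort), seed = seed))
  }
  list(predictions = predictions, table = tb, summary = summ)
}

#' Accuracy panel from bare 2x2 counts ("replay" mode)
#'
#' Computes the full diagnostic panel directly from published confusion
#' counts, without any cohort — useful to re-derive every reported
#' accuracy metric from a printed table.
#'
#' @inheritParams contingency_table
#' @return A [diagnostic_summary()].
#' @export
#' @examples
#' replay_summary(100, 9, 9, 110)
replay_summary <- function(tn, fp, fn, tp) {
  diagnostic_summary(contingency_table(tn, fp, fn, tp))
}
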