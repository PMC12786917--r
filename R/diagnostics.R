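#' 2x2 contingency table for a diagnostic test
#'
#' Fixed orientation throughout the package: rows are the true condition
#' (first row `NO_EMS`, second row `EMS`), columns the test result (first
#' column negative, second positive). The cells are therefore `tn`, `fp`
#' (first row) and `fn`, `tp` (second row).
#'
#' @param tn,fp,fn,tp Non-negative integer cell counts.
#' @return An object of class `endoscreen_ct` (a named integer vector).
#' @export
#' @examples
#' contingency_table(100, 9, 9, 110)
contingency_table <- function(tn, fp, fn, tp) {
  cells <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers")
  }
  structure(as.integer(cells), names = names(cells),
            class = "endoscreen_ct")
}

#' @export
print.endoscreen_ct <- function(x, ...) {
  m <- matrix(x[c("tn", "fp", "fn", "tp")], 2, 2, byrow = TRUE,
              dimnames = list(truth = c("NO_EMS", "EMS"),
                              test = c("negative", "positive")))
  print(m)
  invisible(x)
}

as_ct_matrix <- function(table) {
  matrix(table[c("tn", "fp", "fn", "tp")], 2, 2, byrow = TRUE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test. The two-sided p-value follows the
#' point-probability definition: the sum of the probabilities of all
#' tables (with the observed margins) whose point probability does not
#' exceed that of the observed table. A table with a zero margin carries
#' no information and returns p = 1 with a method note.
#'
#' @param table A [contingency_table()].
#' @param alternative `"two_sided"` (default), `"less"`, or `"greater"`.
#' @return List of class `endoscreen_test` with `statistic` (sample odds
#'   ratio), `p_value`, and `method`.
#' @export
#' @examples
#' fisher_exact(contingency_table(108, 1, 77, 42))$p_value  # << 0.001
fisher_exact <- function(table, alternative = c("two_sided", "less",
                                                "greater")) {
  alternative <- match.arg(alternative)
  m <- as_ct_matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(structure(list(statistic = NA_real_, p_value = 1,
                          method = "Fisher's exact test (degenerate margin)"),
                     class = "endoscreen_test"))
  }
  ft <- stats::fisher.test(m, alternative = switch(alternative,
                                                   two_sided = "two.sided",
                                                   less = "less",
                                                   greater = "greater"))
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  structure(list(statistic = or, p_value = ft$p.value,
                 method = "Fisher's exact test"),
            class = "endoscreen_test")
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration when both samples have at most 8 observations and no
#' ties are present; otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List of class `endoscreen_test` with `statistic` (the U
#'   statistic for `group_a`), `p_value`, and `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- length(group_a) <= 8 && length(group_b) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = !exact))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) {
                   "Mann-Whitney U test (exact)"
                 } else {
                   "Mann-Whitney U test (normal approximation, tie-corrected)"
                 }),
            class = "endoscreen_test")
}

#' @export
print.endoscreen_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format.pval(x$p_value), "\n")
  invisible(x)
}

# internal: Wilson score interval for x successes out of n
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# internal: log-method (Woolf-type) CI for a ratio estimate
log_ci <- function(est, se_log, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(lower = exp(log(est) - z * se_log), upper = exp(log(est) + z * se_log))
}

#' Diagnostic-accuracy panel for a 2x2 table
#'
#' Point estimates and 95% confidence intervals for the standard accuracy
#' metrics of a binary test against disease status:
#' sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive values, accuracy, the likelihood ratios
#' `LR+ = sens/(1-spec)` and `LR- = (1-sens)/spec`, the diagnostic odds
#' ratio `DOR = LR+/LR- = (tp*tn)/(fp*fn)`, and the relative risk of
#' disease given a positive versus a negative test, `RR = PPV/(1-NPV)`.
#' Proportion intervals use the Wilson score method; ratio intervals use
#' the log (Woolf-type) method. When any cell is zero, the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied to the
#' ratio estimates only, and the result is flagged via `correction`.
#'
#' @param table A [contingency_table()] with a positive total.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `endoscreen_summary`: a list with one element
#'   per metric, each `c(estimate, lower, upper)`, plus `correction`
#'   (logical) and `table`.
#' @export
#' @examples
#' s <- diagnostic_summary(contingency_table(100, 9, 9, 110))
#' round(s$sensitivity["estimate"], 3)  # 0.924
#' round(s$dor["estimate"], 1)          # 135.8
diagnostic_summary <- function(table, conf = 0.95) {
  m <- table[c("tn", "fp", "fn", "tp")]
  total <- sum(m)
  if (total == 0) stop("table total must be positive")
  tn <- m[["tn"]]; fp <- m[["fp"]]; fn <- m[["fn"]]; tp <- m[["tp"]]

  prop <- function(x, n) {
    if (n == 0) return(c(estimate = NA_real_, lower = NA_real_,
                         upper = NA_real_))
    c(estimate = x / n, wilson_ci(x, n, conf))
  }
  out <- list(
    sensitivity = prop(tp, tp + fn),
    specificity = prop(tn, tn + fp),
    ppv = prop(tp, tp + fp),
    npv = prop(tn, tn + fn),
    accuracy = prop(tp + tn, total)
  )

  correction <- any(m == 0)
  k <- if (correction) 0.5 else 0
  tn2 <- tn + k; fp2 <- fp + k; fn2 <- fn + k; tp2 <- tp + k
  sens2 <- tp2 / (tp2 + fn2); spec2 <- tn2 / (tn2 + fp2)
  ppv2 <- tp2 / (tp2 + fp2); npv2 <- tn2 / (tn2 + fn2)

  lr_pos <- sens2 / (1 - spec2)
  lr_neg <- (1 - sens2) / spec2
  dor <- (tp2 * tn2) / (fp2 * fn2)
  rr <- ppv2 / (1 - npv2)

  se_lr_pos <- sqrt(1 / tp2 - 1 / (tp2 + fn2) + 1 / fp2 - 1 / (fp2 + tn2))
  se_lr_neg <- sqrt(1 / fn2 - 1 / (tp2 + fn2) + 1 / tn2 - 1 / (fp2 + tn2))
  se_dor <- sqrt(1 / tp2 + 1 / fp2 + 1 / fn2 + 1 / tn2)
  se_rr <- sqrt(1 / tp2 - 1 / (tp2 + fp2) + 1 / fn2 - 1 / (fn2 + tn2))

  out$lr_pos <- c(estimate = lr_pos, log_ci(lr_pos, se_lr_pos, conf))
  out$lr_neg <- c(estimate = lr_neg, log_ci(lr_neg, se_lr_neg, conf))
  out$odds_ratio <- c(estimate = dor, log_ci(dor, se_dor, conf))
  out$relative_risk <- c(estimate = rr, log_ci(rr, se_rr, conf))
  out$correction <- correction
  out$table <- table
  class(out) <- "endoscreen_summary"
  out
}

#' @export
print.endoscreen_summary <- function(x, digits = 3, ...) {
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "accuracy",
               "lr_pos", "lr_neg", "odds_ratio", "relative_risk")
  cat("Diagnostic accuracy (",
      paste(names(x$table), x$table, sep = "=", collapse = ", "), ")\n",
      sep = "")
  if (x$correction) {
    cat("  [Haldane-Anscombe +0.5 applied to ratio estimates]\n")
  }
  for (mname in metrics) {
    v <- x[[mname]]
    cat(sprintf("  %-14s %s (%s-%s)\n", mname,
                format(round(v[["estimate"]], digits)),
                format(round(v[["lower"]], digits)),
                format(round(v[["upper"]], digits))))
  }
  invisible(x)
}

#' Turn a diagnostic summary into a one-row data frame
#'
#' @param x An `endoscreen_summary`.
#' @param ... Unused.
#' @return Data frame with `<metric>`, `<metric>_lower`, `<metric>_upper`
#'   columns and the four cell counts.
#' @export
as.data.frame.endoscreen_summary <- function(x, ...) {
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "accuracy",
               "lr_pos", "lr_neg", "odds_ratio", "relative_risk")
  vals <- unlist(lapply(metrics, function(mname) {
    v <- x[[mname]]
    stats::setNames(v[c("estimate", "lower", "upper")],
                    c(mname, paste0(mname, "_lower"), paste0(mname, "_upper")))
  }))
  cbind(as.data.frame(as.list(vals)),
        as.data.frame(as.list(stats::setNames(as.integer(x$table),
                                              names(x$table)))),
        correction = x$correction)
}

#' ROC analysis with Youden-optimal cut-off
#'
#' The AUC is computed with the rank (Mann-Whitney) formula with ties
#' counted as one half, and its confidence interval with the
#' Hanley-McNeil standard error. The best cut-off maximises Youden's
#' J = sensitivity + specificity - 1 over thresholds placed midway
#' between adjacent distinct observed values (a value above the cut-off
#' is test-positive); ties in J are resolved toward the higher
#' specificity (the larger cut-off).
#'
#' @param scores Numeric vector.
#' @param labels Vector with both classes present; `positive` marks the
#'   disease class.
#' @param positive Label value treated as diseased (default `"EMS"`).
#' @param conf Confidence level for the AUC interval.
#' @return List of class `endoscreen_roc`: `auc`, `auc_ci`, `best_cutoff`,
#'   `youden_j`, `sensitivity`, `specificity` (at the best cut-off), `n_pos`,
#'   `n_neg`.
#' @export
#' @examples
#' roc_cutoff(c(1, 2, 8, 9), c("NO_EMS", "NO_EMS", "EMS", "EMS"))
roc_cutoff <- function(scores, labels, positive = "EMS", conf = 0.95) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present for ROC analysis")
  }
  rk <- rank(scores)
  auc <- (sum(rk[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))

  uniq <- sort(unique(scores))
  cuts <- if (length(uniq) > 1) (uniq[-1] + uniq[-length(uniq)]) / 2 else
    uniq
  sens <- vapply(cuts, function(ct) mean(scores[pos] > ct), numeric(1))
  spec <- vapply(cuts, function(ct) mean(scores[!pos] <= ct), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(spec[best])]

  structure(list(auc = auc, auc_ci = ci, best_cutoff = cuts[best],
                 youden_j = j[best], sensitivity = sens[best],
                 specificity = spec[best], n_pos = n_pos, n_neg = n_neg),
            class = "endoscreen_roc")
}

#' @export
print.endoscreen_roc <- function(x, digits = 3, ...) {
  cat(sprintf("ROC: AUC %s (%s-%s), best cutoff %s (J = %s)\n",
              format(round(x$auc, digits)),
              format(round(x$auc_ci[["lower"]], digits)),
              format(round(x$auc_ci[["upper"]], digits)),
              format(x$best_cutoff), format(round(x$youden_j, digits))))
  invisible(x)
}

#' Per-item contingency table from a labeled cohort
#'
#' Builds the group-by-indicator 2x2 table for a codebook item, a
#' registry rule, or a tree predicate, with missing answers counted as
#' indicator-negative (and reported separately).
#'
#' @inheritParams sp_indicators
#' @param indicator Either an `sp_id` from `registry`, an item id of a
#'   boolean codebook item, or a predicate list as in tree documents.
#' @return List with `table` (a [contingency_table()] where "positive"
#'   means indicator true and "condition" the EMS group) and
#'   `missing` (named count of missing answers per group, raw items only).
#' @export
contingency_from_indicator <- function(cohort, indicator,
                                       registry = default_sp_registry()) {
  if (anyNA(cohort$label)) stop("cohort must be fully labeled")
  miss <- c(NO_EMS = 0L, EMS = 0L)
  if (is.list(indicator)) {
    scores <- score_cohort(cohort, registry)
    v <- eval_predicate(indicator, cohort, scores)
  } else if (indicator %in% registry$sp_id) {
    ind <- sp_indicators(cohort, registry)
    v <- ind[, indicator]
    rule <- registry[registry$sp_id == indicator, ]
    if (!is.na(rule$item_id) && rule$item_id %in% names(cohort)) {
      na_raw <- is.na(cohort[[rule$item_id]])
      miss <- c(NO_EMS = sum(na_raw & cohort$label == "NO_EMS"),
                EMS = sum(na_raw & cohort$label == "EMS"))
    }
  } else if (indicator %in% names(cohort)) {
    x <- cohort[[indicator]]
    v <- !is.na(x) & x
    miss <- c(NO_EMS = sum(is.na(x) & cohort$label == "NO_EMS"),
              EMS = sum(is.na(x) & cohort$label == "EMS"))
  } else {
    stop("unknown indicator '", indicator, "'")
  }
  ems <- cohort$label == "EMS"
  list(table = contingency_table(tn = sum(!ems & !v), fp = sum(!ems & v),
                                 fn = sum(ems & !v), tp = sum(ems & v)),
       missing = miss)
}
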