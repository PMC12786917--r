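# brute-force hypergeometric oracle for the two-sided Fisher p-value:
# enumerate every table with the observed margins, sum the probabilities
# of those no more probable than the observed table
fisher_oracle <- function(tn, fp, fn, tp) {
  r1 <- tn + fp
  c1 <- tn + fn
  n <- tn + fp + fn + tp
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tn, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("two-sided Fisher p matches full enumeration on small tables", {
  expect_equal(fisher_exact(contingency_table(5, 5, 5, 5))$p_value, 1)
  t1 <- contingency_table(2, 3, 4, 1)
  expect_equal(fisher_exact(t1)$p_value, fisher_oracle(2, 3, 4, 1),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:200) {
    cells <- as.integer(stats::rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    got <- fisher_exact(do.call(contingency_table, as.list(cells)))$p_value
    want <- fisher_oracle(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("Fisher p is invariant under transposition and row+column swap", {
  set.seed(6)
  for (i in 1:50) {
    cells <- as.integer(stats::rmultinom(1, 30, c(0.4, 0.2, 0.2, 0.2)))
    tn <- cells[1]; fp <- cells[2]; fn <- cells[3]; tp <- cells[4]
    p <- fisher_exact(contingency_table(tn, fp, fn, tp))$p_value
    p_t <- fisher_exact(contingency_table(tn, fn, fp, tp))$p_value
    p_s <- fisher_exact(contingency_table(tp, fn, fp, tn))$p_value
    expect_equal(p, p_t, tolerance = 1e-12)
    expect_equal(p, p_s, tolerance = 1e-12)
  }
})

test_that("a strongly discriminating symptom table is highly significant", {
  # dysuria: 1/109 controls vs 42/119 cases
  expect_lt(fisher_exact(contingency_table(108, 1, 77, 42))$p_value, 0.001)
  # degenerate margin carries no information
  res <- fisher_exact(contingency_table(0, 0, 5, 5))
  expect_equal(res$p_value, 1)
  expect_match(res$method, "degenerate")
  expect_error(contingency_table(-1, 2, 3, 4), "non-negative")
})

test_that("accuracy-panel identities hold over random tables", {
  set.seed(8)
  for (i in 1:1000) {
    cells <- as.integer(stats::rmultinom(1, sample(10:200, 1),
                                         rep(0.25, 4))) + 1L
    tb <- do.call(contingency_table, as.list(cells))
    s <- diagnostic_summary(tb)
    tn <- cells[1]; fp <- cells[2]; fn <- cells[3]; tp <- cells[4]
    expect_equal(s$odds_ratio[["estimate"]], (tp * tn) / (fp * fn),
                 tolerance = 1e-12)
    expect_equal(s$odds_ratio[["estimate"]],
                 s$lr_pos[["estimate"]] / s$lr_neg[["estimate"]],
                 tolerance = 1e-9)
    expect_equal(s$relative_risk[["estimate"]],
                 s$ppv[["estimate"]] / (1 - s$npv[["estimate"]]),
                 tolerance = 1e-12)
    expect_equal(s$accuracy[["estimate"]], (tp + tn) / sum(cells),
                 tolerance = 1e-12)
    for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
      expect_true(s[[m]][["lower"]] <= s[[m]][["estimate"]] &&
                    s[[m]][["estimate"]] <= s[[m]][["upper"]])
    }
  }
})

test_that("a zero cell triggers the half-count correction, flagged", {
  s <- diagnostic_summary(contingency_table(10, 0, 0, 10))
  expect_true(s$correction)
  expect_equal(s$odds_ratio[["estimate"]], (10.5 * 10.5) / (0.5 * 0.5))
  expect_equal(s$sensitivity[["estimate"]], 1)  # proportions uncorrected
})

test_that("rank-sum test matches exact enumeration and handles ties", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  # permutation oracle: 6 equally likely rank assignments, the observed
  # split is one of the two most extreme -> two-sided p = 2/6
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_match(r$method, "exact")

  r2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r2$statistic), 4.5)
  expect_gt(r2$p_value, 0.9)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("widely separated pain-intensity groups are detected across seeds", {
  # chronic pelvic pain moments: 0.78 (2.2) controls vs 4.5 (3.6) cases
  hits <- 0
  for (seed in 1:30) {
    set.seed(seed)
    a <- pmin(pmax(round(stats::rnorm(119, 4.5, 3.6)), 0), 10)
    b <- pmin(pmax(round(stats::rnorm(109, 0.78, 2.2)), 0), 10)
    if (mann_whitney(a, b)$p_value < 0.001) hits <- hits + 1
  }
  expect_equal(hits, 30)
})

test_that("AUC equals brute-force pair counting and pROC agrees", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    scores <- sample(0:15, n, replace = TRUE)
    labels <- sample(c("EMS", "NO_EMS"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    r <- roc_cutoff(scores, labels)
    pos <- scores[labels == "EMS"]
    neg <- scores[labels == "NO_EMS"]
    pairs <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(pairs), tolerance = 1e-12)
  }
  pr <- pROC::roc(response = c(0, 0, 1, 1, 0, 1, 1),
                  predictor = c(1, 4, 3, 6, 2, 7, 7), quiet = TRUE)
  r <- roc_cutoff(c(1, 4, 3, 6, 2, 7, 7),
                  c("NO_EMS", "NO_EMS", "EMS", "EMS", "NO_EMS", "EMS",
                    "EMS"))
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("the Youden cut-off sits midway between observed values", {
  r <- roc_cutoff(c(1, 2, 8, 9), c("NO_EMS", "NO_EMS", "EMS", "EMS"))
  expect_equal(r$auc, 1)
  expect_equal(r$best_cutoff, 5)
  expect_equal(r$youden_j, 1)
  # ties in J resolve toward the higher specificity (larger cut-off)
  r2 <- roc_cutoff(c(1, 2, 3, 4), c("NO_EMS", "EMS", "NO_EMS", "EMS"))
  all_j <- sapply(c(1.5, 2.5, 3.5), function(ct) {
    mean(c(2, 4) > ct) + mean(c(1, 3) <= ct) - 1
  })
  expect_equal(r2$best_cutoff, c(1.5, 2.5, 3.5)[max(which(all_j == max(all_j)))])
  expect_error(roc_cutoff(1:5, rep("EMS", 5)), "both classes")
})

test_that("per-item contingency counts respect groups and missing answers", {
  coh <- empty_cohort(5)
  coh$patient_id <- letters[1:5]
  coh$label <- c("EMS", "EMS", "EMS", "NO_EMS", "NO_EMS")
  coh$dysuria <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  out <- contingency_from_indicator(coh, "dysuria")
  expect_equal(as.integer(out$table), c(2L, 0L, 0L, 3L))
  expect_equal(sum(out$missing), 0)

  coh$dysuria[2] <- NA
  out <- contingency_from_indicator(coh, "dysuria")
  expect_equal(out$table[["tp"]], 2L)   # missing counted as indicator-false
  expect_equal(out$table[["fn"]], 1L)
  expect_equal(out$missing[["EMS"]], 1L)
  expect_error(contingency_from_indicator(coh, "nonexistent"), "unknown")
})
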