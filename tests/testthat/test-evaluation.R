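# brute-force AUC oracle: average over all positive-negative pairs,
# ties counting one half
auc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

test_that("confusion tables binarize by stratum and conserve totals", {
  ct <- confusion_for_stratum(c("HSIL+", "LSIL", "NILM"),
                              c("HSIL+", "NILM", "LSIL"), "ASC-US+")
  expect_equal(ct[c("tp", "fp", "fn", "tn")],
               list(tp = 1, fp = 1, fn = 1, tn = 0))
  perfect <- confusion_for_stratum(c("HSIL+", "NILM"), c("HSIL+", "NILM"),
                                   "HSIL+")
  expect_equal(perfect$fp + perfect$fn, 0)
  all_n <- confusion_for_stratum(rep("NILM", 4), rep("NILM", 4), "LSIL+")
  expect_equal(all_n$tn, 4)
  expect_error(confusion_for_stratum("NILM", c("NILM", "LSIL"), "LSIL+"),
               "equal-length")
})

test_that("diagnostic metrics match hand arithmetic with exact CIs", {
  ct <- confusion_from_calls(c(rep(TRUE, 15), FALSE, FALSE, FALSE),
                             c(rep(TRUE, 16), FALSE, FALSE))
  rep <- diagnostic_metrics(ct)
  expect_equal(round(rep$sensitivity$estimate, 3), 0.938) # 15/16
  expect_equal(rep$accuracy$estimate, (15 + 2) / 18)
  # identity acc * n = tp + tn
  expect_equal(rep$accuracy$estimate * ct$n, ct$tp + ct$tn)
  # every point estimate inside its CI
  for (nm in c("sensitivity", "specificity", "accuracy", "ppv", "npv")) {
    m <- rep[[nm]]
    expect_gte(m$estimate, m$lower)
    expect_lte(m$estimate, m$upper)
  }
  # perfect 2x2
  rep1 <- diagnostic_metrics(confusion_from_calls(c(TRUE, FALSE),
                                                  c(TRUE, FALSE)))
  expect_equal(rep1$sensitivity$estimate, 1)
  expect_equal(rep1$npv$estimate, 1)
  # zero denominator -> undefined, not zero
  rep_nd <- diagnostic_metrics(confusion_from_calls(c(FALSE, FALSE),
                                                    c(FALSE, FALSE)))
  expect_true(is.na(rep_nd$sensitivity$estimate))
  expect_equal(rep_nd$specificity$estimate, 1)
})

test_that("Clopper-Pearson hits the exact boundaries", {
  expect_equal(unname(clopper_pearson(0, 20)[1]), 0)
  expect_equal(unname(clopper_pearson(20, 20)[2]), 1)
  # all-successes interval is asymmetric: lower = 0.025^(1/n), upper = 1
  ci <- clopper_pearson(29, 29)
  expect_equal(unname(ci[2]), 1)
  expect_equal(unname(round(ci[1], 3)), 0.881)
  expect_error(clopper_pearson(5, 0), "n > 0")
})

test_that("prevalence-weighted identities reproduce printed arithmetic", {
  m <- prevalence_weighted_metrics(0.946, 0.890, 0.04)
  expect_equal(round(m$accuracy, 3), 0.892)
  expect_equal(round(m$npv, 3), 0.997)
  m0 <- prevalence_weighted_metrics(0.7, 0.9, 0)
  expect_equal(m0$accuracy, 0.9)
  expect_equal(m0$npv, 1)
})

test_that("roc_auc matches the rank formulation and the pair oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10), c(F, F, T, T), n_boot = 5)$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), c(T, T, F, F, F, T), n_boot = 5)$auc,
               0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(F, F, T, T),
                       n_boot = 5)$auc, 0.75)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both")
  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE) # force ties
    expect_equal(roc_auc(scores, labels, n_boot = 2)$auc,
                 auc_pairs(scores, labels), tolerance = 1e-12)
  }
  # bootstrap CI is seeded and brackets the point estimate
  set.seed(1)
  sc <- c(runif(40, 0, 0.7), runif(25, 0.3, 1))
  lb <- rep(c(FALSE, TRUE), c(40, 25))
  r1 <- roc_auc(sc, lb, n_boot = 200, seed = 5)
  r2 <- roc_auc(sc, lb, n_boot = 200, seed = 5)
  expect_identical(r1, r2)
  expect_lte(r1$lower, r1$auc)
  expect_gte(r1$upper, r1$auc)
})

test_that("roc_curve spans (0,0) to (1,1) monotonically", {
  set.seed(2)
  sc <- runif(50)
  lb <- sc + rnorm(50, 0, 0.3) > 0.5
  rc <- roc_curve(sc, lb)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("chi-squared comparison matches the direct formula", {
  same <- compare_proportions_chi2(10, 100, 20, 200)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # direct Sum (O-E)^2 / E oracle on [[10,90],[50,50]]
  O <- rbind(c(10, 90), c(50, 50))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  res <- compare_proportions_chi2(10, 100, 50, 100)
  expect_equal(res$chi2, sum((O - E)^2 / E))
  # significance flag consistent with the chi2(1) critical value
  set.seed(3)
  for (i in 1:50) {
    a <- sample(1:29, 1); b <- sample(1:29, 1)
    r <- compare_proportions_chi2(a, 30, b, 30)
    expect_equal(r$significant, r$chi2 > qchisq(0.95, 1))
  }
  expect_error(compare_proportions_chi2(0, 10, 0, 10), "margin")
})

test_that("sensitivity differences are reported in percentage points", {
  expect_equal(sensitivity_difference(1.000, 0.867), 13.3)
  expect_equal(sensitivity_difference(0.5, 0.75), -25.0)
  a <- diagnostic_metrics(confusion_from_calls(c(TRUE, TRUE), c(TRUE, TRUE)))
  expect_equal(sensitivity_difference(a, a), 0)
})
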