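test_that("AUC follows the rank construction with the ties convention", {
  # perfectly separating scores
  expect_equal(roc_auc(c(1, 2, 9, 10), c(0, 0, 1, 1))$auc, 1)
  # pos {3,5}, neg {1,4}: 3 of 4 pairs concordant
  expect_equal(roc_auc(c(3, 5, 1, 4), c(1, 1, 0, 0))$auc, 3 / 4)
  # all scores identical: every pair ties at one half
  expect_equal(roc_auc(rep(2, 10), rep(0:1, 5))$auc, 0.5)
  # exhaustive pair-counting oracle on random tied data
  set.seed(9)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    scores <- sample(1:12, n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_oracle(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both outcome classes")
})

test_that("the ROC staircase is monotone and the AUC sits in its CI", {
  set.seed(2)
  scores <- rnorm(300) + rep(c(0, 1), each = 150)
  labels <- rep(0:1, each = 150)
  r <- roc_auc(scores, labels)
  expect_true(all(diff(r$roc$sensitivity) <= 0))
  expect_true(all(diff(r$roc$specificity) >= 0))
  expect_gte(r$auc, r$ci[1])
  expect_lte(r$auc, r$ci[2])
  expect_true(all(r$ci >= 0 & r$ci <= 1))
})

test_that("AUC, CI and comparison agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- rnorm(200) + rep(c(0, 0.8), each = 100)
  labels <- rep(0:1, each = 100)
  mine <- roc_auc(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$ci, ref_ci[c(1, 3)], tolerance = 1e-9)
  # paired DeLong comparison against pROC on shared subjects
  scores2 <- scores + rnorm(200, sd = 0.6)
  mine2 <- roc_auc(scores2, labels)
  cmp <- compare_auc(mine, mine2, paired = TRUE)
  ref_cmp <- pROC::roc.test(
    ref, pROC::roc(labels, scores2, quiet = TRUE, direction = "<"),
    method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, ref_cmp$p.value, tolerance = 1e-9)
  # unpaired variant against pROC with independent samples
  set.seed(13)
  s3 <- rnorm(150) + rep(c(0, 0.5), each = 75)
  l3 <- rep(0:1, each = 75)
  mine3 <- roc_auc(s3, l3)
  cmp_u <- compare_auc(mine, mine3)
  ref_u <- pROC::roc.test(
    ref, pROC::roc(l3, s3, quiet = TRUE, direction = "<"),
    method = "delong", paired = FALSE)
  # pROC refers the same statistic to a Welch t rather than a normal,
  # so compare the statistic itself
  expect_equal(cmp_u$statistic, unname(ref_u$statistic),
               tolerance = 1e-9)
})

test_that("AUC comparisons are symmetric and self-consistent", {
  set.seed(5)
  a <- roc_auc(rnorm(100), rbinom(100, 1, 0.5))
  b <- roc_auc(rnorm(80) + rep(c(0, 1), each = 40),
               rep(0:1, each = 40))
  ab <- compare_auc(a, b); ba <- compare_auc(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$difference, -ba$difference)
  self <- compare_auc(a, a, paired = TRUE)
  expect_equal(self$difference, 0)
  expect_equal(self$p_value, 1)
  expect_error(compare_auc(a, b, paired = TRUE), "identical participant")
})

test_that("strongly different AUCs are detected with high power", {
  reject <- vapply(1:20, function(s) {
    set.seed(s + 300)
    # generating AUCs near 0.85 and 0.60 via shifted normals
    a <- roc_auc(c(rnorm(150), rnorm(150) + 1.47),
                 rep(0:1, each = 150))
    b <- roc_auc(c(rnorm(150), rnorm(150) + 0.36),
                 rep(0:1, each = 150))
    compare_auc(a, b)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.9)
})

test_that("risk scores respect their predictors and degeneracies", {
  set.seed(30)
  n <- 400
  coh <- data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 40, 70),
                    bmi = rnorm(n, 25, 3), htn = rbinom(n, 1, 0.3),
                    fhdm = rbinom(n, 1, 0.2))
  coh$dm <- rbinom(n, 1, plogis(-6 + 0.1 * coh$age))
  rs <- fit_risk_score(coh)
  # single informative predictor: score monotone in it
  grid <- coh[1:5, ]
  grid$age <- seq(40, 70, length.out = 5)
  expect_true(all(diff(predict(rs, grid)) > 0) ||
                all(diff(predict(rs, grid)) < 0))
  # constant predictor is dropped, fit succeeds
  coh$htn <- 0
  rs2 <- fit_risk_score(coh)
  expect_false("htn" %in% rs2$features)
  expect_true("htn" %in% rs2$dropped)
  # complete separation flagged with a penalised fallback
  sep <- data.frame(sex = rep(0, 60), age = c(runif(30, 40, 50),
                                              runif(30, 60, 70)),
                    bmi = rnorm(60, 25, 1), htn = rep(0, 60),
                    fhdm = rep(0, 60), dm = rep(0:1, each = 30))
  rs3 <- fit_risk_score(sep)
  expect_true(rs3$separation)
  expect_true(all(is.finite(predict(rs3, sep))))
  expect_error(fit_risk_score(transform(coh, dm = 0)), "single outcome")
})

test_that("threshold sweeps are exact finite-sample proportions", {
  fg <- c(4.9, 5.0, 5.2, 5.3, 5.6, 6.0)
  labels <- c(0, 0, 1, 0, 1, 1)
  sw <- threshold_sweep(fg, labels)
  row52 <- sw[abs(sw$threshold - 5.2) < 1e-9, ]
  expect_equal(row52$sensitivity, 3 / 3)
  expect_equal(row52$specificity, 2 / 3)
  row55 <- sw[abs(sw$threshold - 5.5) < 1e-9, ]
  expect_equal(row55$sensitivity, 2 / 3)
  expect_equal(row55$specificity, 1)
  # a threshold below every value: sensitivity 1, specificity 0
  sw0 <- threshold_sweep(fg, labels, grid = 4.0)
  expect_equal(sw0$sensitivity, 1)
  expect_equal(sw0$specificity, 0)
  # monotone in the threshold within each cluster
  set.seed(3)
  fg2 <- rnorm(200, 5.3, 0.4)
  lab2 <- rbinom(200, 1, 0.3)
  cl2 <- rep(1:2, 100)
  sw2 <- threshold_sweep(fg2, lab2, cl2)
  for (cl in 1:2) {
    s <- sw2[sw2$cluster == cl, ]
    expect_true(all(diff(s$sensitivity) <= 0))
    expect_true(all(diff(s$specificity) >= 0))
  }
  # a cluster lacking one class is flagged, not fabricated
  expect_warning(
    sw3 <- threshold_sweep(c(5, 5.4), c(0, 0), c(1, 1)),
    "lacks an outcome class")
  expect_true(all(is.na(sw3$sensitivity)))
})

test_that("a pooled model evaluated per cluster behaves consistently", {
  set.seed(44)
  n <- 900
  coh <- data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 40, 70),
                    bmi = rnorm(n, 25, 3), htn = rbinom(n, 1, 0.3),
                    fhdm = rbinom(n, 1, 0.2))
  coh$dm <- rbinom(n, 1, plogis(-7 + 0.1 * coh$age + 0.08 * coh$bmi))
  one <- rep(1, n)
  res1 <- single_model_cluster_aucs(coh, one)
  # with a single cluster the per-cluster and pooled evaluations agree
  expect_equal(res1[["1"]]$auc, res1$all$auc)
  # a cluster whose outcome ignores the features scores near 1/2
  coh$dm[1:450] <- rbinom(450, 1, 0.3)
  split2 <- rep(1:2, each = 450)
  res2 <- single_model_cluster_aucs(coh, split2)
  expect_lt(abs(res2[["1"]]$auc - 0.5), 3 * sqrt(res2[["1"]]$var))
  # homogeneous data: per-cluster AUCs statistically indistinguishable
  set.seed(45)
  coh$dm <- rbinom(n, 1, plogis(-7 + 0.1 * coh$age + 0.08 * coh$bmi))
  res3 <- single_model_cluster_aucs(coh, rep(1:3, each = 300))
  for (pair in list(c("1", "2"), c("1", "3"), c("2", "3"))) {
    cmp <- compare_auc(res3[[pair[1]]], res3[[pair[2]]])
    expect_gt(cmp$p_value, 0.001)
  }
})

test_that("cluster-specific scores support cross-validated evaluation", {
  set.seed(50)
  coh <- separated_cohort(n_per = 250, seed = 50)
  coh$dm <- rbinom(nrow(coh), 1,
                   plogis(-9 + 0.12 * coh$age + 0.1 * coh$bmi))
  labels <- rep(1:3, each = 250)
  apparent <- cluster_specific_aucs(coh, labels)
  cved <- cluster_specific_aucs(coh, labels, cv_folds = 5)
  expect_named(apparent, c("1", "2", "3"))
  for (cl in c("1", "2", "3")) {
    expect_true(apparent[[cl]]$auc >= 0 && apparent[[cl]]$auc <= 1)
    # CV AUC should not exceed the apparent AUC by much
    expect_lt(cved[[cl]]$auc, apparent[[cl]]$auc + 0.1)
  }
})
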