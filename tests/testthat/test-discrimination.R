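test_that("AUC equals brute-force pair counting, ties worth 1/2", {
  r <- empirical_roc(c(1, 2, 3, 2, 3, 4), c(F, F, F, T, T, T))
  expect_equal(r$auc, 7 / 9)
  expect_equal(empirical_roc(c(1, 2, 3, 4), c(F, F, T, T))$auc, 1.0)
  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    scores <- round(rnorm(n), 1)            # rounding forces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(empirical_roc(scores, labels)$auc,
                 oracle_auc(scores[labels], scores[!labels]))
  }
})

test_that("ROC curve is a valid staircase whose trapezoid area is the AUC", {
  set.seed(5)
  scores <- round(c(rnorm(40, 1), rnorm(40)), 1)
  labels <- rep(c(TRUE, FALSE), each = 40)
  r <- empirical_roc(scores, labels)
  expect_true(all(diff(r$sens) >= 0))       # thresholds descend
  expect_true(all(diff(r$spec) <= 0))
  fpr <- 1 - r$spec
  area <- sum(diff(fpr) * (head(r$sens, -1) + tail(r$sens, -1)) / 2)
  expect_equal(area, r$auc)
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(13)
  scores <- rlnorm(80); labels <- rep(c(TRUE, FALSE), 40)
  a <- empirical_roc(scores, labels)$auc
  expect_equal(empirical_roc(log(scores), labels)$auc, a)
  expect_equal(empirical_roc(scores^3, labels)$auc, a)
})

test_that("identically distributed classes give AUC near 1/2", {
  set.seed(19)
  scores <- rnorm(4000)
  labels <- rep(c(TRUE, FALSE), 2000)
  expect_equal(empirical_roc(scores, labels)$auc, 0.5, tolerance = 0.03)
})

test_that("AUC agrees with pROC on a tied sample", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- round(c(rnorm(60, 0.8), rnorm(60)), 1)
  labels <- rep(c(1, 0), each = 60)
  ours <- empirical_roc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs)
})

test_that("binormal closed form predicts the empirical AUC of log-normal classes", {
  set.seed(29)
  mu1 <- log(63.5); s1 <- 0.45; mu2 <- log(211.1); s2 <- 0.46
  neg <- rlnorm(1e5, mu1, s1); pos <- rlnorm(1e5, mu2, s2)
  a <- empirical_roc(c(neg, pos), rep(c(FALSE, TRUE), each = 1e5))$auc
  expect_equal(a, pnorm((mu2 - mu1) / sqrt(s1^2 + s2^2)), tolerance = 0.005)
})

test_that("Youden cutoff equals the exhaustive-scan maximiser", {
  r <- empirical_roc(c(1, 2, 3, 4), c(F, F, T, T))
  y <- youden_threshold(r)
  expect_equal(y$threshold, 3)
  expect_equal(y$youden_j, 1)
  set.seed(37)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    scores <- round(runif(n, 0, 5), 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    y <- youden_threshold(empirical_roc(scores, labels))
    o <- oracle_youden(scores, labels)
    expect_equal(y$threshold, o$threshold)
    expect_equal(y$youden_j, o$j)
  }
})

test_that("degenerate all-equal scores give J = 0 with sensitivity 1", {
  y <- youden_threshold(empirical_roc(rep(2, 6), c(T, T, T, F, F, F)))
  expect_equal(y$youden_j, 0)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 0)
})

test_that("fixed-target operating points respect their constraints", {
  set.seed(41)
  neg <- 1:10; pos <- 6:15
  r <- empirical_roc(c(neg, pos), rep(c(FALSE, TRUE), each = 10))
  t_spec <- threshold_at_target(r, 0.90, "specificity")
  expect_equal(t_spec$threshold, 10)
  expect_equal(t_spec$specificity, 0.9)
  t_sens <- threshold_at_target(r, 1.0, "sensitivity")
  expect_true(t_sens$threshold <= min(pos))
  # among cutoffs meeting the sensitivity target, the returned one
  # maximises specificity (scan oracle)
  for (target in c(0.90, 0.95)) {
    tr <- threshold_at_target(r, target, "sensitivity")
    cands <- c(Inf, sort(unique(c(neg, pos)), decreasing = TRUE))
    feas <- cands[vapply(cands, function(t) mean(pos >= t) >= target - 1e-12, TRUE)]
    specs <- vapply(feas, function(t) mean(neg < t), 0)
    expect_equal(tr$specificity, max(specs))
  }
  expect_error(threshold_at_target(r, 1.5, "sensitivity"), "target")
})

test_that("bootstrap intervals are deterministic, ordered and shrink with n", {
  set.seed(43)
  scores <- c(rnorm(40, 2), rnorm(40)); labels <- rep(c(T, F), each = 40)
  b1 <- bootstrap_metrics(scores, labels, 1, B = 400, seed = 9)
  b2 <- bootstrap_metrics(scores, labels, 1, B = 400, seed = 9)
  expect_identical(b1$ci, b2$ci)
  for (m in names(b1$ci)) expect_lte(b1$ci[[m]][1], b1$ci[[m]][2])
  # perfectly separated data: sensitivity CI collapses at 1
  sep <- bootstrap_metrics(c(1, 1, 1, 5, 5, 5), c(F, F, F, T, T, T), 3,
                           B = 200, seed = 1)
  expect_equal(sep$ci$sensitivity, c(1, 1))
  expect_equal(sep$ci$specificity, c(1, 1))
  # width roughly halves when n quadruples
  big <- c(rnorm(160, 2), rnorm(160)); lab_big <- rep(c(T, F), each = 160)
  bb <- bootstrap_metrics(big, lab_big, 1, B = 400, seed = 9)
  w1 <- diff(b1$ci$sensitivity); w2 <- diff(bb$ci$sensitivity)
  expect_lt(w2, w1)
  expect_equal(w2 / w1, 0.5, tolerance = 0.5)
})

test_that("DeLong self-comparison gives z = 0, p = 1; label swap negates z", {
  set.seed(47)
  x <- rnorm(30); y <- x + rnorm(30, sd = 0.5)
  labels <- rep(c(TRUE, FALSE), 15)
  self <- delong_compare_paired(x, x, labels)
  expect_equal(self$z, 0)
  expect_equal(self$p_two_sided, 1)
  ab <- delong_compare_paired(x, y, labels)
  ba <- delong_compare_paired(y, x, labels)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_two_sided, ba$p_two_sided)
  expect_gte(ab$var_diff, 0)
  expect_true(ab$p_two_sided >= 0 && ab$p_two_sided <= 1)
})

test_that("DeLong variance of one AUC is close to the jackknife estimate", {
  set.seed(53)
  scores <- c(rnorm(25, 1.2), rnorm(25)); labels <- rep(c(T, F), each = 25)
  v <- delong_auc_variance(scores, labels)$var_auc
  n <- length(scores)
  auc_i <- vapply(seq_len(n), function(i)
    empirical_roc(scores[-i], labels[-i])$auc, 0)
  jack <- (n - 1) / n * sum((auc_i - mean(auc_i))^2)
  expect_equal(v, jack, tolerance = 0.10)
})

test_that("DeLong comparison agrees with pROC on shared data", {
  skip_if_not_installed("pROC")
  set.seed(59)
  labels <- rep(c(1, 0), each = 40)
  a <- rnorm(80) + labels; b <- rnorm(80) + 0.7 * labels
  ours <- delong_compare_paired(a, b, labels)
  theirs <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE, direction = "<"),
                           pROC::roc(labels, b, quiet = TRUE, direction = "<"),
                           method = "delong", paired = TRUE)
  expect_equal(ours$p_two_sided, as.numeric(theirs$p.value))
})

test_that("zoning splits records correctly and scores the determinate zone", {
  scores <- c(1, 2, 3, 4, 5, 6); labels <- c(F, F, F, T, T, T)
  z <- two_threshold_zoning(scores, labels, 2.5, 4.5)
  expect_equal(z$counts, c(Low = 2L, Indeterminate = 2L, High = 2L))
  expect_equal(z$fraction_indeterminate, 1 / 3)
  expect_equal(z$accuracy_determinate, 1.0)
  expect_equal(z$ppv_high, 1.0)
  expect_equal(z$npv_low, 1.0)
  same <- two_threshold_zoning(scores, labels, 4, 4)
  expect_equal(same$fraction_indeterminate, 0)
  expect_warning(two_threshold_zoning(scores, labels, 5, 4), "collapsed")
})

test_that("zoning metrics match a direct per-record scan on a synthetic cohort", {
  co <- generate_cohort(seed = 8)
  st <- classify_stage(co)
  keep <- st %in% STAGEABLE_LEVELS
  x <- co$p217_fg_ml[keep]; y <- st[keep] != "A_NEG_T_NEG"
  r <- empirical_roc(x, y)
  lo <- threshold_at_target(r, 0.95, "sensitivity")$threshold
  hi <- threshold_at_target(r, 0.90, "specificity")$threshold
  z <- two_threshold_zoning(x, y, lo, hi)
  zone <- ifelse(x < lo, "Low", ifelse(x >= hi, "High", "Ind"))
  det <- zone != "Ind"
  expect_equal(z$fraction_indeterminate, mean(!det))
  expect_equal(z$accuracy_determinate,
               mean((zone[det] == "High") == y[det]))
})

test_that("two-step screening reruns the ROC on survivors only", {
  co <- generate_cohort(seed = 12)
  st <- classify_stage(co)
  keep <- st %in% STAGEABLE_LEVELS
  ts <- two_step_youden(co$p217_fg_ml[keep], st[keep],
                        step1_pos = c("INTERMEDIATE", "ADVANCED"),
                        step2_pos = "ADVANCED")
  thr1 <- ts$step1$report$threshold
  expect_equal(ts$step1$n_survivors, sum(co$p217_fg_ml[keep] >= thr1))
  # the second contrast is harder than the first
  expect_lt(ts$step2$roc$auc, ts$step1$roc$auc)
  # an empty step-2 class raises
  few <- st[keep] %in% c("A_NEG_T_NEG", "INITIAL")
  expect_error(two_step_youden(co$p217_fg_ml[keep][few], st[keep][few],
                               c("INITIAL"), "ADVANCED"),
               "degenerate")
})

test_that("logistic risk model matches a likelihood grid search on a toy set", {
  x <- c(-2, -1, -0.5, 0.5, 1, 2)
  y <- c(0, 0, 1, 0, 1, 1)
  fit <- fit_risk_model(data.frame(x = x), y)
  grid <- oracle_logistic_grid(x, y)
  expect_equal(unname(fit$coefficients[1]), unname(grid["intercept"]),
               tolerance = 1e-3)
  expect_equal(unname(fit$coefficients[2]), unname(grid["slope"]),
               tolerance = 1e-3)
})

test_that("risk model degeneracies are caught", {
  set.seed(61)
  y <- rep(c(0, 1), 10)
  expect_error(fit_risk_model(data.frame(a = rep(1, 20)), y), "constant")
  x_sep <- ifelse(y == 1, 2, -2) + runif(20, -0.1, 0.1)
  expect_error(fit_risk_model(data.frame(x = x_sep), y), "separation")
})

test_that("adding the marker itself never hurts the model AUC", {
  set.seed(67)
  n <- 120
  marker <- rlnorm(n, 4.5, 0.5)
  y <- rbinom(n, 1, plogis(-8 + 0.08 * marker))
  if (sum(y) > 2 && sum(1 - y) > 2) {
    base_auc <- empirical_roc(marker, y)$auc
    full <- fit_risk_model(data.frame(p217 = marker,
                                      age = rnorm(n, 73, 6)), y)
    expect_gte(empirical_roc(full$scores, y)$auc, base_auc - 0.02)
  }
})
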