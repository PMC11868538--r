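staged_cohort <- function(seed) {
  co <- generate_cohort(seed = seed)
  list(cohort = co, stages = classify_stage(co))
}

test_that("A-T- curve falls and Advanced curve rises with p217", {
  d <- staged_cohort(4)
  cur <- fit_stage_curves(d$cohort, d$stages)
  expect_lt(cur$models$A_NEG_T_NEG[["slope"]], 0)
  expect_gt(cur$models$ADVANCED[["slope"]], 0)
  expect_gt(cur$models$INTERMEDIATE[["slope"]], 0)
  p <- predict_stage_curves(cur, c(20, 250, 490))
  expect_true(all(p > 0 & p < 1))
})

test_that("stage curve coefficients match a likelihood grid search on a toy set", {
  x <- c(10, 30, 60, 100, 150, 220, 300, 420)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  fit <- glm_toy <- fit_risk_model(data.frame(p217 = x), y)
  grid <- oracle_logistic_grid(x / 100, y)  # scaled for a stable grid
  expect_equal(unname(fit$coefficients[1]), unname(grid["intercept"]),
               tolerance = 1e-3)
  expect_equal(unname(fit$coefficients[2]) * 100, unname(grid["slope"]),
               tolerance = 1e-3)
})

test_that("records above the concentration cap are excluded and counted", {
  d <- staged_cohort(6)
  cur <- fit_stage_curves(d$cohort, d$stages, fit_max = 500)
  over <- sum(d$cohort$p217_fg_ml > 500 &
                d$stages %in% STAGEABLE_LEVELS)
  expect_equal(cur$n_over_cap, over)
  keep <- d$stages %in% STAGEABLE_LEVELS & d$cohort$p217_fg_ml <= 500
  expect_equal(cur$n_fit, sum(keep))
})

test_that("band fractions equal a direct group-by count and sum to 1", {
  d <- staged_cohort(9)
  bands <- sliding_window_probabilities(d$cohort, d$stages)
  pcols <- paste0("p_", c("A_NEG_T_NEG", "INITIAL_EARLY", "INTERMEDIATE",
                          "ADVANCED"))
  expect_equal(unname(rowSums(bands[, pcols])), rep(1, nrow(bands)))
  merged <- merge_initial_early(d$stages)
  keep <- merged %in% c("A_NEG_T_NEG", "INITIAL_EARLY", "INTERMEDIATE",
                        "ADVANCED") & d$cohort$p217_fg_ml <= 500
  x <- d$cohort$p217_fg_ml[keep]; s <- as.character(merged[keep])
  for (i in seq_len(nrow(bands))) {
    in_band <- x >= bands$band_start[i] & x < bands$band_end[i]
    expect_equal(bands$n[i], sum(in_band))
    expect_equal(bands$p_ADVANCED[i], mean(s[in_band] == "ADVANCED"))
  }
  expect_equal(bands$band_center, bands$band_start + 40)
})

test_that("sparse bands are omitted and an overlapping stride is supported", {
  d <- staged_cohort(9)
  strict <- sliding_window_probabilities(d$cohort, d$stages,
                                         min_per_band = 10^6)
  expect_equal(nrow(strict), 0)
  expect_gt(attr(strict, "n_omitted_bands"), 0)
  overlap <- sliding_window_probabilities(d$cohort, d$stages, stride = 40)
  nonover <- sliding_window_probabilities(d$cohort, d$stages)
  expect_gt(nrow(overlap), nrow(nonover))
})

test_that("single-stage input yields probability 1 in every populated band", {
  p217 <- seq(20, 70, by = 5)
  co <- toy_cohort(p217, rep("A_NEG_T_NEG", length(p217)))
  bands <- sliding_window_probabilities(co, attr(co, "stage"))
  expect_true(all(bands$p_A_NEG_T_NEG == 1))
})

test_that("crossover of two hand-built curves is found to 0.01 fg/ml", {
  cur <- structure(list(
    models = list(
      A_NEG_T_NEG = c(intercept = 2, slope = -0.02),
      INITIAL_EARLY = c(intercept = -20, slope = 0),     # never argmax
      INTERMEDIATE = c(intercept = -21, slope = 0),
      ADVANCED = c(intercept = -1, slope = 0.01)
    ),
    fit_range = c(0, 500), group = "all", n_fit = 0, n_over_cap = 0,
    degenerate = character()), class = "stage_prob_curves")
  # linear predictors equal where 2 - 0.02 x = -1 + 0.01 x  =>  x = 100
  cx <- crossover_points(cur)
  expect_equal(nrow(cx), 1)
  expect_equal(cx$boundary, 100, tolerance = 0.011)
  expect_equal(cx$from_stage, "A_NEG_T_NEG")
  expect_equal(cx$to_stage, "ADVANCED")
})

test_that("a dominant stage yields no crossovers", {
  cur <- structure(list(
    models = list(
      A_NEG_T_NEG = c(intercept = 5, slope = 0),
      INITIAL_EARLY = c(intercept = -5, slope = 0),
      INTERMEDIATE = c(intercept = -5, slope = 0),
      ADVANCED = c(intercept = -5, slope = 0.001)
    ),
    fit_range = c(0, 500), group = "all", n_fit = 0, n_over_cap = 0,
    degenerate = character()), class = "stage_prob_curves")
  expect_equal(nrow(crossover_points(cur)), 0)
})

test_that("argmax traversal is monotone through the stage order", {
  # the generative model orders the stages by p217; the most-likely stage
  # must never move backwards as concentration rises
  stage_rank <- c(A_NEG_T_NEG = 1, INITIAL_EARLY = 2, INTERMEDIATE = 3,
                  ADVANCED = 4)
  for (seed in 1:10) {
    d <- staged_cohort(seed)
    cx <- crossover_points(fit_stage_curves(d$cohort, d$stages))
    expect_gte(nrow(cx), 2)
    expect_true(all(diff(cx$boundary) > 0))
    ranks <- stage_rank[c(cx$from_stage[1], cx$to_stage)]
    expect_true(all(diff(ranks) > 0))
    expect_equal(cx$from_stage[1], "A_NEG_T_NEG")
  }
})

test_that("logistic and band estimates agree on the same cohort", {
  d <- staged_cohort(2)
  cur <- fit_stage_curves(d$cohort, d$stages)
  bands <- sliding_window_probabilities(d$cohort, d$stages)
  cc <- concordance(cur, bands)
  expect_lt(cc$overall, 0.15)
  expect_equal(length(cc$per_stage), 4)
  expect_identical(cc, concordance(cur, bands))  # deterministic
})

test_that("logistic fit recovers known generating parameters within 3 SE", {
  set.seed(71)
  n <- 5000
  x <- runif(n, 0, 500)
  b0 <- -3; b1 <- 0.012
  y <- rbinom(n, 1, plogis(b0 + b1 * x))
  fit <- fit_risk_model(data.frame(x = x), y)
  se <- sqrt(diag(vcov(fit$model)))
  expect_lt(abs(fit$coefficients[1] - b0), 3 * se[1])
  expect_lt(abs(fit$coefficients[2] - b1), 3 * se[2])
})
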