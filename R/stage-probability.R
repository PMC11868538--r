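MERGED_STAGES <- c("A_NEG_T_NEG", "INITIAL_EARLY", "INTERMEDIATE", "ADVANCED")

# Restrict a staged cohort to the analysis set used by the probability
# methods: stageable records, Initial/Early merged, optional CI-only
# subgroup, marker capped at fit_max. Returns p217, merged stage factor and
# the number of records removed by the cap.
probability_analysis_set <- function(cohort, stages, group = c("all", "ci"),
                                     fit_max = 500) {
  group <- match.arg(group)
  merged <- merge_initial_early(stages)
  keep <- merged %in% MERGED_STAGES
  if (group == "ci")
    keep <- keep & cohort$clinical_group %in% c("MCI", "DEM", "dementia")
  x <- cohort$p217_fg_ml[keep]
  s <- factor(as.character(merged[keep]), levels = MERGED_STAGES)
  over <- x > fit_max
  list(p217 = x[!over], stage = s[!over], n_over_cap = sum(over))
}

#' One-vs-rest logistic stage-probability curves
#'
#' For each of the four consolidated stages (A-T-, Initial/Early,
#' Intermediate, Advanced), fits a binary logistic regression of
#' stage membership on plasma p217+tau over records with p217+tau at or
#' below `fit_max` fg/ml (very sparse concentrations above the cap would
#' otherwise dominate the slope). The fitted curves give, at any
#' concentration, each stage's one-vs-rest probability; these need not sum
#' to 1 across stages and are not normalised by default.
#'
#' @param cohort Staged-input data frame (needs `p217_fg_ml` and
#'   `clinical_group`).
#' @param stages Stage factor from [classify_stage()] aligned with `cohort`.
#' @param group `"all"` or `"ci"` (cognitively impaired only).
#' @param fit_max Upper p217+tau bound for the fit, fg/ml (default 500).
#' @return Object of class `stage_prob_curves`: `models` (per-stage
#'   intercept and slope), `fit_range`, `group`, `n_fit`, `n_over_cap`,
#'   `degenerate` (stages with one class only, curve constant).
#' @export
fit_stage_curves <- function(cohort, stages, group = c("all", "ci"),
                             fit_max = 500) {
  group <- match.arg(group)
  d <- probability_analysis_set(cohort, stages, group, fit_max)
  if (length(d$p217) < 4L) stop("too few records after the 0-", fit_max,
                                " fg/ml restriction")
  models <- list(); degenerate <- character()
  for (s in MERGED_STAGES) {
    y <- as.integer(d$stage == s)
    if (length(unique(y)) < 2L) {
      degenerate <- c(degenerate, s)
      models[[s]] <- c(intercept = if (y[1] == 1L) Inf else -Inf, slope = 0)
      next
    }
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ d$p217, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    cf <- stats::coef(fit)
    if (fit$deviance < 1e-6 || (sep_warn && any(abs(cf) > 50)))
      stop("perfect separation fitting the ", s, " curve")
    models[[s]] <- c(intercept = unname(cf[1]), slope = unname(cf[2]))
  }
  structure(list(models = models, fit_range = c(0, fit_max), group = group,
                 n_fit = length(d$p217), n_over_cap = d$n_over_cap,
                 degenerate = degenerate),
            class = "stage_prob_curves")
}

#' Evaluate stage-probability curves at given concentrations
#'
#' @param curves A [fit_stage_curves()] object.
#' @param x p217+tau concentrations (fg/ml).
#' @return Matrix (length(x) x 4) of one-vs-rest probabilities.
#' @export
predict_stage_curves <- function(curves, x) {
  stopifnot(inherits(curves, "stage_prob_curves"))
  out <- vapply(MERGED_STAGES, function(s) {
    m <- curves$models[[s]]
    stats::plogis(m[["intercept"]] + m[["slope"]] * x)
  }, numeric(length(x)))
  if (length(x) == 1L) out <- matrix(out, nrow = 1,
                                     dimnames = list(NULL, MERGED_STAGES))
  out
}

#' @export
print.stage_prob_curves <- function(x, ...) {
  cat(sprintf("One-vs-rest logistic stage curves (%s participants, n = %d fit, %d above %g fg/ml cap)\n",
              x$group, x$n_fit, x$n_over_cap, x$fit_range[2]))
  for (s in names(x$models))
    cat(sprintf("  %-14s intercept %8.4f  slope %8.5f\n", s,
                x$models[[s]][["intercept"]], x$models[[s]][["slope"]]))
  if (length(x$degenerate))
    cat("  degenerate (single-class) stages:",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Sliding-window (sequential band) stage probabilities
#'
#' Splits the p217+tau axis into sequential non-overlapping bands of
#' `band_width` fg/ml starting at 0 and, within each band, estimates each
#' consolidated stage's probability as its fraction of the band's records.
#' Each band's estimate is centred at the band midpoint. Bands holding
#' fewer than `min_per_band` records are omitted (their count is recorded).
#' An overlapping-window sensitivity mode is available by setting `stride`
#' below `band_width`.
#'
#' @inheritParams fit_stage_curves
#' @param band_width Band width in fg/ml (default 80, chosen as a balance
#'   between over-smoothing and noise).
#' @param min_per_band Minimum records for a band to be reported.
#' @param stride Distance between band starts; defaults to `band_width`
#'   (non-overlapping).
#' @return Data frame: `band_center`, `band_start`, `band_end`, `n`, and
#'   `p_<stage>` fractions summing to 1 per band; attribute
#'   `n_omitted_bands`.
#' @export
sliding_window_probabilities <- function(cohort, stages, group = c("all", "ci"),
                                         band_width = 80, min_per_band = 5,
                                         fit_max = 500, stride = band_width) {
  group <- match.arg(group)
  if (band_width <= 0 || stride <= 0) stop("band_width and stride must be positive")
  d <- probability_analysis_set(cohort, stages, group, fit_max)
  starts <- seq(0, fit_max - 1e-9, by = stride)
  rows <- list(); omitted <- 0L
  for (a in starts) {
    b <- a + band_width
    in_band <- d$p217 >= a & d$p217 < b
    n <- sum(in_band)
    if (n < min_per_band) { omitted <- omitted + 1L; next }
    frac <- as.numeric(table(d$stage[in_band])) / n
    rows[[length(rows) + 1L]] <- data.frame(
      band_center = a + band_width / 2, band_start = a, band_end = b, n = n,
      t(stats::setNames(frac, paste0("p_", MERGED_STAGES))))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(band_center = numeric(), band_start = numeric(),
               band_end = numeric(), n = integer())
  rownames(out) <- NULL
  attr(out, "n_omitted_bands") <- omitted
  out
}

#' Crossover points of the most-likely stage
#'
#' Scans the fitted one-vs-rest curves over `[0, fit_max]` and reports the
#' p217+tau concentrations at which the stage with the highest probability
#' changes. Each boundary found on the grid is refined by bisection to
#' 0.01 fg/ml. On well-behaved cohorts the boundaries are increasing and
#' traverse A-T- to Initial/Early to Intermediate to Advanced.
#'
#' @param curves A [fit_stage_curves()] object.
#' @param grid_step Initial scan step, fg/ml (default 0.5).
#' @param tol Bisection tolerance, fg/ml (default 0.01).
#' @return Data frame with columns `boundary`, `from_stage`, `to_stage`,
#'   ordered by increasing boundary; zero rows when one stage dominates
#'   everywhere.
#' @export
crossover_points <- function(curves, grid_step = 0.5, tol = 0.01) {
  stopifnot(inherits(curves, "stage_prob_curves"))
  lo <- curves$fit_range[1]; hi <- curves$fit_range[2]
  grid <- seq(lo, hi, by = grid_step)
  argmax_at <- function(x) {
    p <- predict_stage_curves(curves, x)
    max.col(p, ties.method = "first")
  }
  am <- argmax_at(grid)
  ch <- which(diff(am) != 0)
  if (!length(ch))
    return(data.frame(boundary = numeric(), from_stage = character(),
                      to_stage = character(), stringsAsFactors = FALSE))
  res <- lapply(ch, function(i) {
    a <- grid[i]; b <- grid[i + 1]
    fa <- am[i]; fb <- am[i + 1]
    while (b - a > tol) {
      m <- (a + b) / 2
      if (argmax_at(m) == fa) a <- m else b <- m
    }
    data.frame(boundary = (a + b) / 2,
               from_stage = MERGED_STAGES[fa], to_stage = MERGED_STAGES[fb],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$boundary), , drop = FALSE]
}

#' Concordance between logistic curves and band estimates
#'
#' Mean absolute difference between the logistic one-vs-rest probabilities
#' evaluated at each populated band's centre and the band's empirical stage
#' fractions; reported per stage and overall. Small values indicate the two
#' individual-level estimators agree.
#'
#' @param curves A [fit_stage_curves()] object.
#' @param bands Output of [sliding_window_probabilities()] on the same
#'   cohort and group.
#' @return List: `per_stage` (named mean |diff| per stage), `overall`,
#'   `n_bands`.
#' @export
concordance <- function(curves, bands) {
  stopifnot(inherits(curves, "stage_prob_curves"))
  if (!nrow(bands)) stop("no populated bands")
  pred <- predict_stage_curves(curves, bands$band_center)
  obs <- as.matrix(bands[, paste0("p_", MERGED_STAGES)])
  d <- abs(pred - obs)
  list(per_stage = stats::setNames(colMeans(d), MERGED_STAGES),
       overall = mean(d), n_bands = nrow(bands))
}
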