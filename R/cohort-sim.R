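#' Fit a log-normal distribution from a median and quartiles
#'
#' Skewed biomarkers in the study are summarised as median (Q1-Q3). A
#' log-normal with `mu = ln(median)` and
#' `sigma = (ln Q3 - ln Q1) / (2 * qnorm(0.75))` reproduces the requested
#' median exactly and the requested quartile ratio `Q3/Q1` exactly, which
#' makes it the natural generative stand-in for strictly positive,
#' right-skewed concentrations. Because a two-parameter log-normal is
#' symmetric on the log scale, its implied quartiles are the geometric
#' symmetrisation `median / sqrt(Q3/Q1)` and `median * sqrt(Q3/Q1)`; when
#' the printed quartiles are asymmetric around the median on the log scale
#' the individual quartiles are matched only up to that asymmetry (1.6-3.4%
#' across the study's p217+tau rows).
#'
#' @param median,q1,q3 Positive reals with `q1 < median < q3` (strict mode).
#' @param strict If `TRUE` (default) enforce strict ordering
#'   `0 < q1 < median < q3`; if `FALSE`, allow the median to tie a quartile
#'   (printed summaries rounded to one decimal can produce such ties) while
#'   still requiring `0 < q1 <= median <= q3` and `q1 < q3`.
#' @return List with `mu` (log fg/ml) and `sigma` (> 0), class
#'   `lognormal_params`.
#' @examples
#' fit_lognormal_from_quartiles(63.5, 46.0, 84.9)
#' @export
fit_lognormal_from_quartiles <- function(median, q1, q3, strict = TRUE) {
  if (!all(is.finite(c(median, q1, q3)))) stop("quartile summary must be finite")
  if (q1 <= 0) stop("quartiles must be strictly positive")
  ok <- if (strict) q1 < median && median < q3 else
    q1 <= median && median <= q3 && q1 < q3
  if (!ok)
    stop("quartile ordering violated: need q1 < median < q3 (got ",
         q1, ", ", median, ", ", q3, ")")
  z75 <- stats::qnorm(0.75)
  structure(list(mu = log(median), sigma = (log(q3) - log(q1)) / (2 * z75)),
            class = "lognormal_params")
}

# Table 1 truncation ranges per stage. Each entry: c(lower, upper), with
# closed lower and open upper bound, matching the inclusive-positivity rule.
stage_ranges <- function(thr) {
  pos <- thr$centiloid_pos
  list(
    A_NEG_T_NEG = list(cl = c(-Inf, pos), me = c(0, thr$me_pos),
                       te = c(0, thr$te_pos), r = c(0, thr$r_pos)),
    INITIAL = list(cl = c(pos, Inf), me = c(0, thr$me_pos),
                   te = c(0, thr$te_pos), r = c(0, thr$r_pos)),
    EARLY = list(cl = c(pos, Inf), me = c(thr$me_pos, Inf),
                 te = c(0, thr$te_pos), r = c(0, thr$r_pos)),
    INTERMEDIATE = list(cl = c(pos, Inf), me = c(0, Inf),
                        te = c(thr$te_pos, thr$te_high), r = c(0, Inf)),
    ADVANCED = list(cl = c(pos, Inf), me = c(0, Inf),
                    te = c(thr$te_high, Inf), r = c(0, Inf))
  )
}

#' Per-stage generative parameters from the published summary table
#'
#' Returns the study's printed per-stage summaries as a data frame with one
#' row per stageable stratum: sample size, plasma p217+tau median and
#' quartiles (fg/ml), Centiloid and Me/Te SUVR medians and quartiles, age
#' mean and SD (years), and the percentages of female sex, APOE e4
#' carriership and cognitive impairment (MCI or dementia).
#'
#' @return Data frame with 5 rows (stages `A_NEG_T_NEG`, `INITIAL`, `EARLY`,
#'   `INTERMEDIATE`, `ADVANCED`) and columns `stage`, `n`,
#'   `p217_median/q1/q3`, `centiloid_median/q1/q3`, `me_median/q1/q3`,
#'   `te_median/q1/q3`, `age_mean`, `age_sd`, `pct_female`, `pct_apoe_e4`,
#'   `pct_ci`.
#' @examples
#' spec <- default_table2_spec()
#' sum(spec$n)  # 475
#' @export
default_table2_spec <- function() {
  data.frame(
    stage = STAGEABLE_LEVELS,
    n = c(192L, 80L, 31L, 128L, 44L),
    p217_median = c(63.5, 118.7, 140.7, 211.1, 336.8),
    p217_q1 = c(46.0, 84.0, 112.7, 147.8, 256.9),
    p217_q3 = c(84.9, 156.8, 168.6, 288.7, 425.0),
    centiloid_median = c(-0.7, 69.5, 86.7, 120.9, 120.5),
    centiloid_q1 = c(-3.8, 43.3, 59.7, 90.2, 101.0),
    centiloid_q3 = c(4.4, 102.4, 126.7, 145.7, 139.9),
    me_median = c(0.9, 1.0, 1.3, 1.8, 2.2),
    me_q1 = c(0.8, 0.8, 1.3, 1.5, 1.9),
    me_q3 = c(1.0, 1.0, 1.5, 2.1, 2.7),
    te_median = c(1.0, 1.0, 1.1, 1.7, 3.5),
    te_q1 = c(0.9, 1.0, 1.1, 1.4, 3.0),
    te_q3 = c(1.1, 1.1, 1.2, 2.2, 4.0),
    age_mean = c(74.1, 76.0, 75.2, 75.5, 68.3),
    age_sd = c(6.2, 7.2, 8.4, 7.1, 7.8),
    pct_female = c(50, 42, 45, 54, 50),
    pct_apoe_e4 = c(21, 54, 74, 71, 61),
    pct_ci = c(19, 40, 55, 78, 95),
    stringsAsFactors = FALSE
  )
}

# Truncated sampling by inverse-CDF. p/q are the distribution's CDF and
# quantile function taking (x, ...) with parameters already bound.
rtrunc <- function(n, pfun, qfun, lower, upper, stage, var) {
  lo <- pfun(lower)
  hi <- pfun(upper)
  if (!is.finite(lo)) lo <- 0
  if (!is.finite(hi)) hi <- 1
  if (hi - lo < 1e-6)
    stop("truncation range for ", var, " in stage ", stage,
         " carries probability mass < 1e-6")
  u <- stats::runif(n, lo, hi)
  x <- qfun(u)
  # guard against quantile-function saturation exactly at an open bound
  pmin(pmax(x, lower + 1e-9), upper - 1e-9)
}

rtrunc_norm <- function(n, mean, sd, range, stage, var) {
  rtrunc(n, function(x) stats::pnorm(x, mean, sd),
         function(u) stats::qnorm(u, mean, sd),
         range[1], range[2], stage, var)
}

rtrunc_lnorm <- function(n, mu, sigma, range, stage, var) {
  rtrunc(n, function(x) stats::plnorm(x, mu, sigma),
         function(u) stats::qlnorm(u, mu, sigma),
         max(range[1], 0), range[2], stage, var)
}

#' Generate a synthetic cohort with the study's per-stage structure
#'
#' Draws, for each stage stratum, `n` participants whose plasma p217+tau is
#' log-normal (fitted from the stage's printed median and quartiles), whose
#' Centiloid is normal (median, IQR/1.349) truncated to the stage's
#' Centiloid range, whose Me and Te SUVR are log-normal (fitted from their
#' quartiles) truncated to the stage's SUVR ranges, and whose
#' rest-of-neocortex SUVR is normal(1.0, 0.1) truncated to the stage's R
#' constraint (the published table has no R summary; this is a free
#' parameter of the generator). Age is normal(mean, sd); sex, APOE e4 and
#' cognitive impairment are Bernoulli draws from the printed percentages.
#' Truncation to the rule-table ranges guarantees every record re-classifies
#' to its intended stage.
#'
#' Each stratum is driven by its own RNG substream derived from `seed`, so
#' the same seed always yields an identical cohort and adding or resizing a
#' stratum does not perturb the others.
#'
#' @param spec Data frame as returned by [default_table2_spec()]; `n` may be
#'   scaled for calibration experiments.
#' @param thr A [staging_thresholds()] object defining the truncation ranges.
#' @param seed Integer seed.
#' @param pct_mci_among_ci Percentage of the cognitively impaired stratum
#'   labelled MCI rather than dementia (study-wide ratio 144:83).
#' @return Data frame with columns `participant_id`, `age_years`, `sex`
#'   (`"F"`/`"M"`), `apoe_e4` (0/1), `clinical_group` (`"CU"`, `"MCI"`,
#'   `"DEM"`), `centiloid`, `suvr_me`, `suvr_te`, `suvr_r`, `p217_fg_ml`,
#'   and `stage_true` (the generating stratum).
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' table(classify_stage(cohort))
#' @export
generate_cohort <- function(spec = default_table2_spec(),
                            thr = staging_thresholds(), seed,
                            pct_mci_among_ci = 100 * 144 / 227) {
  if (missing(seed) || !is.finite(seed)) stop("an integer seed is required")
  stopifnot(is.data.frame(spec), all(spec$n > 0))
  ranges <- stage_ranges(thr)
  unknown <- setdiff(spec$stage, names(ranges))
  if (length(unknown))
    stop("spec contains non-stageable stage(s): ", paste(unknown, collapse = ", "))

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })

  strata <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    stg <- row$stage
    rng <- ranges[[stg]]
    n <- row$n
    # independent substream per stratum; offsets stay far below 2^31
    set.seed(as.integer(seed) + i * 10007L)

    p217_par <- fit_lognormal_from_quartiles(row$p217_median, row$p217_q1,
                                             row$p217_q3)
    p217 <- stats::rlnorm(n, p217_par$mu, p217_par$sigma)

    cl_sd <- (row$centiloid_q3 - row$centiloid_q1) / (2 * stats::qnorm(0.75))
    cl <- rtrunc_norm(n, row$centiloid_median, cl_sd, rng$cl, stg, "centiloid")

    me_par <- fit_lognormal_from_quartiles(row$me_median, row$me_q1, row$me_q3,
                                           strict = FALSE)
    me <- rtrunc_lnorm(n, me_par$mu, me_par$sigma, rng$me, stg, "suvr_me")

    te_par <- fit_lognormal_from_quartiles(row$te_median, row$te_q1, row$te_q3,
                                           strict = FALSE)
    te <- rtrunc_lnorm(n, te_par$mu, te_par$sigma, rng$te, stg, "suvr_te")

    r <- rtrunc_norm(n, 1.0, 0.1, c(max(rng$r[1], 0), rng$r[2]), stg, "suvr_r")

    age <- stats::rnorm(n, row$age_mean, row$age_sd)
    sex <- ifelse(stats::runif(n) < row$pct_female / 100, "F", "M")
    apoe <- as.integer(stats::runif(n) < row$pct_apoe_e4 / 100)
    ci <- stats::runif(n) < row$pct_ci / 100
    mci <- stats::runif(n) < pct_mci_among_ci / 100
    grp <- ifelse(!ci, "CU", ifelse(mci, "MCI", "DEM"))

    strata[[i]] <- data.frame(
      age_years = age, sex = sex, apoe_e4 = apoe, clinical_group = grp,
      centiloid = cl, suvr_me = me, suvr_te = te, suvr_r = r,
      p217_fg_ml = p217, stage_true = stg, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, strata)
  out <- cbind(participant_id = sprintf("S%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
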