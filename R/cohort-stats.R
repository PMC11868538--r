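#' Per-stage descriptive summary
#'
#' Reproduces the study's summary-table layout over the five stageable
#' strata: sample size; median (Q1, Q3) for the skewed variables (plasma
#' p217+tau, Centiloid, Me and Te SUVR); mean and SD for age; percentages
#' of female sex, APOE e4 carriership and cognitive impairment. Empty
#' stages are reported with n = 0 and missing statistics.
#'
#' @param cohort Staged-input data frame.
#' @param stages Stage factor from [classify_stage()] aligned with `cohort`.
#' @return Data frame, one row per stageable stage.
#' @export
describe_by_stage <- function(cohort, stages) {
  stages <- factor(as.character(stages), levels = STAGE_LEVELS)
  med3 <- function(x) if (length(x)) stats::quantile(x, c(0.5, 0.25, 0.75),
                                                     type = 7, names = FALSE)
  else c(NA_real_, NA_real_, NA_real_)
  rows <- lapply(STAGEABLE_LEVELS, function(s) {
    idx <- which(stages == s)
    d <- cohort[idx, , drop = FALSE]
    p <- med3(d$p217_fg_ml); cl <- med3(d$centiloid)
    me <- med3(d$suvr_me); te <- med3(d$suvr_te)
    n <- length(idx)
    data.frame(
      stage = s, n = n,
      p217_median = p[1], p217_q1 = p[2], p217_q3 = p[3],
      centiloid_median = cl[1], centiloid_q1 = cl[2], centiloid_q3 = cl[3],
      me_median = me[1], me_q1 = me[2], me_q3 = me[3],
      te_median = te[1], te_q1 = te[2], te_q3 = te[3],
      age_mean = if (n) mean(d$age_years) else NA_real_,
      age_sd = if (n > 1) stats::sd(d$age_years) else NA_real_,
      pct_female = if (n) 100 * mean(d$sex %in% c("F", "Female", "female")) else NA_real_,
      pct_apoe_e4 = if (n) 100 * mean(d$apoe_e4 == 1) else NA_real_,
      pct_ci = if (n) 100 * mean(d$clinical_group %in% c("MCI", "DEM", "dementia")) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohen's d effect size
#'
#' Standardised mean difference `(mean(group2) - mean(group1)) / s_pooled`
#' with the pooled SD using n - 1 denominators.
#'
#' @param group1,group2 Numeric vectors, each with at least 2 values.
#' @return Scalar d; positive when `group2` has the larger mean.
#' @examples
#' cohens_d(c(1, 2, 3), c(2, 3, 4))  # 1
#' @export
cohens_d <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("pooled SD is zero")
  (mean(group2) - mean(group1)) / sqrt(sp2)
}

#' Median fold change between two groups
#'
#' Ratio of group medians, `median(group2) / median(group1)`; both medians
#' must be strictly positive.
#'
#' @param group1,group2 Numeric vectors (reference group first).
#' @return Scalar fold change.
#' @examples
#' median_fold_change(63.5, 336.8)  # 5.304
#' @export
median_fold_change <- function(group1, group2) {
  m1 <- stats::median(group1); m2 <- stats::median(group2)
  if (!is.finite(m1) || !is.finite(m2) || m1 <= 0 || m2 <= 0)
    stop("group medians must be strictly positive")
  m2 / m1
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Overall tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()])
#' followed by Dunn's z test for every group pair: the difference in mean
#' ranks over its standard error from the pooled rank variance
#' `(N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j)`, where
#' `T = sum(t^3 - t)` over tie groups. Pairwise p values are two-sided
#' normal and adjusted for multiple comparisons (Holm by default).
#' Each pair also carries Cohen's d and the median fold change
#' (later-stage over earlier-stage group, in the order the factor levels
#' run).
#'
#' @param values Numeric response.
#' @param groups Factor (or coercible) of group membership.
#' @param adjust Multiplicity adjustment: `"holm"` (default) or
#'   `"bonferroni"`.
#' @return List: `H`, `df`, `p_value`, and `pairwise` data frame
#'   (`group1`, `group2`, `z`, `p_raw`, `p_adjusted`, `cohens_d`,
#'   `median_fold_change`).
#' @export
kruskal_dunn <- function(values, groups, adjust = c("holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0L)) stop("every group must be non-empty")
  if (length(values) != length(groups)) stop("values and groups differ in length")

  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(values)
  T_ties <- sum(ties^3 - ties)
  pooled <- N * (N + 1) / 12 - T_ties / (12 * (N - 1))

  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p_raw <- d <- fc <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(pooled * (1 / ns[[i]] + 1 / ns[[j]]))
    z[k] <- if (se > 0) (mean_ranks[[j]] - mean_ranks[[i]]) / se else 0
    p_raw[k] <- 2 * stats::pnorm(-abs(z[k]))
    vi <- values[groups == i]; vj <- values[groups == j]
    d[k] <- tryCatch(cohens_d(vi, vj), error = function(e) NA_real_)
    fc[k] <- tryCatch(median_fold_change(vi, vj), error = function(e) NA_real_)
  }
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             z = z, p_raw = p_raw,
                             p_adjusted = stats::p.adjust(p_raw, method = adjust),
                             cohens_d = d, median_fold_change = fc,
                             stringsAsFactors = FALSE))
}

#' Pearson chi-square test on a stage-by-category count table
#'
#' Plain Pearson chi-square with `(r - 1)(c - 1)` degrees of freedom and no
#' continuity correction, as used for the categorical stage comparisons
#' (sex, APOE e4 carriership, clinical group).
#'
#' @param counts Matrix (or table) of non-negative counts.
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_categorical <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in the count table")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ht$expected <= 0)) stop("expected count of zero")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = ht$expected)
}
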