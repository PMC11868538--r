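check_binary_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  labels <- as.logical(labels)
  if (anyNA(labels) || anyNA(scores) || !all(is.finite(scores)))
    stop("scores and labels must be finite and non-missing")
  if (!any(labels) || all(labels))
    stop("both classes must be present (n_pos = ", sum(labels),
         ", n_neg = ", sum(!labels), ")")
  labels
}

#' Empirical ROC curve and Mann-Whitney AUC
#'
#' Orientation is fixed: higher marker values indicate the positive class,
#' and a record is test-positive when its score is at or above the cutoff.
#' Candidate cutoffs are the distinct observed scores plus +Inf, so every
#' reported threshold is expressible in the marker's own units. The AUC is
#' the Mann-Whitney statistic with ties counted 1/2, which equals the
#' trapezoidal area under the empirical curve.
#'
#' @param scores Numeric marker values.
#' @param labels Logical (or 0/1) class indicator, `TRUE` = positive.
#' @return Object of class `roc_curve`: `thresholds` (descending, starting
#'   at `Inf`), `sens`, `spec`, `auc`, `n_pos`, `n_neg`.
#' @examples
#' empirical_roc(c(1, 2, 3, 2, 3, 4), c(0, 0, 0, 1, 1, 1))$auc  # 7/9
#' @export
empirical_roc <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  n_pos <- as.numeric(sum(labels)); n_neg <- as.numeric(sum(!labels))
  u <- sort(unique(scores), decreasing = TRUE)
  idx <- match(scores, u)
  pos_counts <- tabulate(idx[labels], nbins = length(u))
  neg_counts <- tabulate(idx[!labels], nbins = length(u))
  thr <- c(Inf, u)
  sens <- c(0, cumsum(pos_counts)) / n_pos       # test-positive: score >= cutoff
  spec <- c(n_neg, n_neg - cumsum(neg_counts)) / n_neg
  r <- rank(scores)                      # midranks handle ties as 1/2
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(thresholds = thr, sens = sens, spec = spec, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC = %.4f (%d positives, %d negatives, %d cutoffs)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

threshold_report <- function(roc, idx) {
  sens <- roc$sens[idx]; spec <- roc$spec[idx]
  tp <- sens * roc$n_pos; fn <- roc$n_pos - tp
  fp <- (1 - spec) * roc$n_neg; tn <- roc$n_neg - fp
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  structure(list(threshold = roc$thresholds[idx], sensitivity = sens,
                 specificity = spec, ppv = ppv, npv = npv,
                 youden_j = sens + spec - 1,
                 prevalence = roc$n_pos / (roc$n_pos + roc$n_neg)),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("Operating point at threshold %.4g:\n", x$threshold))
  fmt <- function(nm) {
    ci <- x$ci[[nm]]
    if (is.null(ci)) sprintf("%.3f", x[[nm]])
    else sprintf("%.3f [%.3f-%.3f]", x[[nm]], ci[1], ci[2])
  }
  cat(sprintf("  sensitivity %s  specificity %s\n  PPV %s  NPV %s  (prevalence %.3f)\n",
              fmt("sensitivity"), fmt("specificity"), fmt("ppv"), fmt("npv"),
              x$prevalence))
  invisible(x)
}

#' Youden-optimal operating point
#'
#' Returns the cutoff maximising Youden's J = sensitivity + specificity - 1
#' over the curve's candidate thresholds. Ties in J are broken toward the
#' lowest threshold, which maximises sensitivity at the optimum.
#'
#' @param roc A [empirical_roc()] object.
#' @return A `threshold_report` (threshold, sens, spec, PPV, NPV,
#'   `youden_j`, prevalence).
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$sens + roc$spec - 1
  best <- max(j)
  # thresholds are descending; the last index attaining the max is lowest
  idx <- max(which(j >= best - 1e-12))
  threshold_report(roc, idx)
}

#' Operating point at a target sensitivity or specificity
#'
#' In sensitivity mode returns the highest cutoff whose sensitivity meets
#' the target (maximising specificity subject to the constraint); in
#' specificity mode the lowest cutoff whose specificity meets the target
#' (maximising sensitivity).
#'
#' @param roc A [empirical_roc()] object.
#' @param target Target level in (0, 1].
#' @param mode `"sensitivity"` or `"specificity"`.
#' @return A `threshold_report`.
#' @export
threshold_at_target <- function(roc, target, mode = c("sensitivity", "specificity")) {
  stopifnot(inherits(roc, "roc_curve"))
  mode <- match.arg(mode)
  if (!is.finite(target) || target <= 0 || target > 1)
    stop("target must lie in (0, 1]")
  if (mode == "sensitivity") {
    ok <- which(roc$sens >= target - 1e-12)
    if (!length(ok)) stop("target sensitivity ", target, " unattainable (max ",
                          max(roc$sens), ")")
    idx <- min(ok)                       # highest threshold meeting the target
  } else {
    ok <- which(roc$spec >= target - 1e-12)
    if (!length(ok)) stop("target specificity ", target, " unattainable (max ",
                          max(roc$spec), ")")
    idx <- max(ok)                       # lowest threshold meeting the target
  }
  threshold_report(roc, idx)
}

metrics_at <- function(scores, labels, threshold) {
  pos <- labels; test_pos <- scores >= threshold
  tp <- sum(test_pos & pos); fp <- sum(test_pos & !pos)
  fn <- sum(!test_pos & pos); tn <- sum(!test_pos & !pos)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Bootstrap confidence intervals for an operating point
#'
#' Stratified nonparametric bootstrap: positives and negatives are resampled
#' within class, the four operating characteristics are recomputed at the
#' fixed cutoff, and percentile 2.5/97.5 limits are taken per metric.
#' Replicates in which PPV (or NPV) is undefined because no record is
#' test-positive (test-negative) are dropped from that metric's percentile
#' computation; the number dropped is recorded.
#'
#' @param scores,labels As in [empirical_roc()].
#' @param threshold Cutoff (test-positive iff score >= threshold).
#' @param B Number of bootstrap replicates (default 2000).
#' @param seed Integer seed; same seed gives identical intervals.
#' @param conf Confidence level (default 0.95).
#' @return A `threshold_report` with a `ci` element (list of
#'   `c(low, high)` per metric) and `n_dropped` counts.
#' @export
bootstrap_metrics <- function(scores, labels, threshold, B = 2000, seed,
                              conf = 0.95) {
  labels <- check_binary_labels(scores, labels)
  if (missing(seed) || !is.finite(seed)) stop("an integer seed is required")
  if (B < 1) stop("B must be positive")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  ipos <- which(labels); ineg <- which(!labels)
  reps <- matrix(NA_real_, nrow = B, ncol = 4,
                 dimnames = list(NULL, c("sensitivity", "specificity", "ppv", "npv")))
  for (b in seq_len(B)) {
    idx <- c(sample(ipos, length(ipos), replace = TRUE),
             sample(ineg, length(ineg), replace = TRUE))
    reps[b, ] <- metrics_at(scores[idx], labels[idx], threshold)
  }
  alpha <- (1 - conf) / 2
  ci <- lapply(colnames(reps), function(nm) {
    v <- reps[, nm]; v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_))
    unname(stats::quantile(v, c(alpha, 1 - alpha), type = 7))
  })
  names(ci) <- colnames(reps)
  n_dropped <- colSums(is.na(reps))

  point <- metrics_at(scores, labels, threshold)
  structure(list(threshold = threshold,
                 sensitivity = point[["sensitivity"]],
                 specificity = point[["specificity"]],
                 ppv = point[["ppv"]], npv = point[["npv"]],
                 youden_j = point[["sensitivity"]] + point[["specificity"]] - 1,
                 prevalence = mean(labels),
                 ci = ci, n_boot = B, n_dropped = n_dropped),
            class = "threshold_report")
}

# Structural components of the Mann-Whitney AUC: for each positive, the
# fraction of negatives it beats (ties 1/2); for each negative, the fraction
# of positives beating it.
delong_components <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two markers measured on the same subjects using the
#' structural-components estimate of var(AUC_a - AUC_b), which accounts for
#' the pairing. The z statistic is the AUC difference over its standard
#' error, with a two-sided normal p value.
#'
#' @param scores_a,scores_b Marker values for the same subjects.
#' @param labels Class indicator shared by both markers.
#' @return Object of class `delong_result`: `auc_a`, `auc_b`, `var_diff`,
#'   `z`, `p_two_sided`, and `degenerate` (`TRUE` when the variance is zero
#'   with a nonzero AUC difference, in which case p is reported as 0).
#' @export
delong_compare_paired <- function(scores_a, scores_b, labels) {
  labels <- check_binary_labels(scores_a, labels)
  check_binary_labels(scores_b, labels)
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  var_diff <- max(var_diff, 0)
  diff <- ca$auc - cb$auc
  degenerate <- FALSE
  if (var_diff == 0) {
    if (abs(diff) < 1e-12) { z <- 0; p <- 1 }
    else { z <- sign(diff) * Inf; p <- 0; degenerate <- TRUE }
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc, var_diff = var_diff,
                 z = z, p_two_sided = p, degenerate = degenerate),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong paired AUC comparison: %.4f vs %.4f, z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$z, x$p_two_sided,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' DeLong variance of a single AUC
#'
#' Structural-components estimate of var(AUC) for one marker; used for
#' asymptotic AUC confidence intervals.
#'
#' @inheritParams empirical_roc
#' @return List with `auc`, `var_auc`, and a normal-approximation 95% CI.
#' @export
delong_auc_variance <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  comp <- delong_components(scores, labels)
  v <- stats::var(comp$v10) / length(comp$v10) +
    stats::var(comp$v01) / length(comp$v01)
  half <- stats::qnorm(0.975) * sqrt(v)
  list(auc = comp$auc, var_auc = v,
       ci = c(max(0, comp$auc - half), min(1, comp$auc + half)))
}

#' Two-threshold triage into Low / Indeterminate / High zones
#'
#' Classifies each record as Low (score < `thr_low`), High (score >=
#' `thr_high`) or Indeterminate, and evaluates performance among the
#' determinate calls only: accuracy (High calls that are positive plus Low
#' calls that are negative), PPV within the High zone and NPV within the
#' Low zone. In practice `thr_low` is a high-sensitivity cutoff (e.g. 95%
#' sensitivity) and `thr_high` a high-specificity cutoff (e.g. 90%
#' specificity).
#'
#' @param scores,labels As in [empirical_roc()].
#' @param thr_low,thr_high Zone boundaries; if `thr_low > thr_high` the
#'   indeterminate zone collapses (both set to `thr_high`) with a warning.
#' @return List: `zone` (factor per record), `counts`,
#'   `fraction_indeterminate`, `accuracy_determinate`, `ppv_high`,
#'   `npv_low`, `thr_low`, `thr_high`.
#' @export
two_threshold_zoning <- function(scores, labels, thr_low, thr_high) {
  labels <- check_binary_labels(scores, labels)
  if (thr_low > thr_high) {
    warning("thr_low > thr_high; indeterminate zone collapsed to thr_high")
    thr_low <- thr_high
  }
  zone <- factor(ifelse(scores < thr_low, "Low",
                        ifelse(scores >= thr_high, "High", "Indeterminate")),
                 levels = c("Low", "Indeterminate", "High"))
  counts <- table(zone)
  det <- zone != "Indeterminate"
  correct <- (zone == "High" & labels) | (zone == "Low" & !labels)
  list(zone = zone,
       counts = stats::setNames(as.integer(counts), names(counts)),
       fraction_indeterminate = mean(zone == "Indeterminate"),
       accuracy_determinate = if (any(det)) sum(correct[det]) / sum(det) else NA_real_,
       ppv_high = if (any(zone == "High")) mean(labels[zone == "High"]) else NA_real_,
       npv_low = if (any(zone == "Low")) mean(!labels[zone == "Low"]) else NA_real_,
       thr_low = thr_low, thr_high = thr_high)
}

#' Two-step Youden screening
#'
#' Step 1 derives the Youden cutoff for a first stage contrast (e.g.
#' Intermediate-or-Advanced vs lower stages) on the whole cohort; step 2
#' re-runs the ROC analysis among step-1 screen-positives only (score at or
#' above the step-1 cutoff) for a second contrast (e.g. Advanced vs the
#' rest of the screen-positives). This mirrors using a cheap plasma test to
#' enrich before a confirmatory tau PET.
#'
#' @param scores Marker values.
#' @param stages Stage factor aligned with `scores`.
#' @param step1_pos Character vector of stage labels forming the step-1
#'   positive class.
#' @param step2_pos Stage labels forming the step-2 positive class among
#'   survivors.
#' @return List: `step1` (`roc`, `report`, `n_survivors`, `survivor_stages`)
#'   and `step2` (`roc`, `report`).
#' @export
two_step_youden <- function(scores, stages, step1_pos, step2_pos) {
  stages <- as.character(stages)
  lab1 <- stages %in% step1_pos
  roc1 <- empirical_roc(scores, lab1)
  rep1 <- youden_threshold(roc1)
  keep <- scores >= rep1$threshold
  s2 <- scores[keep]; g2 <- stages[keep]
  lab2 <- g2 %in% step2_pos
  if (length(s2) < 2L || !any(lab2) || all(lab2))
    stop("step 2 degenerate: ", length(s2), " survivors with ",
         sum(lab2), " positives")
  roc2 <- empirical_roc(s2, lab2)
  rep2 <- youden_threshold(roc2)
  list(step1 = list(roc = roc1, report = rep1, n_survivors = sum(keep),
                    survivor_stages = table(factor(g2, levels = unique(stages)))),
       step2 = list(roc = roc2, report = rep2))
}

#' Logistic risk model producing ROC scores
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()],
#' convergence when the deviance change is below 1e-8 or after 100
#' iterations) of a binary stage contrast on a feature matrix — typically
#' p217+tau alone, the demographic base model (age, sex, APOE e4), or the
#' full model combining them. The per-subject linear predictor is returned
#' as the ROC score.
#'
#' @param features Data frame or matrix of predictors (columns may be
#'   numeric or two-level factors).
#' @param labels Binary outcome.
#' @return List: `coefficients`, `scores` (linear predictor), `fitted`
#'   (probabilities), `converged`, `model` (the glm fit).
#' @export
fit_risk_model <- function(features, labels) {
  features <- as.data.frame(features)
  labels <- check_binary_labels(seq_len(nrow(features)), labels)
  if (nrow(features) <= ncol(features) + 1L)
    stop("need more observations than features")
  const <- vapply(features, function(col) length(unique(col)) < 2L, TRUE)
  if (any(const))
    stop("constant feature column(s): ",
         paste(names(features)[const], collapse = ", "))
  dat <- cbind(.y = as.integer(labels), features)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  coefs <- stats::coef(fit)
  # complete separation drives the deviance to zero (or saturates the
  # fitted probabilities) while the coefficient norm diverges
  if (fit$deviance < 1e-6 || (sep_warn && any(abs(coefs[-1]) > 50)))
    stop("perfect separation detected; consider a penalized fit (e.g. glmnet)")
  lp <- as.numeric(stats::predict(fit, type = "link"))
  list(coefficients = coefs, scores = lp,
       fitted = as.numeric(stats::fitted(fit)),
       converged = fit$converged, model = fit)
}
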