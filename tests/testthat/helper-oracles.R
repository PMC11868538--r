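# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# AUC by explicit pair counting, ties worth 1/2.
oracle_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Sort-and-interpolate percentile, h = (n - 1) p / 100 + 1.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Exhaustive scan over candidate cutoffs (observed values + Inf); returns
# the J-maximising cutoff with ties toward the lowest cutoff.
oracle_youden <- function(scores, labels) {
  cands <- c(Inf, sort(unique(scores), decreasing = TRUE))
  best <- -Inf; best_thr <- Inf; best_sens <- NA; best_spec <- NA
  for (t in cands) {
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    j <- sens + spec - 1
    if (j > best + 1e-12 || (abs(j - best) <= 1e-12 && t < best_thr)) {
      best <- j; best_thr <- t; best_sens <- sens; best_spec <- spec
    }
  }
  list(threshold = best_thr, j = best, sens = best_sens, spec = best_spec)
}

# Logistic log-likelihood for an intercept/slope pair.
logistic_loglik <- function(beta, x, y) {
  eta <- beta[1] + beta[2] * x
  sum(y * eta - log1p(exp(eta)))
}

# Two-parameter likelihood maximisation by iterated grid refinement;
# independent of glm's IRLS path.
oracle_logistic_grid <- function(x, y, b0_range = c(-10, 10),
                                 b1_range = c(-10, 10), iters = 30) {
  b0 <- b0_range; b1 <- b1_range
  for (i in seq_len(iters)) {
    g0 <- seq(b0[1], b0[2], length.out = 21)
    g1 <- seq(b1[1], b1[2], length.out = 21)
    ll <- outer(g0, g1, Vectorize(function(a, b) logistic_loglik(c(a, b), x, y)))
    k <- arrayInd(which.max(ll), dim(ll))
    step0 <- diff(b0) / 20; step1 <- diff(b1) / 20
    b0 <- c(g0[k[1]] - step0, g0[k[1]] + step0)
    b1 <- c(g1[k[2]] - step1, g1[k[2]] + step1)
  }
  c(intercept = mean(b0), slope = mean(b1))
}

# Dunn z statistics from first principles for small inputs.
oracle_dunn <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  Tt <- sum(ties^3 - ties)
  pooled <- N * (N + 1) / 12 - Tt / (12 * (N - 1))
  lev <- levels(groups)
  out <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) if (i < j) {
    ri <- mean(r[groups == lev[i]]); rj <- mean(r[groups == lev[j]])
    ni <- sum(groups == lev[i]); nj <- sum(groups == lev[j])
    z <- (rj - ri) / sqrt(pooled * (1 / ni + 1 / nj))
    out[[paste(lev[i], lev[j], sep = ".")]] <- z
  }
  out
}

# Small staged test cohort builder: stage-labelled records with fields the
# analysis functions need.
toy_cohort <- function(p217, stage, group = rep("CU", length(p217))) {
  data.frame(participant_id = sprintf("T%03d", seq_along(p217)),
             age_years = 70, sex = "F", apoe_e4 = 0L,
             clinical_group = group,
             centiloid = 50, suvr_me = 1, suvr_te = 1, suvr_r = 1,
             p217_fg_ml = p217, stringsAsFactors = FALSE) -> d
  attr(d, "stage") <- factor(stage, levels = ptaustage::STAGE_LEVELS)
  d
}
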