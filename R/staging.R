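#' Stage labels used throughout the package
#'
#' The five stageable labels of the biological PET staging scheme (the A-T-
#' comparison group plus the four disease stages) followed by the two
#' non-stageable labels: amyloid-negative but tau-positive participants
#' (excluded from all downstream analyses, consistent with a primary
#' age-related tauopathy / discordant-PET profile) and amyloid-positive
#' participants whose tau profile matches no row of the rule table.
#'
#' @format Character vector of length 7.
#' @export
STAGE_LEVELS <- c(
  "A_NEG_T_NEG", "INITIAL", "EARLY", "INTERMEDIATE", "ADVANCED",
  "EXCLUDED_A_NEG_T_POS", "UNSTAGED"
)

#' The five stageable labels (in disease order)
#' @rdname STAGE_LEVELS
#' @export
STAGEABLE_LEVELS <- STAGE_LEVELS[1:5]

#' PET positivity thresholds for biological staging
#'
#' Bundles the cut-points that drive [classify_stage()]: the Centiloid
#' threshold for amyloid positivity and the SUVR thresholds for tau
#' positivity in the mesial-temporal (Me), temporo-parietal (Te) and
#' rest-of-neocortex (R) composite regions, plus the high-tau Te threshold
#' separating moderate from high neocortical tau burden.
#'
#' Defaults are the values used in the study this package reproduces:
#' 25 Centiloid; 1.18 / 1.24 / 1.08 SUVR for Me / Te / R (95th percentile of
#' amyloid-negative cognitively unimpaired participants); 2.68 Te SUVR for
#' high tau (top quartile of tau PET in amyloid-positive cognitively
#' impaired participants, corresponding to 80 CenTauR).
#'
#' @param centiloid_pos Centiloid value at or above which a scan is amyloid
#'   positive. May be any real.
#' @param me_pos,te_pos,r_pos Tau positivity SUVR thresholds for the Me, Te
#'   and R regions; strictly positive.
#' @param te_high Te SUVR separating moderate from high tau; must exceed
#'   `te_pos`.
#' @return An object of class `staging_thresholds` (named list).
#' @examples
#' thr <- staging_thresholds()
#' thr$te_high
#' @export
staging_thresholds <- function(centiloid_pos = 25, me_pos = 1.18,
                               te_pos = 1.24, r_pos = 1.08, te_high = 2.68) {
  for (nm in c("centiloid_pos", "me_pos", "te_pos", "r_pos", "te_high")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("threshold '", nm, "' must be a single finite number")
  }
  if (me_pos <= 0 || te_pos <= 0 || r_pos <= 0 || te_high <= 0)
    stop("SUVR thresholds must be strictly positive")
  if (te_pos >= te_high)
    stop("te_pos must be strictly less than te_high")
  structure(
    list(centiloid_pos = centiloid_pos, me_pos = me_pos, te_pos = te_pos,
         r_pos = r_pos, te_high = te_high),
    class = "staging_thresholds"
  )
}

#' @export
print.staging_thresholds <- function(x, ...) {
  cat("Biological PET staging thresholds\n")
  cat(sprintf("  amyloid positivity : Centiloid >= %g\n", x$centiloid_pos))
  cat(sprintf("  tau positivity     : Me >= %g, Te >= %g, R >= %g (SUVR)\n",
              x$me_pos, x$te_pos, x$r_pos))
  cat(sprintf("  high tau (Te)      : SUVR >= %g\n", x$te_high))
  invisible(x)
}

check_finite <- function(x, field) {
  bad <- !is.finite(x)
  if (any(bad))
    stop("non-finite value in field '", field, "' (rows ",
         paste(utils::head(which(bad), 5L), collapse = ", "), ")")
  invisible(x)
}

#' Assign biological PET stages from Centiloid and tau SUVR values
#'
#' Implements the staging rule table. Decision order: amyloid status first
#' (A+ iff Centiloid >= `centiloid_pos`). Amyloid-negative scans are
#' `A_NEG_T_NEG` when all three tau regions are below their positivity
#' thresholds and `EXCLUDED_A_NEG_T_POS` otherwise. Amyloid-positive scans
#' are `ADVANCED` when Te SUVR >= `te_high`; `INTERMEDIATE` when Te falls in
#' the moderate band `[te_pos, te_high)`; otherwise (Te below positivity)
#' `EARLY` when Me is positive with R negative, `INITIAL` when all three
#' regions are negative, and `UNSTAGED` for the remaining profile (Te
#' negative but R positive), which the rule table does not define.
#'
#' Positivity comparisons are inclusive (value >= threshold is positive), so
#' the seven labels partition every finite input with no gaps or overlaps at
#' the boundaries.
#'
#' @param cohort Data frame with numeric columns `centiloid`, `suvr_me`,
#'   `suvr_te`, `suvr_r` (one row per participant), or a single-row list
#'   with those fields.
#' @param thr A [staging_thresholds()] object.
#' @return Factor of stage labels with levels [STAGE_LEVELS], one per row.
#' @examples
#' thr <- staging_thresholds()
#' classify_stage(
#'   data.frame(centiloid = c(120.5, 0), suvr_me = c(2.2, 0.9),
#'              suvr_te = c(3.5, 1.0), suvr_r = c(1.0, 1.0)), thr)
#' @export
classify_stage <- function(cohort, thr = staging_thresholds()) {
  stopifnot(inherits(thr, "staging_thresholds"))
  cohort <- as.data.frame(cohort)
  need <- c("centiloid", "suvr_me", "suvr_te", "suvr_r")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  cl <- as.numeric(cohort$centiloid)
  me <- as.numeric(cohort$suvr_me)
  te <- as.numeric(cohort$suvr_te)
  r  <- as.numeric(cohort$suvr_r)
  check_finite(cl, "centiloid"); check_finite(me, "suvr_me")
  check_finite(te, "suvr_te");   check_finite(r, "suvr_r")
  if (any(me <= 0) || any(te <= 0) || any(r <= 0))
    stop("SUVR values must be strictly positive")

  a_pos <- cl >= thr$centiloid_pos
  t_all_neg <- me < thr$me_pos & te < thr$te_pos & r < thr$r_pos

  out <- character(length(cl))
  # amyloid-negative branch
  out[!a_pos & t_all_neg]  <- "A_NEG_T_NEG"
  out[!a_pos & !t_all_neg] <- "EXCLUDED_A_NEG_T_POS"
  # amyloid-positive branch, evaluated high tau first
  adv <- a_pos & te >= thr$te_high
  int <- a_pos & !adv & te >= thr$te_pos
  te_neg <- a_pos & !adv & !int            # Te < te_pos
  ear <- te_neg & me >= thr$me_pos & r < thr$r_pos
  ini <- te_neg & !ear & t_all_neg
  uns <- te_neg & !ear & !ini
  out[adv] <- "ADVANCED"; out[int] <- "INTERMEDIATE"
  out[ear] <- "EARLY";    out[ini] <- "INITIAL"; out[uns] <- "UNSTAGED"
  factor(out, levels = STAGE_LEVELS)
}

#' Sample percentile by linear interpolation
#'
#' The quantile convention used to derive PET thresholds from reference
#' subcohorts: linear interpolation on the sorted sample at position
#' h = (n - 1) p / 100 + 1 (the common "type 7" rule). Tau positivity
#' thresholds correspond to the 95th percentile of amyloid-negative
#' cognitively unimpaired participants; the high-tau Te threshold to the
#' 75th percentile of amyloid-positive cognitively impaired participants.
#'
#' @param values Numeric vector, at least 2 finite values.
#' @param percentile Percentile in (0, 100).
#' @param type Quantile type passed to [stats::quantile()]; default 7.
#' @return The interpolated sample percentile (scalar).
#' @examples
#' derive_percentile_threshold(1:5, 75)    # 4
#' derive_percentile_threshold(1:10, 95)   # 9.55
#' @export
derive_percentile_threshold <- function(values, percentile, type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values supplied")
  if (length(values) < 2L) stop("need at least 2 finite values")
  if (!is.finite(percentile) || percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  if (!all(is.finite(values))) stop("values must be finite")
  if (percentile >= 90 && length(values) < 20L)
    warning("deriving the ", percentile,
            "th percentile from fewer than 20 values; threshold is unstable")
  unname(stats::quantile(values, percentile / 100, type = type, names = FALSE))
}

#' Derive the high-tau Te threshold from a cohort
#'
#' Top-quartile (75th percentile) temporo-parietal SUVR among
#' amyloid-positive cognitively impaired (MCI or dementia) participants.
#'
#' @param cohort Staged-input data frame with `centiloid`, `suvr_te` and
#'   `clinical_group` columns.
#' @param thr A [staging_thresholds()] object providing `centiloid_pos`.
#' @return Te SUVR threshold (scalar).
#' @export
derive_t_high <- function(cohort, thr = staging_thresholds()) {
  sel <- cohort$centiloid >= thr$centiloid_pos &
    cohort$clinical_group %in% c("MCI", "DEM", "dementia")
  if (!any(sel)) stop("no amyloid-positive cognitively impaired participants")
  derive_percentile_threshold(cohort$suvr_te[sel], 75)
}

#' Stage counts and headline prevalences
#'
#' Tabulates the stage labels and computes the prevalences the study reports
#' over stageable participants only: amyloid-positive fraction, combined
#' Intermediate/Advanced fraction, and Advanced fraction. Excluded and
#' unstaged participants are counted separately and never enter the
#' denominators.
#'
#' @param stages Factor from [classify_stage()] (or a character vector using
#'   the same labels).
#' @return List with `counts` (named integer vector over [STAGE_LEVELS]),
#'   `n_stageable`, `n_excluded`, `n_unstaged`, and `prevalence_pct` (named
#'   vector: `a_pos`, `intermediate_advanced`, `advanced`, in percent).
#' @examples
#' x <- factor(rep(STAGEABLE_LEVELS, c(192, 80, 31, 128, 44)),
#'             levels = STAGE_LEVELS)
#' stage_counts(x)$prevalence_pct
#' @export
stage_counts <- function(stages) {
  if (!length(stages)) stop("empty cohort")
  stages <- factor(as.character(stages), levels = STAGE_LEVELS)
  if (anyNA(stages)) stop("unknown stage label present")
  counts <- table(stages)
  n_stageable <- sum(counts[STAGEABLE_LEVELS])
  a_pos <- sum(counts[c("INITIAL", "EARLY", "INTERMEDIATE", "ADVANCED")])
  int_adv <- sum(counts[c("INTERMEDIATE", "ADVANCED")])
  adv <- counts[["ADVANCED"]]
  prev <- if (n_stageable > 0)
    c(a_pos = 100 * a_pos / n_stageable,
      intermediate_advanced = 100 * int_adv / n_stageable,
      advanced = 100 * adv / n_stageable)
  else c(a_pos = NA_real_, intermediate_advanced = NA_real_, advanced = NA_real_)
  list(
    counts = stats::setNames(as.integer(counts), names(counts)),
    n_stageable = as.integer(n_stageable),
    n_excluded = as.integer(counts[["EXCLUDED_A_NEG_T_POS"]]),
    n_unstaged = as.integer(counts[["UNSTAGED"]]),
    prevalence_pct = prev
  )
}

#' Merge the Initial and Early stages
#'
#' Plasma p217+tau does not separate the Initial (A+T-) and Early (A+ with
#' mesial-temporal-limited tau) stages, so all probability and grouped
#' discrimination analyses consolidate them into a single Initial/Early
#' stage. Other labels pass through unchanged.
#'
#' @param stages Factor from [classify_stage()].
#' @return Factor with levels `A_NEG_T_NEG`, `INITIAL_EARLY`,
#'   `INTERMEDIATE`, `ADVANCED`, `EXCLUDED_A_NEG_T_POS`, `UNSTAGED`.
#' @export
merge_initial_early <- function(stages) {
  s <- as.character(stages)
  if (!all(s %in% STAGE_LEVELS)) stop("unknown stage label present")
  s[s %in% c("INITIAL", "EARLY")] <- "INITIAL_EARLY"
  factor(s, levels = c("A_NEG_T_NEG", "INITIAL_EARLY", "INTERMEDIATE",
                       "ADVANCED", "EXCLUDED_A_NEG_T_POS", "UNSTAGED"))
}
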