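REQUIRED_COLUMNS <- c("participant_id", "age_years", "sex", "apoe_e4",
                      "clinical_group", "centiloid", "suvr_me", "suvr_te",
                      "suvr_r", "p217_fg_ml")

normalize_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- ifelse(x %in% c("F", "FEMALE"), "F",
                ifelse(x %in% c("M", "MALE"), "M", NA_character_))
  if (anyNA(out)) stop("unrecognised sex code(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

normalize_clinical_group <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x %in% c("DEMENTIA", "AD", "DEM")] <- "DEM"
  bad <- !x %in% c("CU", "MCI", "DEM")
  if (any(bad)) stop("unrecognised clinical group(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  x
}

#' Read a participant cohort CSV
#'
#' Reads the participant dialect used throughout the package
#' (`participant_id, age_years, sex, apoe_e4, clinical_group, centiloid,
#' suvr_me, suvr_te, suvr_r, p217_fg_ml` plus optional `p217_cv_pct`),
#' normalising sex (`F`/`Female`, `M`/`Male`) and clinical group
#' (`DEM`/`dementia`/`AD`). Unknown extra columns are preserved.
#'
#' @param path CSV file path.
#' @return Data frame with normalised codes.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(REQUIRED_COLUMNS, names(d))
  if (length(miss)) stop(paste(miss, collapse = ", "), " required")
  d$sex <- normalize_sex(d$sex)
  d$clinical_group <- normalize_clinical_group(d$clinical_group)
  for (col in c("age_years", "centiloid", "suvr_me", "suvr_te", "suvr_r",
                "p217_fg_ml")) {
    d[[col]] <- as.numeric(d[[col]])
    check_finite(d[[col]], col)
  }
  if (any(d$p217_fg_ml <= 0)) stop("p217_fg_ml must be strictly positive")
  d
}

#' Write a participant cohort CSV
#'
#' @param cohort Data frame in the participant dialect.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param thresholds A [staging_thresholds()] object.
#' @param bootstrap_B Bootstrap replicates for operating-point CIs
#'   (minimum 100).
#' @param seed Integer seed (mandatory; drives the bootstrap).
#' @param band_width Sliding-window band width, fg/ml.
#' @param fit_max Upper p217+tau bound for regression fits, fg/ml.
#' @param adjust_method `"holm"` or `"bonferroni"`.
#' @return List of class `run_config`.
#' @export
run_config <- function(thresholds = staging_thresholds(), bootstrap_B = 2000,
                       seed, band_width = 80, fit_max = 500,
                       adjust_method = c("holm", "bonferroni")) {
  if (missing(seed) || !is.finite(seed)) stop("config requires an integer seed")
  if (bootstrap_B < 100) stop("bootstrap_B must be at least 100")
  if (fit_max <= 0) stop("fit_max must be positive")
  structure(list(thresholds = thresholds, bootstrap_B = bootstrap_B,
                 seed = as.integer(seed), band_width = band_width,
                 fit_max = fit_max, adjust_method = match.arg(adjust_method)),
            class = "run_config")
}

# The three headline stage contrasts; positive class listed per contrast.
contrast_classes <- function() {
  list(
    AposAll = list(neg = "A_NEG_T_NEG",
                   pos = c("INITIAL", "EARLY", "INTERMEDIATE", "ADVANCED")),
    IntAdv = list(neg = c("A_NEG_T_NEG", "INITIAL", "EARLY"),
                  pos = c("INTERMEDIATE", "ADVANCED")),
    Adv = list(neg = c("A_NEG_T_NEG", "INITIAL", "EARLY", "INTERMEDIATE"),
               pos = "ADVANCED")
  )
}

run_contrast <- function(cohort, stages, contrast, config, seed_offset) {
  keep <- stages %in% c(contrast$neg, contrast$pos)
  x <- cohort$p217_fg_ml[keep]
  y <- as.character(stages[keep]) %in% contrast$pos
  if (!any(y) || all(y)) return(NULL)
  roc <- empirical_roc(x, y)
  dl <- delong_auc_variance(x, y)
  yr <- youden_threshold(roc)
  boot <- bootstrap_metrics(x, y, yr$threshold, B = config$bootstrap_B,
                            seed = config$seed + seed_offset)
  ops <- list(
    youden = boot,
    sens90 = threshold_at_target(roc, 0.90, "sensitivity"),
    sens95 = threshold_at_target(roc, 0.95, "sensitivity"),
    spec90 = threshold_at_target(roc, 0.90, "specificity"),
    spec95 = threshold_at_target(roc, 0.95, "specificity")
  )
  list(auc = roc$auc, auc_ci = dl$ci, n_pos = roc$n_pos, n_neg = roc$n_neg,
       operating_points = ops)
}

#' Run the full staging and discrimination pipeline
#'
#' Stages the cohort, excludes amyloid-negative tau-positive and unstaged
#' records, merges Initial/Early, and then for all participants and the
#' cognitively impaired subgroup runs the three headline contrasts (A-T- vs
#' all A+; lower stages vs Intermediate/Advanced; Advanced vs all others)
#' with Youden and fixed-target operating points (bootstrap CIs on the
#' Youden point), fits the stage-probability curves and sliding-window
#' bands with their crossovers and concordance, and computes the per-stage
#' descriptives and Kruskal-Wallis/Dunn comparisons of p217+tau.
#'
#' @param cohort Participant data frame (see [read_cohort()]).
#' @param config A [run_config()] object.
#' @return Nested list of class `analysis_report`; serialise with
#'   [write_report()].
#' @export
run_full_pipeline <- function(cohort, config) {
  stopifnot(inherits(config, "run_config"))
  stages <- classify_stage(cohort, config$thresholds)
  counts <- stage_counts(stages)

  groups <- list(all = rep(TRUE, nrow(cohort)),
                 ci = cohort$clinical_group %in% c("MCI", "DEM"))
  contrasts <- contrast_classes()
  discrimination <- list()
  off <- 0L
  for (g in names(groups)) {
    sel <- groups[[g]]
    for (cn in names(contrasts)) {
      off <- off + 1L
      res <- run_contrast(cohort[sel, , drop = FALSE], stages[sel],
                          contrasts[[cn]], config, off)
      if (is.null(res)) next
      discrimination[[paste(g, cn, sep = ".")]] <- res
    }
  }

  probability <- list()
  for (g in c("all", "ci")) {
    curves <- fit_stage_curves(cohort, stages, group = g,
                               fit_max = config$fit_max)
    bands <- sliding_window_probabilities(cohort, stages, group = g,
                                          band_width = config$band_width,
                                          fit_max = config$fit_max)
    probability[[g]] <- list(
      curves = curves,
      bands = bands,
      crossovers = crossover_points(curves),
      concordance = if (nrow(bands)) concordance(curves, bands) else NULL
    )
  }

  stageable <- stages %in% STAGEABLE_LEVELS
  kd <- kruskal_dunn(cohort$p217_fg_ml[stageable],
                     factor(as.character(stages[stageable]),
                            levels = STAGEABLE_LEVELS),
                     adjust = config$adjust_method)

  structure(list(
    stage_counts = counts,
    descriptives = describe_by_stage(cohort, stages),
    pairwise_p217 = kd,
    discrimination = discrimination,
    probability = probability,
    provenance = list(
      n_input = nrow(cohort),
      n_excluded_a_neg_t_pos = counts$n_excluded,
      n_unstaged = counts$n_unstaged,
      config = unclass(config)[c("bootstrap_B", "seed", "band_width",
                                 "fit_max", "adjust_method")],
      thresholds = unclass(config$thresholds),
      package_version = as.character(utils::packageVersion("ptaustage"))
    )
  ), class = "analysis_report")
}

#' Serialise an analysis report to JSON
#'
#' Writes the report losslessly (full numeric precision); re-running the
#' pipeline with the same config and input reproduces the file byte for
#' byte.
#'
#' @param report An `analysis_report` (or any list).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  clean <- unclass(report)
  clean$probability <- lapply(clean$probability, function(p) {
    p$curves <- list(models = lapply(p$curves$models, unname),
                     fit_range = p$curves$fit_range, group = p$curves$group,
                     n_fit = p$curves$n_fit, n_over_cap = p$curves$n_over_cap)
    p
  })
  clean$discrimination <- lapply(clean$discrimination, function(d) {
    d$operating_points <- lapply(d$operating_points, unclass)
    d
  })
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
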