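#' ACE summary score and elevated-exposure indicator
#'
#' Sums ten dichotomous adverse-childhood-experience components into a 0-10
#' score and dichotomizes at the conventional four-or-more threshold.
#' Components must be complete: scoring happens only after imputation has
#' filled component-level missingness, so a missing component here signals a
#' pipeline error, not a data property.
#'
#' @param components numeric vector of 10 values in \{0, 1\} (single
#'   participant) or a 10-column matrix / data.frame (one row each).
#' @return a list with `score` (integer 0-10) and `elevated` (0/1),
#'   vectorized over rows.
#' @export
#' @examples
#' compute_ace(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))  # score 4, elevated 1
compute_ace <- function(components) {
  m <- if (is.null(dim(components))) {
    matrix(as.numeric(components), nrow = 1L)
  } else {
    as.matrix(components)
  }
  if (ncol(m) != 10L) stop("expected exactly 10 ACE components")
  if (anyNA(m)) {
    stop("missing ACE component: scores must be computed after imputation")
  }
  if (!all(m %in% c(0, 1))) stop("ACE components must be binary 0/1")
  score <- as.integer(rowSums(m))
  list(score = score, elevated = as.integer(score >= 4L))
}

#' Sex-specific weighted decile boundaries for triglycerides and HDL
#'
#' Computes the survey-weighted decile boundaries needed by the metabolic
#' syndrome classifier: the upper-triglyceride boundary (7th decile for
#' males -- "top 3 deciles" -- and 8th for females) and the lower-HDL
#' boundary (2nd decile for males, 3rd for females).  Boundaries are
#' left-continuous inverse-CDF quantiles (see [weighted_quantile()]), so
#' they are invariant to rescaling all weights.
#'
#' @param cohort data.frame with `sex`, `triglycerides`, `hdl` columns.
#' @param weights numeric vector of sampling weights (default: the cohort's
#'   `weight` column, or unit weights).
#' @return object of class `"decile_cutoffs"`: a list with per-sex
#'   `triglycerides` (upper boundary) and `hdl` (lower boundary).
#' @export
decile_cutoffs <- function(cohort, weights = NULL) {
  w <- weights %||% cohort$weight %||% rep(1, nrow(cohort))
  out <- list()
  trig_p <- c(male = 0.7, female = 0.8)  # top 3 / top 2 deciles
  hdl_p  <- c(male = 0.2, female = 0.3)  # bottom 2 / bottom 3 deciles
  for (s in c("male", "female")) {
    idx <- which(cohort$sex == s)
    for (v in c("triglycerides", "hdl")) {
      ok <- idx[!is.na(cohort[[v]][idx])]
      if (length(ok) < 10L) {
        stop(sprintf("fewer than 10 non-missing %s values for sex '%s'", v, s))
      }
    }
    out[[s]] <- list(
      triglycerides = weighted_quantile(cohort$triglycerides[idx], w[idx],
                                        trig_p[[s]], na.rm = TRUE),
      hdl = weighted_quantile(cohort$hdl[idx], w[idx], hdl_p[[s]],
                              na.rm = TRUE)
    )
  }
  structure(out, class = "decile_cutoffs")
}

#' @export
print.decile_cutoffs <- function(x, ...) {
  cat("Sex-specific weighted decile boundaries\n")
  for (s in c("male", "female")) {
    cat(sprintf("  %-6s triglycerides >= %.2f, HDL <= %.2f\n",
                s, x[[s]]$triglycerides, x[[s]]$hdl))
  }
  invisible(x)
}

# The blood-pressure / diagnosis / medication rule shared by the MetS
# composite's first category and the standalone hypertension outcome.
# Boundary-inclusive on both pressures (>= 130 systolic, >= 80 diastolic).
htn_positive <- function(record) {
  as.integer(record$systolic >= 130 | record$diastolic >= 80 |
               record$htn_diagnosis == 1 | record$htn_medication == 1)
}

#' Classify hypertension
#'
#' Positive when systolic pressure >= 130 mmHg, diastolic >= 80 mmHg, a
#' self-reported hypertension diagnosis, or current antihypertensive
#' medication use.  Identical to the hypertension category of
#' [classify_mets()].
#'
#' @param record data.frame (or one-row list) with `systolic`, `diastolic`,
#'   `htn_diagnosis`, `htn_medication`; values must be non-missing
#'   (post-imputation).
#' @return integer 0/1, vectorized over rows.
#' @export
classify_hypertension <- function(record) {
  need <- c("systolic", "diastolic", "htn_diagnosis", "htn_medication")
  rec <- as.data.frame(record)[need]
  if (anyNA(rec)) stop("missing biomarker: classify after imputation")
  htn_positive(rec)
}

#' Classify metabolic syndrome from five biomarker categories
#'
#' Positive when at least three of the five categories exceed their
#' cutoffs: (1) hypertension (systolic >= 130 or diastolic >= 80 mmHg,
#' diagnosis, or medication); (2) waist circumference (> 102 cm male,
#' > 80 cm female); (3) triglycerides at or above the sex-specific upper
#' decile boundary; (4) HDL at or below the sex-specific lower decile
#' boundary; (5) diabetes (HbA1c > 5.7%, anti-diabetic medication, or
#' diagnosis).
#'
#' @param record data.frame with biomarker columns (see
#'   [generate_cohort()] schema); non-missing post-imputation.
#' @param sex `"male"`/`"female"`, recycled; defaults to `record$sex`.
#' @param cutoffs a [decile_cutoffs()] object.
#' @return integer 0/1, vectorized over rows.
#' @export
classify_mets <- function(record, sex = record$sex, cutoffs) {
  rec <- as.data.frame(record)
  if (!all(sex %in% c("male", "female"))) {
    stop("unknown sex code: ", paste(setdiff(unique(sex), c("male", "female")),
                                     collapse = ", "))
  }
  sex <- rep_len(sex, nrow(rec))
  need <- c("systolic", "diastolic", "waist", "triglycerides", "hdl", "hba1c",
            "htn_diagnosis", "htn_medication", "diabetes_diagnosis",
            "diabetes_medication")
  if (anyNA(rec[need])) stop("missing biomarker: classify after imputation")
  trig_cut <- vapply(sex, function(s) cutoffs[[s]]$triglycerides, numeric(1))
  hdl_cut <- vapply(sex, function(s) cutoffs[[s]]$hdl, numeric(1))
  cat1 <- htn_positive(rec)
  cat2 <- as.integer(rec$waist > ifelse(sex == "male", 102, 80))
  cat3 <- as.integer(rec$triglycerides >= trig_cut)
  cat4 <- as.integer(rec$hdl <= hdl_cut)
  cat5 <- as.integer(rec$hba1c > 5.7 | rec$diabetes_medication == 1 |
                       rec$diabetes_diagnosis == 1)
  as.integer(cat1 + cat2 + cat3 + cat4 + cat5 >= 3L)
}

#' Derive the six adjustment covariates from raw cohort fields
#'
#' Computes equivalized income (household income divided by the square root
#' of household size), the higher of the two parents' five-level education,
#' the parental support index (mean of five Likert items), and the
#' neighborhood disadvantage score (mean of five census-tract proportions).
#' Inputs must be non-missing (post-imputation).
#'
#' @param record data.frame with raw covariate columns (see
#'   [generate_cohort()] schema).
#' @return data.frame with `age`, `sex`, `equivalized_income`,
#'   `parental_education_max`, `parental_support_index`,
#'   `neighborhood_disadvantage`.
#' @export
#' @examples
#' rec <- data.frame(age = 29, sex = "female",
#'                   parent1_education = 4, parent2_education = 3,
#'                   household_income = 100, household_size = 4,
#'                   support_1 = 3, support_2 = 3, support_3 = 4,
#'                   support_4 = 3, support_5 = 4,
#'                   tract_1 = 0.2, tract_2 = 0.2, tract_3 = 0.2,
#'                   tract_4 = 0.2, tract_5 = 0.2)
#' derive_covariates(rec)  # equivalized_income 50, education max 4
derive_covariates <- function(record) {
  rec <- as.data.frame(record)
  if (any(rec$household_size < 1)) stop("household size must be >= 1")
  tr <- as.matrix(rec[tract_cols()])
  if (anyNA(tr) || any(tr < 0 | tr > 1)) {
    stop("tract proportions must be non-missing and within [0, 1]")
  }
  sup <- as.matrix(rec[support_cols()])
  if (anyNA(sup)) stop("missing parental support item: derive after imputation")
  data.frame(
    age = rec$age,
    sex = rec$sex,
    equivalized_income = rec$household_income / sqrt(rec$household_size),
    parental_education_max = pmax(rec$parent1_education,
                                  rec$parent2_education),
    parental_support_index = rowMeans(sup),
    neighborhood_disadvantage = rowMeans(tr),
    stringsAsFactors = FALSE
  )
}

#' Attach all derived analysis variables to a completed cohort
#'
#' Convenience wrapper used by the pipeline: computes the ACE score and
#' elevated indicator, the six adjustment covariates, and -- when
#' `biomarker_outcomes = TRUE` -- replaces the `mets` and `hypertension`
#' columns with the biomarker-derived composites (decile cutoffs computed
#' on this cohort, weighted, after any exclusions the caller applied).
#'
#' @param cohort completed (no missing values) cohort data.frame.
#' @param biomarker_outcomes derive MetS/hypertension from biomarkers
#'   instead of using the generated indicator columns.
#' @return the cohort with derived columns appended.
#' @export
derive_all <- function(cohort, biomarker_outcomes = FALSE) {
  ace <- compute_ace(cohort[ace_cols()])
  cov <- derive_covariates(cohort)
  cohort$ace_score <- ace$score
  cohort$elevated_aces <- ace$elevated
  for (v in setdiff(names(cov), c("age", "sex"))) cohort[[v]] <- cov[[v]]
  if (biomarker_outcomes) {
    cuts <- decile_cutoffs(cohort)
    cohort$mets <- classify_mets(cohort, cutoffs = cuts)
    cohort$hypertension <- classify_hypertension(cohort)
  }
  cohort
}
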