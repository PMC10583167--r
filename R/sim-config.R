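# Canonical category and outcome names used throughout the package.

#' Race categories and outcome names
#'
#' `race_levels()` returns the five analysis race categories produced by the
#' generator; `ingest_race_levels()` additionally admits the two categories
#' that are only ever seen on ingest and removed by [apply_exclusions()].
#' `outcome_names()` returns the seven binary health outcomes.
#'
#' @return character vector of category names.
#' @export
race_levels <- function() {
  c("Multiracial", "White", "Black", "Asian", "AI/NA")
}

#' @rdname race_levels
#' @export
ingest_race_levels <- function() {
  c(race_levels(), "Hispanic/Latino", "Other")
}

#' @rdname race_levels
#' @export
outcome_names <- function() {
  c("mets", "hypertension", "asthma", "depression", "anxiety",
    "suicidal_ideation", "drug_use")
}

ace_cols <- function() paste0("ace_", 1:10)
support_cols <- function() paste0("support_", 1:5)
tract_cols <- function() paste0("tract_", 1:5)
covariate_raw_cols <- function() {
  c("age", "sex", "parent1_education", "parent2_education",
    "household_income", "household_size", support_cols(), tract_cols())
}
biomarker_cols <- function() {
  c("systolic", "diastolic", "waist", "triglycerides", "hdl", "hba1c",
    "htn_diagnosis", "htn_medication", "diabetes_diagnosis",
    "diabetes_medication")
}

# Default within-group risk ratios for elevated (>=4) ACEs, by outcome and
# race group.  These are the generator's study conditions: the adjusted
# within-group associations the synthetic population is built to carry.
default_true_rr <- function() {
  m <- rbind(
    mets              = c(1.00, 1.03, 1.00, 1.00, 0.99),
    hypertension      = c(0.98, 0.99, 1.01, 1.02, 0.86),
    asthma            = c(1.13, 1.04, 1.02, 1.00, 1.15),
    depression        = c(1.14, 1.13, 1.13, 1.10, 1.21),
    anxiety           = c(1.12, 1.05, 1.03, 0.98, 0.99),
    suicidal_ideation = c(1.05, 1.05, 1.05, 1.08, 1.07),
    drug_use          = c(1.13, 1.11, 1.08, 1.08, 1.30)
  )
  colnames(m) <- race_levels()
  m
}

# Risk ratio of each race group versus the Multiracial referent in the
# low-ACE cell, chosen so marginal outcome prevalences differ across groups
# the way a diverse national adolescent cohort's do.
default_race_main_rr <- function() {
  m <- rbind(
    mets              = c(1, 0.87, 1.23, 0.87, 1.81),
    hypertension      = c(1, 1.02, 1.10, 0.92, 1.32),
    asthma            = c(1, 0.63, 0.63, 0.42, 0.67),
    depression        = c(1, 1.00, 0.74, 0.49, 0.91),
    anxiety           = c(1, 0.83, 0.33, 0.16, 0.18),
    suicidal_ideation = c(1, 0.72, 0.74, 0.60, 1.50),
    drug_use          = c(1, 0.98, 0.29, 0.60, 1.10)
  )
  colnames(m) <- race_levels()
  m
}

default_confounder_params <- function() {
  list(
    age_mean = 29, age_sd = 1.8,
    male_prob = 0.51,
    # five-level parental education: <HS, vocational/GED, HS diploma,
    # some college, college graduate or greater
    parental_education_probs = c(0.06, 0.05, 0.35, 0.18, 0.36),
    income_meanlog = log(45), income_sdlog = 0.7,
    household_size_mean = 3.5,
    support_probs = c(0.07, 0.15, 0.32, 0.31, 0.15),
    tract_shape1 = 2, tract_shape2 = 12,
    # optional per-outcome named vectors of log-RR per unit of a *derived*
    # covariate (centered at its realized mean), e.g.
    # list(asthma = c(neighborhood_disadvantage = 0.5))
    covariate_log_rr = list()
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic survey cohort: design geometry
#' (strata, clusters, weight heterogeneity), race composition, the
#' race-specific prevalence of elevated (>= 4 of 10) adverse childhood
#' experiences, baseline risks and risk ratios of the seven binary outcomes
#' under a log-linear risk model, confounder distributions, and missingness
#' rates.  Defaults describe a cohort like a multi-wave nationally
#' representative US adolescent-to-adult health study: about 74% White, 17%
#' Black, 3.2% Asian, 0.6% American Indian/Native American and 5.8%
#' Multiracial (weighted), with elevated-ACE prevalence between 21% and 40%
#' by group.
#'
#' @param n_individuals number of participants to generate.
#' @param n_strata number of design strata.
#' @param clusters_per_stratum primary sampling units per stratum.
#' @param race_proportions named probabilities over [race_levels()];
#'   must sum to 1 (within 1e-9).
#' @param ace_prevalence_by_race named probability of elevated ACEs per race.
#' @param baseline_risk_by_outcome named risks in the doubly-unexposed
#'   (Multiracial referent, low-ACE) cell, one per outcome.
#' @param true_rr outcome x race matrix of within-group risk ratios for
#'   elevated ACEs.
#' @param race_main_rr outcome x race matrix of risk ratios versus the
#'   Multiracial referent at low ACEs (Multiracial column must be 1).
#' @param confounder_params list of distribution parameters for the six
#'   adjustment covariates; see `default_confounder_params()` in the source.
#' @param missing_rates named rates for [induce_missingness()]: entries named
#'   `ace`, `covariate`, `outcome` are row-level (probability a row has at
#'   least one masked variable of that class); any other name must be a
#'   cohort column and is masked element-wise at that rate.
#' @param missing_mechanism `"MCAR"` (default) or `"MAR"` (mask probability
#'   depends on race and parental education, calibrated to the marginal rate).
#' @param weight_dispersion log-normal sd of sampling weights within stratum
#'   (0 = equal weights).
#' @param pregnancy_rate probability of pregnancy among female participants.
#' @param seed integer seed; generation is a pure function of (config, seed).
#' @return an object of class `"sim_config"` (a validated list).
#' @seealso [generate_cohort()], [induce_missingness()]
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 500, seed = 7)
#' cohort <- generate_cohort(cfg)
#' dim(cohort)
sim_config <- function(n_individuals = 12372,
                       n_strata = 20,
                       clusters_per_stratum = 6,
                       race_proportions = NULL,
                       ace_prevalence_by_race = NULL,
                       baseline_risk_by_outcome = NULL,
                       true_rr = NULL,
                       race_main_rr = NULL,
                       confounder_params = NULL,
                       missing_rates = c(ace = 0.55, covariate = 0.21,
                                         outcome = 0.40),
                       missing_mechanism = c("MCAR", "MAR"),
                       weight_dispersion = 0.3,
                       pregnancy_rate = 0.073,
                       seed = 1L) {
  if (is.null(race_proportions)) {
    p <- c(Multiracial = 0.058, White = 0.74, Black = 0.17,
           Asian = 0.032, `AI/NA` = 0.006)
    race_proportions <- p / sum(p)
  }
  if (is.null(ace_prevalence_by_race)) {
    ace_prevalence_by_race <- c(Multiracial = 0.35, White = 0.25,
                                Black = 0.33, Asian = 0.21, `AI/NA` = 0.40)
  }
  if (is.null(baseline_risk_by_outcome)) {
    baseline_risk_by_outcome <- c(
      mets = 0.28, hypertension = 0.47, asthma = 0.21, depression = 0.31,
      anxiety = 0.16, suicidal_ideation = 0.09, drug_use = 0.37)
  }
  if (is.null(true_rr)) true_rr <- default_true_rr()
  if (is.null(race_main_rr)) race_main_rr <- default_race_main_rr()
  cp <- default_confounder_params()
  if (!is.null(confounder_params)) cp[names(confounder_params)] <- confounder_params
  cfg <- structure(list(
    n_individuals = n_individuals,
    n_strata = n_strata,
    clusters_per_stratum = clusters_per_stratum,
    race_proportions = race_proportions,
    ace_prevalence_by_race = ace_prevalence_by_race,
    baseline_risk_by_outcome = baseline_risk_by_outcome,
    true_rr = true_rr,
    race_main_rr = race_main_rr,
    confounder_params = cp,
    missing_rates = missing_rates,
    missing_mechanism = match.arg(missing_mechanism),
    weight_dispersion = weight_dispersion,
    pregnancy_rate = pregnancy_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$n_individuals), length(cfg$n_individuals) == 1L,
            cfg$n_individuals >= 0, cfg$n_individuals == round(cfg$n_individuals))
  if (cfg$n_strata < 1 || cfg$clusters_per_stratum < 1) {
    stop("n_strata and clusters_per_stratum must be positive")
  }
  races <- race_levels()
  rp <- cfg$race_proportions
  if (!setequal(names(rp), races)) {
    stop("race_proportions must be named with exactly: ",
         paste(races, collapse = ", "))
  }
  if (abs(sum(rp) - 1) > 1e-9) stop("race_proportions must sum to 1")
  probs <- c(rp, cfg$ace_prevalence_by_race, cfg$baseline_risk_by_outcome,
             cfg$pregnancy_rate,
             cfg$missing_rates)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  for (m in list(cfg$true_rr, cfg$race_main_rr)) {
    if (!all(rownames(m) %in% outcome_names()) ||
        !setequal(colnames(m), races)) {
      stop("RR matrices must be outcome x race with canonical names")
    }
    if (any(m <= 0)) stop("all risk ratios must be > 0")
  }
  if (any(cfg$race_main_rr[, "Multiracial"] != 1)) {
    stop("race_main_rr must be 1 in the Multiracial referent column")
  }
  if (cfg$weight_dispersion < 0) stop("weight_dispersion must be >= 0")
  # refuse configurations whose cell risks exceed 1 even before covariates
  risks <- outer(rep(1, length(races)), cfg$baseline_risk_by_outcome)
  for (o in rownames(cfg$true_rr)) {
    r <- cfg$baseline_risk_by_outcome[[o]] * cfg$race_main_rr[o, ] *
      pmax(cfg$true_rr[o, ], 1)
    if (any(r > 1)) {
      bad <- names(r)[which.max(r)]
      stop(sprintf("implied risk %.3f > 1 for outcome '%s', race '%s'",
                   max(r), o, bad))
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d in %d strata x %d clusters, weight sdlog %.2f\n",
              x$n_individuals, x$n_strata, x$clusters_per_stratum,
              x$weight_dispersion))
  cat("  race proportions:",
      paste(sprintf("%s %.3f", names(x$race_proportions), x$race_proportions),
            collapse = ", "), "\n")
  cat("  elevated-ACE prevalence:",
      paste(sprintf("%s %.2f", names(x$ace_prevalence_by_race),
                    x$ace_prevalence_by_race), collapse = ", "), "\n")
  cat(sprintf("  outcomes: %s\n", paste(names(x$baseline_risk_by_outcome),
                                        collapse = ", ")))
  cat(sprintf("  missingness (%s): %s\n", x$missing_mechanism,
              paste(sprintf("%s %.2f", names(x$missing_rates),
                            x$missing_rates), collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields override the defaults of [sim_config()]; the matrices
#' `true_rr` and `race_main_rr` may be given as nested maps
#' (outcome -> race -> value).
#'
#' @param path path to a YAML file.
#' @return a `"sim_config"` object.
#' @export
sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("true_rr", "race_main_rr")) {
    if (!is.null(raw[[f]]) && is.list(raw[[f]])) {
      m <- do.call(rbind, lapply(raw[[f]], function(r) unlist(r)[race_levels()]))
      rownames(m) <- names(raw[[f]])
      raw[[f]] <- m
    }
  }
  for (f in c("race_proportions", "ace_prevalence_by_race",
              "baseline_risk_by_outcome", "missing_rates")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(sim_config, raw)
}
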