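#' Row-exclusion rules for the analysis sample
#'
#' Applies the global exclusions -- participants categorized as
#' Hispanic/Latino (race and Hispanic ethnicity cannot be jointly
#' enumerated) and as "Other" race alone (prohibitively small cell) -- and
#' reports, without removing, the count of pregnant participants, who are
#' excluded later but only from the biomarker-based models (MetS and
#' hypertension), since pregnancy shifts those biomarkers.
#'
#' @param cohort cohort data.frame with `race` and `pregnant` columns.
#' @return list: `cohort` (globally filtered), `log` (data.frame of rule /
#'   rows removed), `pregnant_excluded_outcomes` (outcomes from which
#'   pregnant rows are dropped at fit time).
#' @export
apply_exclusions <- function(cohort) {
  n0 <- nrow(cohort)
  drop_hisp <- !is.na(cohort$race) & cohort$race == "Hispanic/Latino"
  drop_other <- !is.na(cohort$race) & cohort$race == "Other"
  kept <- cohort[!(drop_hisp | drop_other), , drop = FALSE]
  n_preg <- sum(kept$pregnant == 1, na.rm = TRUE)
  log <- data.frame(
    rule = c("Hispanic/Latino", "Other alone",
             "pregnant (MetS/hypertension models only)"),
    rows_removed = c(sum(drop_hisp), sum(drop_other), n_preg),
    stringsAsFactors = FALSE
  )
  list(cohort = kept, log = log,
       pregnant_excluded_outcomes = c("mets", "hypertension"))
}

#' Configuration of an end-to-end analysis run
#'
#' @param input a [sim_config()] (cohort is generated) or a path to a
#'   cohort CSV written by [write_cohort()].
#' @param outcomes outcomes to model (default: all seven).
#' @param exposure `"elevated"` (>= 4 ACEs indicator, default) or
#'   `"score"` (continuous 0-10 summary score sensitivity analysis).
#' @param referent referent race for all interactions (default
#'   `"Multiracial"`; `"White"` for the sensitivity analysis).
#' @param covariates adjustment covariates (default: age, sex, parental
#'   education, equivalized income, parental support, neighborhood
#'   disadvantage).
#' @param m number of imputations (default 20).
#' @param n_resamples resamples for excess-case CIs (default 10000).
#' @param seed master seed; every stage derives its stream from it.
#' @param apply_missingness when `input` is a simulation config, mask
#'   values per its `missing_rates` before imputation (default TRUE).
#' @param biomarker_outcomes derive MetS/hypertension from biomarkers via
#'   [classify_mets()] instead of the generated indicators (default FALSE).
#' @param impute_iter chained-equation cycles (default 10).
#' @param standardization R00 standardization for [excess_cases()].
#' @param out_dir optional directory for delimited result tables and the
#'   run manifest.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(input,
                       outcomes = outcome_names(),
                       exposure = c("elevated", "score"),
                       referent = "Multiracial",
                       covariates = default_covariates(),
                       m = 20L,
                       n_resamples = 10000L,
                       seed = 1L,
                       apply_missingness = TRUE,
                       biomarker_outcomes = FALSE,
                       impute_iter = 10L,
                       standardization = c("reference", "marginal"),
                       out_dir = NULL) {
  bad <- setdiff(outcomes, outcome_names())
  if (length(bad)) stop("unknown outcome(s): ", paste(bad, collapse = ", "))
  if (!referent %in% race_levels()) stop("invalid referent race: ", referent)
  structure(list(
    input = input, outcomes = outcomes, exposure = match.arg(exposure),
    referent = referent, covariates = covariates, m = as.integer(m),
    n_resamples = as.integer(n_resamples), seed = as.integer(seed),
    apply_missingness = isTRUE(apply_missingness),
    biomarker_outcomes = isTRUE(biomarker_outcomes),
    impute_iter = as.integer(impute_iter),
    standardization = match.arg(standardization),
    out_dir = out_dir
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' A `simulation:` block is passed to [sim_config()]; otherwise
#' `cohort_path:` names the input file.  Remaining keys map to
#' [run_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `"run_config"`.
#' @export
run_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  input <- if (!is.null(raw$simulation)) {
    do.call(sim_config, raw$simulation)
  } else if (!is.null(raw$cohort_path)) {
    raw$cohort_path
  } else {
    stop("config must contain either 'simulation' or 'cohort_path'")
  }
  raw$simulation <- NULL
  raw$cohort_path <- NULL
  for (f in c("outcomes", "covariates")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(run_config, c(list(input = input), raw))
}

#' Run the full interaction analysis
#'
#' Orchestrates: ingest or simulate the cohort; apply exclusions; multiply
#' impute; derive the ACE score, composites, and adjustment covariates in
#' each completed dataset; fit one modified Poisson race-by-ACE interaction
#' model per outcome per imputation (pregnant participants dropped from
#' the MetS and hypertension fits); pool by Rubin's rules; and convert to
#' the three effect surfaces plus weighted descriptives.  Deterministic
#' given the configuration's seed.
#'
#' @param config a [run_config()].
#' @return object of class `"svyreri_report"`: list with `table1`
#'   (weighted descriptives by race), `table2` (within-group RRs),
#'   `table3` (interaction RRs), `table4` (excess cases per 1000),
#'   `pooled` (named list of pooled fits), `exclusions`, `manifest`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (inherits(config$input, "sim_config")) {
    cfg <- config$input
    ch <- generate_cohort(cfg)
    if (config$apply_missingness && any(cfg$missing_rates > 0)) {
      ch <- induce_missingness(ch, cfg)
    }
    ch
  } else {
    read_cohort(config$input)
  }

  excl <- apply_exclusions(cohort)
  cohort <- excl$cohort

  imp <- impute_chained(cohort, m = config$m, seed = config$seed + 17L,
                        max_iter = config$impute_iter)
  completed <- lapply(imp$imputations, derive_all,
                      biomarker_outcomes = config$biomarker_outcomes)
  race_order <- c(config$referent,
                  setdiff(race_levels(), config$referent))
  completed <- lapply(completed, function(d) {
    d$race <- factor(d$race, levels = intersect(race_order, unique(d$race)))
    d
  })

  design <- survey_design("stratum", "cluster", "weight")
  pooled <- list()
  for (o in config$outcomes) {
    fml <- build_model_formula(o, config$exposure, config$covariates)
    fits <- lapply(completed, function(d) {
      if (o %in% excl$pregnant_excluded_outcomes) {
        d <- d[d$pregnant == 0, , drop = FALSE]
      }
      mpreg(fml, d, design)
    })
    pooled[[o]] <- rubin_pool(fits, single_ok = config$m == 1L)
  }

  groups <- levels(completed[[1L]]$race)
  nonref <- setdiff(groups, config$referent)

  table2 <- do.call(rbind, lapply(config$outcomes, function(o) {
    cbind(outcome = o, within_group_rr(pooled[[o]]))
  })) %||% empty_effect_table()
  table3 <- do.call(rbind, lapply(config$outcomes, function(o) {
    cbind(outcome = o, interaction_rr(pooled[[o]]))
  })) %||% empty_effect_table()

  stacked <- do.call(rbind, completed)
  profile <- reference_profile(stacked, covariates = config$covariates)
  table4 <- do.call(rbind, lapply(seq_along(config$outcomes), function(i) {
    o <- config$outcomes[[i]]
    do.call(rbind, lapply(seq_along(nonref), function(j) {
      res <- excess_cases(
        pooled[[o]], nonref[[j]], baseline_profile = profile,
        n_resamples = config$n_resamples,
        seed = config$seed + 1000L * i + j,
        standardization = config$standardization)
      cbind(outcome = o, res)
    }))
  })) %||% empty_effect_table()

  table1 <- descriptive_table(completed)

  manifest <- list(
    package_version = as.character(utils::packageVersion("svyreri")),
    seed = config$seed,
    m = config$m,
    n_resamples = config$n_resamples,
    exposure = config$exposure,
    referent = config$referent,
    outcomes = config$outcomes,
    covariates = config$covariates,
    n_analysis = nrow(cohort),
    exclusions = excl$log,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  report <- structure(list(
    table1 = table1, table2 = table2, table3 = table3, table4 = table4,
    pooled = pooled, exclusions = excl$log, manifest = manifest,
    config = config
  ), class = "svyreri_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

empty_effect_table <- function() {
  data.frame(outcome = character(0), group = character(0),
             stringsAsFactors = FALSE)
}

# Stable hash of the configuration (md5 of its canonical YAML).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  if (inherits(cfg$input, "sim_config")) {
    cfg$input <- lapply(unclass(cfg$input), function(x) {
      if (is.matrix(x)) apply(x, 1L, as.list) else x
    })
  }
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

# Weighted descriptives by race, averaged across imputations.
descriptive_table <- function(completed) {
  groups <- levels(completed[[1L]]$race)
  stats_one <- function(d) {
    per_group <- lapply(groups, function(g) {
      rows <- d$race == g
      w <- d$weight[rows]
      c(pct_male = wmean(as.numeric(d$sex[rows] == "male"), w) * 100,
        mean_age = wmean(d$age[rows], w),
        mean_equivalized_income = wmean(d$equivalized_income[rows], w),
        mean_parental_support = wmean(d$parental_support_index[rows], w),
        mean_neighborhood_disadvantage =
          wmean(d$neighborhood_disadvantage[rows], w),
        pct_elevated_aces = wmean(d$elevated_aces[rows], w) * 100,
        vapply(outcome_names(), function(o) {
          if (!o %in% names(d)) return(NA_real_)
          wmean(d[[o]][rows], w) * 100
        }, numeric(1)))
    })
    do.call(rbind, per_group)
  }
  avg <- Reduce(`+`, lapply(completed, stats_one)) / length(completed)
  n_unweighted <- as.integer(table(completed[[1L]]$race)[groups])
  out <- data.frame(race = groups, n = n_unweighted, avg,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write report tables and manifest to a directory
#'
#' Emits `table1.csv` .. `table4.csv` and `manifest.json`.
#'
#' @param report a `"svyreri_report"`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in paste0("table", 1:4)) {
    utils::write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE, na = "")
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.svyreri_report <- function(x, ...) {
  cat("Race-by-ACE interaction analysis report\n")
  cat(sprintf("  n = %s, M = %d imputations, referent = %s, exposure = %s\n",
              x$manifest$n_analysis, x$manifest$m, x$manifest$referent,
              x$manifest$exposure))
  cat(sprintf("  outcomes: %s\n", paste(x$manifest$outcomes, collapse = ", ")))
  if (nrow(x$table4)) {
    cat("\nExcess cases per 1000 (vs referent):\n")
    print(x$table4[c("outcome", "group", "excess_cases", "ci_low", "ci_high")],
          digits = 3, row.names = FALSE)
  }
  invisible(x)
}
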