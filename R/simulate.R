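#' Per-item probability matching a target elevated-ACE prevalence
#'
#' ACE components are generated as exchangeable Bernoulli(p) draws; this
#' solves for the per-item probability p such that the dichotomized sum
#' satisfies P(sum >= threshold) = `prevalence` under Binomial(10, p).
#'
#' @param prevalence target probability of an elevated score.
#' @param n_items number of components (10).
#' @param threshold elevated means score >= threshold (4).
#' @return per-item probability in (0, 1).
#' @export
#' @examples
#' p <- ace_item_prob(0.25)
#' 1 - pbinom(3, 10, p)  # 0.25
ace_item_prob <- function(prevalence, n_items = 10L, threshold = 4L) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  if (prevalence == 0) return(0)
  if (prevalence == 1) return(1)
  f <- function(p) (1 - stats::pbinom(threshold - 1L, n_items, p)) - prevalence
  stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

# Biomarker location/scale constants (adult, late twenties); sex-shifted.
biomarker_defaults <- function() {
  list(
    systolic  = c(male = 121, female = 113, sd = 12),
    diastolic = c(male = 76,  female = 71,  sd = 9),
    waist     = c(male = 95,  female = 89,  sd = 14),
    trig_meanlog = c(male = log(110), female = log(90)), trig_sdlog = 0.45,
    hdl       = c(male = 47,  female = 55,  sd = 12),
    hba1c_mean = 5.35, hba1c_sd = 0.4,
    diag_rate = c(htn_diagnosis = 0.12, htn_medication = 0.06,
                  diabetes_diagnosis = 0.04, diabetes_medication = 0.03)
  )
}

#' Generate a synthetic survey cohort
#'
#' Draws a complete cohort under the configured stratified cluster design:
#' race from the configured composition; ten exchangeable ACE components
#' whose dichotomized sum hits the race-specific elevated prevalence in
#' expectation; six raw confounder blocks (age, sex, parental education for
#' two parents, household income and size, five parental-support Likert
#' items, five census-tract disadvantage proportions); biomarkers; a
#' pregnancy indicator (females only); and the seven binary outcomes drawn
#' Bernoulli under the log-linear risk model
#' `risk = baseline x race_main_rr x true_rr^(elevated ACEs) x covariate terms`.
#' Because the data-generating process is log-linear, the configured risk
#' ratios are exactly the estimands of the modified Poisson model fit by
#' [mpreg()].
#'
#' Sampling weights are log-normal with mean 1 within stratum; no
#' missingness is introduced here (see [induce_missingness()]).
#'
#' @param config a [sim_config()] object.
#' @param seed optional override of `config$seed`.
#' @return a `data.frame` with one row per participant and an attached
#'   `"schema"` attribute; deterministic given `(config, seed)`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  n <- as.integer(config$n_individuals)
  cols <- cohort_schema()
  if (n == 0L) {
    empty <- as.data.frame(lapply(cols$type, function(t) {
      switch(t, integer = integer(0), numeric = numeric(0),
             character = character(0))
    }), stringsAsFactors = FALSE)
    names(empty) <- cols$column
    attr(empty, "schema") <- cols
    return(empty)
  }
  with_seed(seed, {
    cp <- config$confounder_params
    bm <- biomarker_defaults()
    races <- race_levels()

    # design: rows assigned uniformly to strata, then to clusters
    stratum <- sample.int(config$n_strata, n, replace = TRUE)
    cluster_within <- sample.int(config$clusters_per_stratum, n, replace = TRUE)
    cluster <- (stratum - 1L) * config$clusters_per_stratum + cluster_within
    if (config$weight_dispersion > 0) {
      w <- stats::rlnorm(n, meanlog = -config$weight_dispersion^2 / 2,
                         sdlog = config$weight_dispersion)
      # normalize to mean 1 within stratum
      w <- w / ave(w, stratum, FUN = mean)
    } else {
      w <- rep(1, n)
    }

    race <- sample(names(config$race_proportions), n, replace = TRUE,
                   prob = config$race_proportions)

    item_p <- vapply(config$ace_prevalence_by_race, ace_item_prob, numeric(1))
    ace <- matrix(0L, n, 10L, dimnames = list(NULL, ace_cols()))
    for (r in races) {
      idx <- which(race == r)
      ace[idx, ] <- stats::rbinom(length(idx) * 10L, 1L, item_p[[r]])
    }
    ace_score <- rowSums(ace)
    elevated <- as.integer(ace_score >= 4L)

    age <- stats::rnorm(n, cp$age_mean, cp$age_sd)
    sex <- ifelse(stats::rbinom(n, 1L, cp$male_prob) == 1L, "male", "female")
    pedu1 <- sample.int(5L, n, replace = TRUE, prob = cp$parental_education_probs)
    pedu2 <- sample.int(5L, n, replace = TRUE, prob = cp$parental_education_probs)
    income <- stats::rlnorm(n, cp$income_meanlog, cp$income_sdlog)
    hh_size <- 1L + stats::rpois(n, cp$household_size_mean - 1)
    support <- matrix(sample.int(5L, n * 5L, replace = TRUE,
                                 prob = cp$support_probs),
                      n, 5L, dimnames = list(NULL, support_cols()))
    tract <- matrix(stats::rbeta(n * 5L, cp$tract_shape1, cp$tract_shape2),
                    n, 5L, dimnames = list(NULL, tract_cols()))

    male <- sex == "male"
    systolic <- stats::rnorm(n, ifelse(male, bm$systolic[["male"]],
                                       bm$systolic[["female"]]),
                             bm$systolic[["sd"]])
    diastolic <- stats::rnorm(n, ifelse(male, bm$diastolic[["male"]],
                                        bm$diastolic[["female"]]),
                              bm$diastolic[["sd"]])
    waist <- stats::rnorm(n, ifelse(male, bm$waist[["male"]],
                                    bm$waist[["female"]]), bm$waist[["sd"]])
    trig <- stats::rlnorm(n, ifelse(male, bm$trig_meanlog[["male"]],
                                    bm$trig_meanlog[["female"]]), bm$trig_sdlog)
    hdl <- pmax(stats::rnorm(n, ifelse(male, bm$hdl[["male"]],
                                       bm$hdl[["female"]]), bm$hdl[["sd"]]), 5)
    hba1c <- stats::rnorm(n, bm$hba1c_mean, bm$hba1c_sd)
    diag <- sapply(bm$diag_rate, function(p) stats::rbinom(n, 1L, p))
    pregnant <- integer(n)
    pregnant[!male] <- stats::rbinom(sum(!male), 1L, config$pregnancy_rate)

    # optional covariate log-RR terms act on centered derived covariates
    cov_lp <- function(outcome) {
      eff <- cp$covariate_log_rr[[outcome]]
      if (is.null(eff) || length(eff) == 0L) return(rep(0, n))
      derived <- data.frame(
        age = age,
        male = as.numeric(male),
        equivalized_income = income / sqrt(hh_size),
        parental_education_max = pmax(pedu1, pedu2),
        parental_support_index = rowMeans(support),
        neighborhood_disadvantage = rowMeans(tract)
      )
      lp <- rep(0, n)
      for (v in names(eff)) {
        if (!v %in% names(derived)) {
          stop("unknown covariate in covariate_log_rr: ", v)
        }
        lp <- lp + eff[[v]] * (derived[[v]] - mean(derived[[v]]))
      }
      lp
    }

    out <- matrix(NA_integer_, n, length(outcome_names()),
                  dimnames = list(NULL, outcome_names()))
    for (o in outcome_names()) {
      risk <- config$baseline_risk_by_outcome[[o]] *
        config$race_main_rr[o, race] *
        ifelse(elevated == 1L, config$true_rr[o, race], 1) *
        exp(cov_lp(o))
      if (any(risk > 1)) {
        bad <- which.max(risk)
        stop(sprintf(
          "implied risk %.3f > 1 for outcome '%s' in cell race '%s', elevated=%d",
          risk[bad], o, race[bad], elevated[bad]))
      }
      out[, o] <- stats::rbinom(n, 1L, risk)
    }

    cohort <- data.frame(
      id = seq_len(n), stratum = stratum, cluster = cluster, weight = w,
      race = race,
      ace, age = age, sex = sex,
      parent1_education = pedu1, parent2_education = pedu2,
      household_income = income, household_size = hh_size,
      support, tract,
      systolic = systolic, diastolic = diastolic, waist = waist,
      triglycerides = trig, hdl = hdl, hba1c = hba1c,
      diag, pregnant = pregnant,
      out,
      stringsAsFactors = FALSE, check.names = FALSE
    )
    attr(cohort, "schema") <- cols
    cohort
  })
}

cohort_schema <- function() {
  cols <- c("id", "stratum", "cluster", "weight", "race",
            ace_cols(), covariate_raw_cols(), biomarker_cols(),
            "pregnant", outcome_names())
  type <- ifelse(cols %in% c("race", "sex"), "character",
          ifelse(cols %in% c("id", "stratum", "cluster", "parent1_education",
                             "parent2_education", "household_size",
                             support_cols(), ace_cols(), "pregnant",
                             "htn_diagnosis", "htn_medication",
                             "diabetes_diagnosis", "diabetes_medication",
                             outcome_names()),
                 "integer", "numeric"))
  data.frame(column = cols, type = type, stringsAsFactors = FALSE)
}

# Column classes addressed by the row-level missingness rates.
missingness_classes <- function() {
  list(ace = ace_cols(),
       covariate = covariate_raw_cols(),
       outcome = c(outcome_names(), biomarker_cols()))
}

#' Mask cohort values to emulate survey missingness
#'
#' Rates named `ace`, `covariate` or `outcome` are row-level: the given
#' fraction of rows gets at least one masked variable of that class (a
#' random non-empty subset of the class's columns).  A rate named after a
#' specific column masks that column element-wise.  Under `"MCAR"` rows are
#' chosen uniformly; under `"MAR"` the choice depends on race (non-White
#' rows more likely) and parental education (lower education more likely),
#' with the intercept calibrated so the marginal rate is preserved.  Design
#' variables (stratum, cluster, weight) are never maskable.
#'
#' @param cohort a cohort `data.frame` from [generate_cohort()] or
#'   [read_cohort()].
#' @param config a [sim_config()] (uses `missing_rates` and
#'   `missing_mechanism`), or a bare named numeric vector of rates.
#' @param seed RNG seed; default derives from the config seed.
#' @return the cohort with values replaced by `NA`.
#' @export
induce_missingness <- function(cohort, config, seed = NULL) {
  if (is.numeric(config) && !is.null(names(config))) {
    config <- list(missing_rates = config, missing_mechanism = "MCAR",
                   seed = 1L)
  }
  rates <- config$missing_rates
  if (any(rates < 0 | rates > 1)) stop("missing rates must lie in [0, 1]")
  protected <- c("id", "stratum", "cluster", "weight")
  if (any(names(rates) %in% protected)) {
    stop("design variables (stratum/cluster/weight) cannot be masked")
  }
  classes <- missingness_classes()
  n <- nrow(cohort)
  if (n == 0L || all(rates == 0)) return(cohort)
  with_seed(seed %||% (config$seed + 104729L), {
    mechanism <- config$missing_mechanism %||% "MCAR"
    row_prob <- function(rate) {
      if (rate == 0) return(rep(0, n))
      if (identical(mechanism, "MAR")) {
        # logit-linear in race and parental education, calibrated by uniroot
        z <- 0.8 * (cohort$race != "White") -
          0.3 * (pmax(cohort$parent1_education, cohort$parent2_education) - 3)
        f <- function(a) mean(stats::plogis(a + z)) - rate
        a <- stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
        stats::plogis(a + z)
      } else {
        rep(rate, n)
      }
    }
    for (nm in names(rates)) {
      rate <- rates[[nm]]
      if (rate == 0) next
      if (nm %in% names(classes)) {
        cols <- intersect(classes[[nm]], names(cohort))
        hit <- which(stats::runif(n) < row_prob(rate))
        if (length(hit)) {
          # each flagged row masks a random subset of the class's columns
          # (each column w.p. 0.15, at least one forced)
          m <- matrix(stats::runif(length(hit) * length(cols)) < 0.15,
                      nrow = length(hit))
          none <- which(rowSums(m) == 0L)
          if (length(none)) {
            m[cbind(none, sample.int(length(cols), length(none),
                                     replace = TRUE))] <- TRUE
          }
          for (j in seq_along(cols)) {
            rows <- hit[m[, j]]
            if (length(rows)) cohort[[cols[j]]][rows] <- NA
          }
        }
      } else if (nm %in% names(cohort)) {
        hit <- stats::runif(n) < row_prob(rate)
        cohort[[nm]][hit] <- NA
      } else {
        stop("unknown missingness target: ", nm)
      }
    }
    cohort
  })
}

#' Write / read a cohort as delimited text with a sidecar schema
#'
#' Cohorts are stored as comma-separated text with a header row and empty
#' fields for missing values, plus a YAML sidecar (`<path>.schema.yml`)
#' recording column names and types so a round trip restores classes.
#'
#' @param cohort a cohort `data.frame`.
#' @param path output CSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  schema <- attr(cohort, "schema") %||% cohort_schema()
  yaml::write_yaml(
    list(columns = as.list(stats::setNames(schema$type, schema$column))),
    paste0(path, ".schema.yml"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  schema_path <- paste0(path, ".schema.yml")
  if (file.exists(schema_path)) {
    sch <- yaml::read_yaml(schema_path)$columns
    colClasses <- vapply(sch, identity, character(1))
    cohort <- utils::read.csv(path, na.strings = "", check.names = FALSE,
                              colClasses = colClasses)
    attr(cohort, "schema") <- data.frame(column = names(sch),
                                         type = unname(colClasses),
                                         stringsAsFactors = FALSE)
  } else {
    cohort <- utils::read.csv(path, na.strings = "", check.names = FALSE)
  }
  bad <- cohort$race[!cohort$race %in% ingest_race_levels() & !is.na(cohort$race)]
  if (length(bad)) stop("unknown race categories: ",
                        paste(unique(bad), collapse = ", "))
  if (any(cohort$weight <= 0, na.rm = TRUE) || anyNA(cohort$weight)) {
    stop("sampling weights must be present and strictly positive")
  }
  cohort
}
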