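# Shared fixtures: all built in code, no stored data.

# Deterministic 2x2 cohort: exposed n1 with p1*n1 cases, unexposed n0 with
# p0*n0 cases; independent rows (own cluster each), one stratum.
toy_2x2 <- function(n1 = 100, p1 = 0.30, n0 = 100, p0 = 0.10) {
  y <- c(rep(1, round(n1 * p1)), rep(0, n1 - round(n1 * p1)),
         rep(1, round(n0 * p0)), rep(0, n0 - round(n0 * p0)))
  data.frame(y = y, x = rep(c(1, 0), c(n1, n0)),
             stratum = 1L, cluster = seq_along(y), weight = 1)
}

# Deterministic saturated race-by-exposure cohort with exact cell risks.
# `risks` is a named vector c("00","01","10","11") -> risk, first index is
# group (0 = referent), second exposure.
toy_cells <- function(risks, n_cell = 2000, group = "Asian",
                      referent = "Multiracial") {
  cells <- expand.grid(g = c(0, 1), e = c(0, 1))
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    r <- risks[[paste0(cells$g[i], cells$e[i])]]
    ny <- round(n_cell * r)
    data.frame(y = rep(c(1, 0), c(ny, n_cell - ny)),
               g = cells$g[i], e = cells$e[i])
  }))
  rows$race <- factor(ifelse(rows$g == 1, group, referent),
                      levels = c(referent, group))
  rows$elevated_aces <- rows$e
  rows$stratum <- 1L
  rows$cluster <- seq_len(nrow(rows))
  rows$weight <- 1
  rows
}

# Hand-built pooled-fit-like object from named log-scale coefficients, for
# exercising the interaction surface functions without a data fit.
mock_fit <- function(coefs, vcov = NULL,
                     races = c("Multiracial", "White", "Black", "Asian",
                               "AI/NA")) {
  p <- length(coefs)
  if (is.null(vcov)) vcov <- diag(1e-4, p)
  dimnames(vcov) <- list(names(coefs), names(coefs))
  structure(list(coefficients = coefs, vcov = vcov,
                 terms = stats::terms(y ~ elevated_aces * race),
                 xlevels = list(race = races), contrasts = NULL,
                 n = NA_integer_),
            class = "mpreg")
}

# Coefficient vector encoding printed within-group RRs (referent RR for the
# exposure main effect, log-ratio interactions for the other groups).
coefs_from_rrs <- function(rr_ref, rr_groups) {
  co <- c(`(Intercept)` = log(0.1), elevated_aces = log(rr_ref))
  for (g in names(rr_groups)) {
    co[[paste0("race", g)]] <- 0
    co[[paste0("elevated_aces:race", g)]] <- log(rr_groups[[g]]) - log(rr_ref)
  }
  co
}

# Simulation config with comfortable cell sizes for small-n pipeline tests:
# balanced race mix, elevated-ACE prevalence ~1/3, risks bounded away from
# 0 and 1 so log-link fits cannot hit empty outcome cells.
balanced_config <- function(n = 1500, seed = 1, ...) {
  props <- c(Multiracial = 0.30, White = 0.30, Black = 0.20,
             Asian = 0.12, `AI/NA` = 0.08)
  ones <- matrix(1, 7, 5,
                 dimnames = list(outcome_names(), names(props)))
  base <- c(mets = 0.30, hypertension = 0.40, asthma = 0.25,
            depression = 0.30, anxiety = 0.25, suicidal_ideation = 0.20,
            drug_use = 0.35)
  sim_config(n_individuals = n, seed = seed,
             race_proportions = props,
             ace_prevalence_by_race = c(Multiracial = 0.35, White = 0.30,
                                        Black = 0.33, Asian = 0.30,
                                        `AI/NA` = 0.35),
             baseline_risk_by_outcome = base,
             true_rr = ones, race_main_rr = ones, ...)
}

# Two-group config with exact cell risks (referent + one group), used for
# excess-case recovery: risks named as in toy_cells().
two_group_config <- function(risks, group = "Asian", n = 12000, seed = 1,
                             ace_prev = c(ref = 0.35, grp = 0.21),
                             outcome = "anxiety") {
  props <- stats::setNames(rep(0, 5), race_levels())
  props["Multiracial"] <- 0.5
  props[group] <- 0.5
  prev <- stats::setNames(rep(0.3, 5), race_levels())
  prev["Multiracial"] <- ace_prev[["ref"]]
  prev[group] <- ace_prev[["grp"]]
  true_rr <- default_true_rr_safe()
  main_rr <- true_rr; main_rr[] <- 1
  true_rr[] <- 1
  true_rr[outcome, "Multiracial"] <- risks[["01"]] / risks[["00"]]
  true_rr[outcome, group] <- risks[["11"]] / risks[["10"]]
  main_rr[outcome, group] <- risks[["10"]] / risks[["00"]]
  base <- stats::setNames(rep(0.2, 7), outcome_names())
  base[outcome] <- risks[["00"]]
  sim_config(n_individuals = n, seed = seed, race_proportions = props,
             ace_prevalence_by_race = prev,
             baseline_risk_by_outcome = base,
             true_rr = true_rr, race_main_rr = main_rr)
}

# A biomarker record with every value below every cutoff, overridable
# field by field.
make_record <- function(...) {
  base <- data.frame(systolic = 110, diastolic = 70, waist = 80,
                     triglycerides = 100, hdl = 60, hba1c = 5.0,
                     htn_diagnosis = 0L, htn_medication = 0L,
                     diabetes_diagnosis = 0L, diabetes_medication = 0L)
  mod <- list(...)
  for (v in names(mod)) base[[v]] <- mod[[v]]
  base
}

flat_cutoffs <- function(trig_m = 150, trig_f = 170, hdl_m = 40, hdl_f = 45) {
  structure(list(male = list(triglycerides = trig_m, hdl = hdl_m),
                 female = list(triglycerides = trig_f, hdl = hdl_f)),
            class = "decile_cutoffs")
}

default_true_rr_safe <- function() {
  m <- matrix(1, 7, 5, dimnames = list(outcome_names(), race_levels()))
  m
}
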