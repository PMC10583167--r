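test_that("empty configuration yields an empty table with the full schema", {
  cfg <- sim_config(n_individuals = 0)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch), 0L)
  expect_setequal(names(ch), svyreri:::cohort_schema()$column)
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- balanced_config(n = 400, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a, c2))
})

test_that("per-item ACE probability inverts the binomial tail", {
  for (prev in c(0.05, 0.21, 0.35, 0.40, 0.8)) {
    p <- ace_item_prob(prev)
    expect_equal(1 - pbinom(3, 10, p), prev, tolerance = 1e-9)
  }
  expect_equal(ace_item_prob(0), 0)
  expect_equal(ace_item_prob(1), 1)
})

test_that("weighted race shares and ACE prevalences match the configuration", {
  cfg <- sim_config(n_individuals = 50000, seed = 7)
  ch <- generate_cohort(cfg)
  shares <- prop.table(tapply(ch$weight, ch$race, sum))
  for (r in race_levels()) {
    target <- cfg$race_proportions[[r]]
    se <- sqrt(target * (1 - target) / nrow(ch))
    expect_lt(abs(shares[[r]] - target), 3.5 * se)
  }
  elevated <- compute_ace(ch[svyreri:::ace_cols()])$elevated
  for (r in race_levels()) {
    rows <- ch$race == r
    target <- cfg$ace_prevalence_by_race[[r]]
    se <- sqrt(target * (1 - target) / sum(rows))
    expect_lt(abs(mean(elevated[rows]) - target), 3.5 * se)
  }
})

test_that("null risk ratios give a crude weighted RR near 1", {
  ones <- matrix(1, 7, 5, dimnames = list(outcome_names(), race_levels()))
  cfg <- sim_config(n_individuals = 50000, seed = 13,
                    true_rr = ones, race_main_rr = ones)
  ch <- generate_cohort(cfg)
  elevated <- compute_ace(ch[svyreri:::ace_cols()])$elevated
  for (o in c("asthma", "depression")) {
    p1 <- weighted.mean(ch[[o]][elevated == 1], ch$weight[elevated == 1])
    p0 <- weighted.mean(ch[[o]][elevated == 0], ch$weight[elevated == 0])
    expect_gt(p1 / p0, 0.97)
    expect_lt(p1 / p0, 1.03)
  }
})

test_that("marginal outcome prevalence matches brute-force mixing of the risk model", {
  cfg <- sim_config(n_individuals = 50000, seed = 19)
  ch <- generate_cohort(cfg)
  for (o in c("asthma", "anxiety", "mets")) {
    implied <- sum(vapply(race_levels(), function(r) {
      pe <- cfg$ace_prevalence_by_race[[r]]
      base <- cfg$baseline_risk_by_outcome[[o]] * cfg$race_main_rr[o, r]
      cfg$race_proportions[[r]] *
        (pe * base * cfg$true_rr[o, r] + (1 - pe) * base)
    }, numeric(1)))
    observed <- weighted.mean(ch[[o]], ch$weight)
    se <- sqrt(implied * (1 - implied) / nrow(ch))
    expect_lt(abs(observed - implied), 3.5 * se)
  }
})

test_that("generation refuses cell risks above 1 and bad sizes", {
  rr <- matrix(1, 7, 5, dimnames = list(outcome_names(), race_levels()))
  rr["asthma", "AI/NA"] <- 6
  main <- rr; main[] <- 1
  expect_error(
    sim_config(baseline_risk_by_outcome = c(
      mets = 0.28, hypertension = 0.47, asthma = 0.30, depression = 0.31,
      anxiety = 0.16, suicidal_ideation = 0.09, drug_use = 0.37),
      true_rr = rr, race_main_rr = main),
    "asthma.*AI/NA")
  expect_error(sim_config(n_individuals = -5))
  expect_error(sim_config(n_strata = 0))
})

test_that("weights are positive, mean 1 within stratum, and clusters nest", {
  cfg <- balanced_config(n = 3000, seed = 5, weight_dispersion = 0.5)
  ch <- generate_cohort(cfg)
  expect_true(all(ch$weight > 0))
  means <- tapply(ch$weight, ch$stratum, mean)
  expect_equal(as.vector(means), rep(1, length(means)), tolerance = 1e-12)
  nesting <- unique(ch[c("stratum", "cluster")])
  expect_false(anyDuplicated(nesting$cluster) > 0)
})

test_that("zero missingness rates leave the cohort untouched", {
  ch <- generate_cohort(balanced_config(n = 300, seed = 2))
  out <- induce_missingness(ch, c(ace = 0, covariate = 0, outcome = 0))
  expect_identical(out, ch)
})

test_that("row-level masked fractions match configured class rates", {
  cfg <- balanced_config(n = 20000, seed = 31)
  ch <- generate_cohort(cfg)
  masked <- induce_missingness(ch, cfg)  # default rates .55/.21/.40
  classes <- svyreri:::missingness_classes()
  targets <- c(ace = 0.55, covariate = 0.21, outcome = 0.40)
  for (cl in names(targets)) {
    cols <- intersect(classes[[cl]], names(masked))
    frac <- mean(apply(is.na(masked[cols]), 1L, any))
    se <- sqrt(targets[[cl]] * (1 - targets[[cl]]) / nrow(masked))
    expect_lt(abs(frac - targets[[cl]]), 3.5 * se)
  }
})

test_that("MCAR masking preserves the complete-case distribution", {
  cfg <- balanced_config(n = 20000, seed = 37)
  ch <- generate_cohort(cfg)
  masked <- induce_missingness(ch, c(age = 0.5))
  cc <- masked$age[!is.na(masked$age)]
  se <- sd(ch$age) * sqrt(1 / length(cc) + 1 / nrow(ch))
  expect_lt(abs(mean(cc) - mean(ch$age)), 3.5 * se)
})

test_that("MAR masking hits the marginal rate but depends on covariates", {
  cfg <- balanced_config(n = 20000, seed = 41,
                         missing_mechanism = "MAR",
                         missing_rates = c(age = 0.3))
  ch <- generate_cohort(cfg)
  masked <- induce_missingness(ch, cfg)
  miss <- is.na(masked$age)
  expect_lt(abs(mean(miss) - 0.3), 3.5 * sqrt(0.3 * 0.7 / nrow(ch)))
  # non-White rows must be masked more often by construction
  expect_gt(mean(miss[ch$race != "White"]), mean(miss[ch$race == "White"]))
})

test_that("design variables can never be masked", {
  ch <- generate_cohort(balanced_config(n = 100, seed = 3))
  expect_error(induce_missingness(ch, c(weight = 0.5)), "design variables")
  expect_error(induce_missingness(ch, c(stratum = 0.5)), "design variables")
})

test_that("cohort round-trips through delimited text with schema sidecar", {
  ch <- generate_cohort(balanced_config(n = 200, seed = 8))
  ch <- induce_missingness(ch, c(covariate = 0.3))
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort(ch, path)
  back <- read_cohort(path)
  expect_equal(back$age, ch$age, tolerance = 1e-12)
  expect_identical(back$race, ch$race)
  expect_identical(is.na(back$parent1_education), is.na(ch$parent1_education))
})
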