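test_that("ACE score sums components and dichotomizes at four", {
  expect_equal(compute_ace(rep(1, 10)), list(score = 10L, elevated = 1L))
  expect_equal(compute_ace(rep(0, 10)), list(score = 0L, elevated = 0L))
  four <- c(rep(1, 4), rep(0, 6))
  three <- c(rep(1, 3), rep(0, 7))
  expect_equal(compute_ace(four)$elevated, 1L)
  expect_equal(compute_ace(four)$score, 4L)
  expect_equal(compute_ace(three)$elevated, 0L)
  expect_equal(compute_ace(three)$score, 3L)
})

test_that("ACE score is permutation invariant and rejects bad input", {
  set.seed(11)
  for (i in 1:25) {
    comp <- rbinom(10, 1, 0.4)
    expect_identical(compute_ace(comp), compute_ace(sample(comp)))
  }
  expect_error(compute_ace(c(rep(1, 9), NA)), "after imputation")
  expect_error(compute_ace(rep(1, 9)), "10 ACE components")
  expect_error(compute_ace(c(rep(1, 9), 2)), "binary")
})

test_that("weighted quantile is the left-continuous inverse CDF", {
  expect_equal(weighted_quantile(1:100, 1, 0.7), 70)
  expect_equal(weighted_quantile(rep(3.5, 40), 1, c(0.2, 0.7, 0.9)),
               rep(3.5, 3))
  set.seed(21)
  x <- rnorm(1000)
  for (p in c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)) {
    expect_equal(weighted_quantile(x, 1, p),
                 unname(quantile(x, p, type = 1)))
  }
  # weight-scale invariance
  w <- runif(1000, 0.5, 2)
  expect_equal(weighted_quantile(x, w, 0.7), weighted_quantile(x, 13 * w, 0.7))
})

test_that("decile cutoffs are sex-specific and demand enough data", {
  n <- 400
  d <- data.frame(sex = rep(c("male", "female"), each = n / 2),
                  triglycerides = c(1:200, 1001:1200),
                  hdl = c(seq(30, 70, length.out = 200),
                          seq(35, 75, length.out = 200)),
                  weight = 1)
  cuts <- decile_cutoffs(d)
  expect_equal(cuts$male$triglycerides, 140)    # 7th decile of 1..200
  expect_equal(cuts$female$triglycerides, 1160) # 8th decile of 1001..1200
  expect_lt(cuts$male$hdl, cuts$female$hdl)
  tiny <- d[c(1:5, 201:205), ]
  expect_error(decile_cutoffs(tiny), "fewer than 10")
})

test_that("metabolic syndrome requires three of five positive categories", {
  cuts <- flat_cutoffs()
  # male: hypertension + waist + triglycerides positive -> MetS
  rec <- make_record(systolic = 135, waist = 110, triglycerides = 160)
  expect_equal(classify_mets(rec, "male", cuts), 1L)
  # everything below every cutoff -> negative
  expect_equal(classify_mets(make_record(), "male", cuts), 0L)
  # female at the systolic boundary: hypertension positive (>= 130) but
  # only one category -> negative overall
  rec2 <- make_record(systolic = 130, diastolic = 70)
  expect_equal(classify_mets(rec2, "female", cuts), 0L)
  expect_equal(svyreri:::htn_positive(rec2), 1L)
  # sex-specific waist rule: 90 cm is positive for females only
  rec3 <- make_record(waist = 90, triglycerides = 180, hba1c = 6.0)
  expect_equal(classify_mets(rec3, "female", cuts), 1L)
  expect_equal(classify_mets(rec3, "male", cuts), 0L)
  expect_error(classify_mets(make_record(), "unknown", cuts), "sex")
})

test_that("worsening any biomarker never flips MetS positive to negative", {
  cuts <- flat_cutoffs()
  set.seed(31)
  for (i in 1:50) {
    rec <- make_record(
      systolic = runif(1, 100, 150), diastolic = runif(1, 60, 95),
      waist = runif(1, 70, 115), triglycerides = runif(1, 80, 220),
      hdl = runif(1, 30, 70), hba1c = runif(1, 4.8, 6.3),
      htn_diagnosis = rbinom(1, 1, 0.2),
      diabetes_medication = rbinom(1, 1, 0.2))
    sex <- sample(c("male", "female"), 1)
    before <- classify_mets(rec, sex, cuts)
    worse <- rec
    worse$systolic <- rec$systolic + 30
    worse$waist <- rec$waist + 20
    worse$triglycerides <- rec$triglycerides + 100
    worse$hdl <- rec$hdl - 20
    worse$hba1c <- rec$hba1c + 1
    expect_gte(classify_mets(worse, sex, cuts), before)
  }
})

test_that("hypertension mirrors the MetS blood-pressure category", {
  expect_equal(classify_hypertension(make_record(diastolic = 80)), 1L)
  expect_equal(classify_hypertension(make_record(systolic = 129,
                                                 diastolic = 79)), 0L)
  expect_equal(classify_hypertension(make_record(htn_medication = 1L)), 1L)
  expect_equal(classify_hypertension(make_record(htn_diagnosis = 1L)), 1L)
  expect_error(classify_hypertension(make_record(systolic = NA)),
               "after imputation")
})

test_that("covariate derivation follows the stated formulas", {
  rec <- data.frame(age = 29, sex = "female",
                    parent1_education = 4, parent2_education = 3,
                    household_income = 100, household_size = 4,
                    support_1 = 3, support_2 = 3, support_3 = 4,
                    support_4 = 3, support_5 = 4,
                    tract_1 = 0.2, tract_2 = 0.2, tract_3 = 0.2,
                    tract_4 = 0.2, tract_5 = 0.2)
  cov <- derive_covariates(rec)
  expect_equal(cov$equivalized_income, 50)
  expect_equal(cov$parental_education_max, 4)   # "some college" wins
  expect_equal(cov$parental_support_index, mean(c(3, 3, 4, 3, 4)))
  expect_equal(cov$neighborhood_disadvantage, 0.2)
  bad <- rec; bad$household_size <- 0
  expect_error(derive_covariates(bad), "household size")
  bad2 <- rec; bad2$tract_3 <- 1.4
  expect_error(derive_covariates(bad2), "tract proportions")
})

test_that("decile cutoffs with unit weights equal the unweighted oracle", {
  set.seed(41)
  n <- 1000
  d <- data.frame(sex = sample(c("male", "female"), n, replace = TRUE),
                  triglycerides = rlnorm(n, log(100), 0.5),
                  hdl = rnorm(n, 50, 12), weight = 1)
  cuts <- decile_cutoffs(d)
  for (s in c("male", "female")) {
    rows <- d$sex == s
    p_trig <- if (s == "male") 0.7 else 0.8
    p_hdl <- if (s == "male") 0.2 else 0.3
    expect_equal(cuts[[s]]$triglycerides,
                 unname(quantile(d$triglycerides[rows], p_trig, type = 1)))
    expect_equal(cuts[[s]]$hdl,
                 unname(quantile(d$hdl[rows], p_hdl, type = 1)))
  }
})
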