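null_fit <- function() {
  mock_fit(coefs_from_rrs(1, c(White = 1, Black = 1, Asian = 1,
                               `AI/NA` = 1)))
}

test_that("a null model gives unit risk ratios in every group", {
  rrs <- within_group_rr(null_fit())
  expect_equal(rrs$rr, rep(1, 5))
  irr <- interaction_rr(null_fit())
  expect_equal(irr$rr, rep(1, 5))
})

test_that("within-group RR combines exposure and interaction coefficients", {
  fit <- mock_fit(c(`(Intercept)` = log(0.1),
                    elevated_aces = log(1.13),
                    raceWhite = 0.2,
                    `elevated_aces:raceWhite` = log(0.92)))
  rrs <- within_group_rr(fit, c("Multiracial", "White"))
  expect_equal(rrs$rr[rrs$group == "Multiracial"], 1.13, tolerance = 1e-12)
  expect_equal(rrs$rr[rrs$group == "White"], 1.13 * 0.92, tolerance = 1e-12)
  expect_equal(round(rrs$rr[rrs$group == "White"], 2), 1.04)
  expect_error(within_group_rr(fit, "Martian"), "unknown group")
})

test_that("interval matches an independent delta-method recomputation", {
  set.seed(3)
  A <- matrix(rnorm(25), 5)
  v <- crossprod(A) / 10
  co <- c(`(Intercept)` = -2, elevated_aces = 0.12, raceWhite = 0.05,
          `elevated_aces:raceWhite` = -0.08, junk = 0.4)
  dimnames(v) <- list(names(co), names(co))
  fit <- mock_fit(co, v)
  rr <- within_group_rr(fit, "White")
  cvec <- c(0, 1, 0, 1, 0)
  se_oracle <- sqrt(drop(t(cvec) %*% v %*% cvec))
  est_oracle <- sum(cvec * co)
  expect_equal(rr$log_se, se_oracle, tolerance = 1e-10)
  expect_equal(rr$rr, exp(est_oracle), tolerance = 1e-10)
  expect_equal(rr$ci_low, exp(est_oracle - qnorm(0.975) * se_oracle),
               tolerance = 1e-10)
})

test_that("interaction RR is the ratio of within-group RRs (model identity)", {
  fit <- mock_fit(coefs_from_rrs(1.13, c(White = 1.04, Black = 1.02,
                                         Asian = 1.00, `AI/NA` = 1.15)))
  wg <- within_group_rr(fit)
  ir <- interaction_rr(fit)
  ref_rr <- wg$rr[wg$group == "Multiracial"]
  for (g in c("White", "Black", "Asian", "AI/NA")) {
    expect_equal(ir$rr[ir$group == g] * ref_rr, wg$rr[wg$group == g],
                 tolerance = 1e-12)
  }
  expect_equal(ir$rr[ir$group == "Multiracial"], 1)
  expect_true(ir$referent[ir$group == "Multiracial"])
})

test_that("RERI follows the three shared-baseline risk ratios", {
  fit <- mock_fit(c(`(Intercept)` = log(0.1),
                    elevated_aces = log(2.0),
                    raceAsian = log(1.5),
                    `elevated_aces:raceAsian` = log(4.0 / (2.0 * 1.5))),
                  races = c("Multiracial", "Asian"))
  # RR_g1 = 4, RR_g0 = 1.5, RR_ref1 = 2 -> RERI = 4 - 1.5 - 2 + 1 = 1.5
  expect_equal(reri(fit, "Asian"), 1.5, tolerance = 1e-12)
  expect_error(reri(fit, "Multiracial"), "referent")
})

test_that("excess cases recover the enumerated interaction contrast", {
  risks <- c("00" = 0.10, "01" = 0.20, "10" = 0.15, "11" = 0.40)
  d <- toy_cells(risks, n_cell = 4000)
  fit <- mpreg(y ~ elevated_aces * race, d)
  pooled <- rubin_pool(list(fit), single_ok = TRUE)
  ec <- excess_cases(pooled, "Asian", data.frame(dummy = 1),
                     n_resamples = 2000, seed = 2)
  # IC = .40 - .15 - .20 + .10 = .15 -> 150 per 1000, exactly on the
  # saturated model
  expect_equal(ec$excess_cases, 150, tolerance = 1e-6)
  expect_equal(ec$r00, 0.10, tolerance = 1e-9)
  expect_true(ec$ci_low < 150 && 150 < ec$ci_high)
})

test_that("null interaction yields zero excess cases with a covering CI", {
  fit <- mock_fit(coefs_from_rrs(1, c(White = 1, Black = 1, Asian = 1,
                                      `AI/NA` = 1)),
                  vcov = diag(1e-3, 10))
  ec <- excess_cases(fit, "White", data.frame(dummy = 1),
                     n_resamples = 2000, seed = 7)
  expect_equal(ec$excess_cases, 0, tolerance = 1e-9)
  expect_true(ec$ci_low < 0 && 0 < ec$ci_high)
})

test_that("resampling CIs are seed-reproducible and stable in n_resamples", {
  risks <- c("00" = 0.10, "01" = 0.20, "10" = 0.15, "11" = 0.40)
  d <- toy_cells(risks, n_cell = 2000)
  fit <- mpreg(y ~ elevated_aces * race, d)
  pooled <- rubin_pool(list(fit), single_ok = TRUE)
  a <- excess_cases(pooled, "Asian", data.frame(dummy = 1),
                    n_resamples = 10000, seed = 42)
  b <- excess_cases(pooled, "Asian", data.frame(dummy = 1),
                    n_resamples = 10000, seed = 42)
  expect_identical(a, b)
  big <- excess_cases(pooled, "Asian", data.frame(dummy = 1),
                      n_resamples = 20000, seed = 42)
  expect_lt(abs(big$ci_low - a$ci_low) / abs(a$ci_low), 0.02)
  expect_lt(abs(big$ci_high - a$ci_high) / abs(a$ci_high), 0.02)
})

test_that("resampling and delta-method intervals agree in width on a toy fit", {
  risks <- c("00" = 0.10, "01" = 0.20, "10" = 0.15, "11" = 0.40)
  d <- toy_cells(risks, n_cell = 2000)
  fit <- mpreg(y ~ elevated_aces * race, d)
  pooled <- rubin_pool(list(fit), single_ok = TRUE)
  ec <- excess_cases(pooled, "Asian", data.frame(dummy = 1),
                     n_resamples = 10000, seed = 11)
  # independent delta-method variance of f(beta) = 1000 * RERI * R00
  co <- coef(pooled)
  v <- vcov(pooled)
  f <- function(b) {
    1000 * (exp(b[2] + b[3] + b[4]) - exp(b[3]) - exp(b[2]) + 1) * exp(b[1])
  }
  grad <- numeric(4)
  h <- 1e-6
  for (j in 1:4) {
    e <- numeric(4); e[j] <- h
    grad[j] <- (f(co + e) - f(co - e)) / (2 * h)
  }
  se_delta <- sqrt(drop(t(grad) %*% v %*% grad))
  width_delta <- 2 * qnorm(0.975) * se_delta
  width_mc <- ec$ci_high - ec$ci_low
  expect_lt(abs(width_mc / width_delta - 1), 0.10)
})

test_that("excess-case sign follows RERI, not the interaction RR", {
  # interaction RR < 1 yet RERI > 0: ref RR 2.0, group main RR 3.0,
  # group within RR 1.9 -> RR_g1 = 5.7, RERI = 5.7 - 3 - 2 + 1 = 1.7 > 0
  fit <- mock_fit(c(`(Intercept)` = log(0.05),
                    elevated_aces = log(2.0),
                    raceWhite = log(3.0),
                    `elevated_aces:raceWhite` = log(1.9 / 2.0)),
                  races = c("Multiracial", "White"))
  ir <- interaction_rr(fit, "White")
  expect_lt(ir$rr, 1)
  expect_gt(reri(fit, "White"), 0)
  ec <- excess_cases(fit, "White", data.frame(dummy = 1),
                     n_resamples = 500, seed = 1)
  expect_gt(ec$excess_cases, 0)
  # mirrored case: interaction RR > 1 with negative RERI
  # ref RR 5.0, group main RR 0.5, interaction 1.1 -> RR_g1 = 2.75,
  # RERI = 2.75 - 0.5 - 5 + 1 = -1.75 < 0
  fit2 <- mock_fit(c(`(Intercept)` = log(0.05),
                     elevated_aces = log(5.0),
                     raceWhite = log(0.5),
                     `elevated_aces:raceWhite` = log(1.1)),
                   races = c("Multiracial", "White"))
  expect_gt(interaction_rr(fit2, "White")$rr, 1)
  expect_lt(reri(fit2, "White"), 0)
  ec2 <- excess_cases(fit2, "White", data.frame(dummy = 1),
                      n_resamples = 500, seed = 1)
  expect_lt(ec2$excess_cases, 0)
})

test_that("degenerate baseline risks are refused", {
  fit <- mock_fit(c(`(Intercept)` = log(1.2), elevated_aces = 0,
                    raceWhite = 0, `elevated_aces:raceWhite` = 0),
                  races = c("Multiracial", "White"))
  expect_error(excess_cases(fit, "White", data.frame(dummy = 1),
                            n_resamples = 100, seed = 1), "R00")
  expect_error(excess_cases(null_fit(), "Multiracial", data.frame(dummy = 1),
                            n_resamples = 100, seed = 1), "referent")
})

test_that("marginal standardization averages predicted baseline risks", {
  set.seed(51)
  d <- toy_cells(c("00" = 0.10, "01" = 0.20, "10" = 0.15, "11" = 0.40),
                 n_cell = 1500)
  d$z <- rnorm(nrow(d))
  fit <- mpreg(y ~ elevated_aces * race + z, d)
  pooled <- rubin_pool(list(fit), single_ok = TRUE)
  profs <- data.frame(z = d$z[1:50])
  ec <- excess_cases(pooled, "Asian", profs, n_resamples = 500, seed = 3,
                     standardization = "marginal")
  co <- coef(pooled)
  r00_manual <- mean(exp(co[["(Intercept)"]] + co[["z"]] * profs$z))
  expect_equal(ec$r00, r00_manual, tolerance = 1e-10)
  expect_error(excess_cases(pooled, "Asian", profs, n_resamples = 100,
                            seed = 3), "single-row")
})
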