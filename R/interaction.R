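# Effect surfaces from a race-by-exposure risk-ratio model.
#
# Model parameterization (referent race = baseline factor level):
#   log risk = b0 + b_exp * exposed + b_race[g] + b_int[g] * exposed + covs
# so within-group RR_g = exp(b_exp + b_int[g]), the interaction RR is
# exp(b_int[g]) = RR_g / RR_referent, and the four cell risk ratios against
# the doubly-unexposed referent cell give
#   RERI = RR_g1 - RR_g0 - RR_ref1 + 1,
#   IC   = RERI * R00,   excess cases per 1000 = 1000 * IC.

exposure_term <- function(fit) {
  labs <- names(stats::coef(fit))
  hit <- intersect(c("elevated_aces", "ace_score"), labs)
  if (length(hit) != 1L) {
    stop("model must contain exactly one ACE exposure main effect ",
         "(elevated_aces or ace_score)")
  }
  hit
}

race_groups <- function(fit) {
  lv <- fit$xlevels[["race"]]
  if (is.null(lv)) stop("model does not contain a race factor")
  lv
}

group_terms <- function(fit, group) {
  ref <- race_groups(fit)[1L]
  if (!group %in% race_groups(fit)) stop("unknown group label: ", group)
  expo <- exposure_term(fit)
  labs <- names(stats::coef(fit))
  if (group == ref) {
    return(list(exposure = expo, race = NULL, interaction = NULL,
                referent = TRUE))
  }
  race_t <- paste0("race", group)
  int_t <- intersect(c(paste0(expo, ":", race_t), paste0(race_t, ":", expo)),
                     labs)
  if (!race_t %in% labs || length(int_t) != 1L) {
    stop("model lacks main/interaction terms for group '", group, "'")
  }
  list(exposure = expo, race = race_t, interaction = int_t, referent = FALSE)
}

contrast_vec <- function(fit, terms_on) {
  labs <- names(stats::coef(fit))
  v <- stats::setNames(numeric(length(labs)), labs)
  v[terms_on] <- 1
  v
}

# CI for exp(c'beta): uses Rubin small-sample df for the contrast when the
# fit carries within/between components, else a normal reference.
lincomb_ci <- function(fit, cvec, conf.level = 0.95) {
  est <- sum(cvec * stats::coef(fit))
  vc <- stats::vcov(fit)
  se <- sqrt(drop(t(cvec) %*% vc %*% cvec))
  q <- stats::qnorm(1 - (1 - conf.level) / 2)
  if (!is.null(fit$within) && !is.null(fit$between) && fit$m >= 2L) {
    w <- drop(t(cvec) %*% fit$within %*% cvec)
    b <- drop(t(cvec) %*% fit$between %*% cvec)
    if (b > 1e-12 * max(w, 1e-300)) {
      df <- (fit$m - 1) * (1 + w / ((1 + 1 / fit$m) * b))^2
      q <- stats::qt(1 - (1 - conf.level) / 2, df)
    }
  }
  c(estimate = est, se = se, low = est - q * se, high = est + q * se)
}

#' Within-group risk ratios for elevated ACEs
#'
#' For the referent race the RR is `exp(b_exposure)`; for any other group
#' `exp(b_exposure + b_interaction)`.  Confidence intervals use the pooled
#' total covariance of the linear combination (Rubin-df t reference when
#' pooled, normal otherwise).
#'
#' @param fit an [mpreg()] or [rubin_pool()] fit with a race interaction.
#' @param groups race groups to report (default: all levels in the model).
#' @param conf.level confidence level (default 0.95).
#' @return data.frame: `group`, `rr`, `ci_low`, `ci_high`, `log_se`.
#' @export
within_group_rr <- function(fit, groups = race_groups(fit),
                            conf.level = 0.95) {
  rows <- lapply(groups, function(g) {
    gt <- group_terms(fit, g)
    cvec <- contrast_vec(fit, c(gt$exposure, gt$interaction))
    ci <- lincomb_ci(fit, cvec, conf.level)
    data.frame(group = g, rr = exp(ci[["estimate"]]),
               ci_low = exp(ci[["low"]]), ci_high = exp(ci[["high"]]),
               log_se = ci[["se"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Interaction risk ratios (ratio of within-group RRs to the referent's)
#'
#' Exponentiated race-by-exposure interaction coefficients.  By the model
#' identity, `interaction_rr(g) * rr(referent) = rr(g)` exactly.  The
#' referent row carries `rr = 1` with `NA` interval and `referent = TRUE`.
#'
#' @inheritParams within_group_rr
#' @return data.frame: `group`, `rr`, `ci_low`, `ci_high`, `referent`.
#' @export
interaction_rr <- function(fit, groups = race_groups(fit),
                           conf.level = 0.95) {
  rows <- lapply(groups, function(g) {
    gt <- group_terms(fit, g)
    if (gt$referent) {
      return(data.frame(group = g, rr = 1, ci_low = NA_real_,
                        ci_high = NA_real_, referent = TRUE,
                        stringsAsFactors = FALSE))
    }
    ci <- lincomb_ci(fit, contrast_vec(fit, gt$interaction), conf.level)
    data.frame(group = g, rr = exp(ci[["estimate"]]),
               ci_low = exp(ci[["low"]]), ci_high = exp(ci[["high"]]),
               referent = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative excess risk due to interaction (RERI)
#'
#' `RERI = RR_g1 - RR_g0 - RR_ref1 + 1`, where the three risk ratios share
#' the doubly-unexposed referent cell as their common baseline:
#' `RR_g1 = exp(b_race + b_exp + b_int)`, `RR_g0 = exp(b_race)`,
#' `RR_ref1 = exp(b_exp)`.
#'
#' @inheritParams within_group_rr
#' @param group a single non-referent race group.
#' @return a single numeric RERI value.
#' @export
reri <- function(fit, group) {
  gt <- group_terms(fit, group)
  if (gt$referent) stop("RERI is undefined for the referent group")
  b <- stats::coef(fit)
  rr_g1 <- exp(b[[gt$race]] + b[[gt$exposure]] + b[[gt$interaction]])
  rr_g0 <- exp(b[[gt$race]])
  rr_ref1 <- exp(b[[gt$exposure]])
  rr_g1 - rr_g0 - rr_ref1 + 1
}

# Model-matrix row(s) of the doubly-unexposed referent cell.
baseline_rows <- function(fit, baseline_profile) {
  ref <- race_groups(fit)[1L]
  expo <- exposure_term(fit)
  prof <- as.data.frame(baseline_profile)
  prof$race <- ref
  prof[[expo]] <- 0
  tt <- stats::delete.response(stats::terms(fit$terms))
  missing_vars <- setdiff(all.vars(tt), names(prof))
  if (length(missing_vars)) {
    stop("baseline profile is missing model terms: ",
         paste(missing_vars, collapse = ", "))
  }
  mf <- stats::model.frame(tt, prof, xlev = fit$xlevels,
                           na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf, contrasts.arg = fit$contrasts)
  labs <- names(stats::coef(fit))
  if (!all(labs %in% colnames(X))) {
    stop("baseline profile model matrix lacks coefficient column(s): ",
         paste(setdiff(labs, colnames(X)), collapse = ", "))
  }
  X[, labs, drop = FALSE]
}

#' Weighted-mean covariate profile for the doubly-unexposed reference cell
#'
#' Builds a one-row profile with every adjustment covariate at its
#' survey-weighted sample mean (character/factor covariates at their
#' weighted modal category), for use as `baseline_profile` in
#' [excess_cases()].
#'
#' @param data analysis data.frame.
#' @param weights sampling weights (default: `data$weight`).
#' @param covariates covariate columns to average.
#' @return one-row data.frame.
#' @export
reference_profile <- function(data, weights = data$weight,
                              covariates = default_covariates()) {
  prof <- lapply(covariates, function(v) {
    x <- data[[v]]
    if (is.null(x)) stop("covariate not found in data: ", v)
    if (is.numeric(x)) {
      wmean(x, weights)
    } else {
      tab <- tapply(weights, x, sum)
      names(tab)[which.max(tab)]
    }
  })
  names(prof) <- covariates
  as.data.frame(prof, stringsAsFactors = FALSE)
}

#' Excess cases per 1000 due to race-by-ACE interaction
#'
#' Converts relative-scale interaction into the absolute scale: recovers
#' the interaction contrast `IC = RERI * R00` and reports
#' `1000 * IC`, the excess (or deficit, when negative) outcome cases per
#' 1000 exposed attributable to interaction, relative to the referent
#' group.  `R00` is the model-predicted risk in the doubly-unexposed
#' referent cell, evaluated at `baseline_profile` (reference-profile
#' standardization; pass several rows and `standardization = "marginal"`
#' to average predicted risks instead).
#'
#' The confidence interval is a Monte-Carlo percentile interval: the same
#' functional evaluated over `n_resamples` multivariate-normal draws of the
#' coefficient vector with the (pooled) total covariance; deterministic
#' given `seed`.
#'
#' @inheritParams within_group_rr
#' @param group a single non-referent race group.
#' @param baseline_profile data.frame of covariate values defining the
#'   doubly-unexposed reference cell (race and exposure are overridden
#'   internally); see [reference_profile()].
#' @param n_resamples Monte-Carlo draws for the CI (default 10000).
#' @param seed RNG seed for the draws.
#' @param standardization `"reference"` (predict at the single profile;
#'   default) or `"marginal"` (average predicted risk over profile rows).
#' @param conf.level confidence level.
#' @return data.frame: `group`, `excess_cases` (per 1000), `ci_low`,
#'   `ci_high`, `reri`, `r00`, `n_resamples`, `seed`.
#' @export
excess_cases <- function(fit, group, baseline_profile,
                         n_resamples = 10000L, seed = 1L,
                         standardization = c("reference", "marginal"),
                         conf.level = 0.95) {
  standardization <- match.arg(standardization)
  gt <- group_terms(fit, group)
  if (gt$referent) stop("excess cases are undefined for the referent group")
  X00 <- baseline_rows(fit, baseline_profile)
  if (standardization == "reference" && nrow(X00) != 1L) {
    stop("reference standardization needs a single-row baseline profile")
  }
  beta <- stats::coef(fit)
  vc <- stats::vcov(fit)
  r00_fun <- function(b) {
    risks <- exp(drop(X00 %*% b))
    if (standardization == "reference") risks[1L] else mean(risks)
  }
  r00 <- r00_fun(beta)
  if (r00 >= 1) stop(sprintf("baseline risk R00 = %.3f >= 1", r00))
  reri_hat <- reri(fit, group)
  point <- 1000 * reri_hat * r00

  idx <- match(c(gt$race, gt$exposure, gt$interaction), names(beta))
  draws <- with_seed(seed, rmvnorm_chol(n_resamples, beta, vc))
  rr_g1 <- exp(draws[, idx[1L]] + draws[, idx[2L]] + draws[, idx[3L]])
  rr_g0 <- exp(draws[, idx[1L]])
  rr_ref1 <- exp(draws[, idx[2L]])
  r00_draws <- if (standardization == "reference") {
    exp(drop(draws %*% X00[1L, ]))
  } else {
    rowMeans(exp(draws %*% t(X00)))
  }
  ec_draws <- 1000 * (rr_g1 - rr_g0 - rr_ref1 + 1) * r00_draws
  alpha <- (1 - conf.level) / 2
  ci <- unname(stats::quantile(ec_draws, c(alpha, 1 - alpha)))
  data.frame(group = group, excess_cases = point,
             ci_low = ci[1L], ci_high = ci[2L],
             reri = reri_hat, r00 = r00,
             n_resamples = as.integer(n_resamples), seed = as.integer(seed),
             stringsAsFactors = FALSE)
}
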