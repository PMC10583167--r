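# Chained-equations multiple imputation.
#
# Deliberately simple engine: binary fields by weighted-data logistic
# posterior draws, 5-level ordinal fields by proportional-odds draws,
# continuous fields by Bayesian normal linear draws with posterior
# predictive noise.  Survey weights enter the imputation models as a
# predictor (log weight), not as fitting weights.  ACE components are
# imputed at component level; summing/dichotomizing happens downstream.

imputable_types <- function(cohort, targets) {
  vapply(targets, function(v) {
    x <- cohort[[v]]
    obs <- x[!is.na(x)]
    if (v == "sex" || is.character(x)) return("binary_char")
    if (all(obs %in% c(0, 1))) return("binary")
    if (v %in% c("parent1_education", "parent2_education", support_cols())) {
      return("ordinal")
    }
    if (v == "household_size") return("count")
    "continuous"
  }, character(1))
}

default_imputation_predictors <- function() {
  c("race", "log_weight", "age", "sex", "parent1_education",
    "parent2_education", "household_income", "household_size",
    outcome_names())
}

#' Multiple imputation of a cohort by chained equations
#'
#' Produces `m` completed copies of the cohort.  Every column with missing
#' values is cycled over for up to `max_iter` iterations; each target is
#' regressed on the currently-completed predictor set (race, log sampling
#' weight, core covariates and all seven outcomes by default; ACE
#' components additionally predict one another), parameters are drawn from
#' their approximate posterior, and missing entries are drawn from the
#' posterior predictive.  Design variables must be complete.
#'
#' @param cohort cohort data.frame (design variables complete).
#' @param m number of imputations (the analysis default is 20).
#' @param seed integer seed; each imputation chain derives its own stream.
#' @param max_iter chained-equation cycles per imputation (default 10).
#' @param predictors character vector of predictor columns (plus
#'   `"log_weight"` for the log sampling weight).
#' @return object of class `"imputation_set"`: list with `imputations`
#'   (list of `m` completed data.frames), `m`, `seed`, `iterations`.
#' @export
impute_chained <- function(cohort, m = 20L, seed = 1L, max_iter = 10L,
                           predictors = default_imputation_predictors()) {
  stopifnot(m >= 1L)
  for (v in c("stratum", "cluster", "weight")) {
    if (anyNA(cohort[[v]])) stop("design variable '", v, "' has missing values")
  }
  targets <- names(cohort)[vapply(cohort, anyNA, logical(1))]
  no_obs <- targets[vapply(targets, function(v) all(is.na(cohort[[v]])),
                           logical(1))]
  if (length(no_obs)) {
    stop("field(s) with no observed values cannot be imputed: ",
         paste(no_obs, collapse = ", "))
  }
  if (length(targets) == 0L) {
    return(structure(list(
      imputations = rep(list(cohort), m), m = m, seed = seed,
      iterations = 0L, targets = character(0)), class = "imputation_set"))
  }
  types <- imputable_types(cohort, targets)
  cohort$log_weight <- log(cohort$weight)
  predictors <- intersect(predictors, c(names(cohort)))

  imputations <- vector("list", m)
  for (k in seq_len(m)) {
    imputations[[k]] <- with_seed(seed + 7919L * k, {
      impute_once(cohort, targets, types, predictors, max_iter)
    })
  }
  imputations <- lapply(imputations, function(d) {
    d$log_weight <- NULL
    d
  })
  structure(list(imputations = imputations, m = m, seed = seed,
                 iterations = max_iter, targets = targets),
            class = "imputation_set")
}

impute_once <- function(cohort, targets, types, predictors, max_iter) {
  obs <- lapply(cohort[targets], function(x) !is.na(x))
  cur <- cohort
  # initialize: fill from observed margins
  for (v in targets) {
    miss <- !obs[[v]]
    cur[[v]][miss] <- sample(cohort[[v]][obs[[v]]], sum(miss), replace = TRUE)
  }
  for (it in seq_len(max_iter)) {
    for (v in targets) {
      miss <- !obs[[v]]
      preds <- setdiff(predictors, v)
      if (v %in% ace_cols()) preds <- union(preds, setdiff(ace_cols(), v))
      X <- stats::model.matrix(
        stats::reformulate(preds),
        cur[c(preds)])
      cur[[v]][miss] <- draw_imputation(
        y_obs = cohort[[v]][obs[[v]]],
        X_obs = X[obs[[v]], , drop = FALSE],
        X_mis = X[miss, , drop = FALSE],
        type = types[[v]])
    }
  }
  cur
}

draw_imputation <- function(y_obs, X_obs, X_mis, type) {
  n_mis <- nrow(X_mis)
  fallback <- function() sample(y_obs, n_mis, replace = TRUE)
  switch(type,
    binary_char = {
      lv <- sort(unique(y_obs))
      if (length(lv) != 2L) return(fallback())
      z <- draw_binary(as.integer(y_obs == lv[2L]), X_obs, X_mis, fallback = NULL)
      if (is.null(z)) return(fallback())
      lv[z + 1L]
    },
    binary = {
      z <- draw_binary(y_obs, X_obs, X_mis, fallback = NULL)
      if (is.null(z)) fallback() else z
    },
    ordinal = draw_ordinal(y_obs, X_obs, X_mis, fallback),
    count = {
      z <- draw_normal(y_obs, X_obs, X_mis)
      if (is.null(z)) fallback() else pmax(1L, as.integer(round(z)))
    },
    continuous = {
      z <- draw_normal(y_obs, X_obs, X_mis)
      # squeeze into the observed range so bounded quantities
      # (proportions, concentrations) stay valid
      if (is.null(z)) fallback() else pmin(pmax(z, min(y_obs)), max(y_obs))
    },
    fallback()
  )
}

draw_binary <- function(y_obs, X_obs, X_mis, fallback) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X_obs, y_obs,
                                    family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(fallback)
  # posterior draw of coefficients from the asymptotic normal
  R <- qr.R(fit$qr)
  keep <- abs(diag(R)) > 1e-8
  if (!all(keep)) return(fallback)
  Vh <- backsolve(R, diag(ncol(R)))   # chol factor of (X'WX)^{-1}
  beta_star <- fit$coefficients + drop(Vh %*% stats::rnorm(ncol(R)))
  p <- stats::plogis(drop(X_mis %*% beta_star))
  stats::rbinom(nrow(X_mis), 1L, p)
}

draw_ordinal <- function(y_obs, X_obs, X_mis, fallback) {
  lv <- sort(unique(y_obs))
  if (length(lv) < 3L) {
    z <- draw_binary(as.integer(y_obs == max(lv)), X_obs, X_mis, NULL)
    if (is.null(z)) return(fallback())
    return(ifelse(z == 1L, max(lv), min(lv)))
  }
  df <- data.frame(y = factor(y_obs, levels = lv),
                   X_obs[, -1L, drop = FALSE], check.names = FALSE)
  fit <- tryCatch(
    suppressWarnings(MASS::polr(y ~ ., data = df, Hess = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback())
  theta <- c(fit$coefficients, fit$zeta)
  V <- tryCatch(solve(fit$Hessian), error = function(e) NULL)
  if (is.null(V)) return(fallback())
  theta_star <- drop(rmvnorm_chol(1L, theta, (V + t(V)) / 2))
  nb <- length(fit$coefficients)
  eta <- drop(X_mis[, -1L, drop = FALSE] %*% theta_star[seq_len(nb)])
  zeta <- sort(theta_star[-seq_len(nb)])
  cum <- vapply(zeta, function(z) stats::plogis(z - eta),
                numeric(nrow(X_mis)))
  cum <- cbind(matrix(cum, nrow = nrow(X_mis)), 1)
  probs <- cum - cbind(0, cum[, -ncol(cum), drop = FALSE])
  probs[probs < 0] <- 0
  idx <- apply(probs, 1L, function(p) sample.int(length(lv), 1L, prob = p))
  as.integer(lv[idx])
}

draw_normal <- function(y_obs, X_obs, X_mis) {
  qrx <- qr(X_obs)
  if (qrx$rank < ncol(X_obs)) return(NULL)
  beta_hat <- qr.coef(qrx, y_obs)
  res <- y_obs - drop(X_obs %*% beta_hat)
  df <- length(y_obs) - ncol(X_obs)
  if (df < 2L) return(NULL)
  sigma_star <- sqrt(sum(res^2) / stats::rchisq(1L, df))
  R <- qr.R(qrx)
  beta_star <- beta_hat + sigma_star * drop(backsolve(R, stats::rnorm(ncol(R))))
  drop(X_mis %*% beta_star) + sigma_star * stats::rnorm(nrow(X_mis))
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("Imputation set: m = %d, %d target column(s), %d cycles, seed %d\n",
              x$m, length(x$targets), x$iterations, x$seed))
  invisible(x)
}

#' Persist / reload an imputation set as delimited files plus a manifest
#'
#' @param imp an `"imputation_set"`.
#' @param dir directory to write `imp_<k>.csv` files and `manifest.yml`.
#' @return `write_imputations()` the directory invisibly;
#'   `read_imputations()` the reconstructed set.
#' @export
write_imputations <- function(imp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(imp$m)) {
    utils::write.csv(imp$imputations[[k]],
                     file.path(dir, sprintf("imp_%02d.csv", k)),
                     row.names = FALSE, na = "")
  }
  yaml::write_yaml(list(m = imp$m, seed = imp$seed,
                        iterations = imp$iterations,
                        targets = as.list(imp$targets)),
                   file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' @rdname write_imputations
#' @export
read_imputations <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yml"))
  imps <- lapply(seq_len(man$m), function(k) {
    utils::read.csv(file.path(dir, sprintf("imp_%02d.csv", k)),
                    na.strings = "", check.names = FALSE)
  })
  structure(list(imputations = imps, m = man$m, seed = man$seed,
                 iterations = man$iterations,
                 targets = unlist(man$targets) %||% character(0)),
            class = "imputation_set")
}
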