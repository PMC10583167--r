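#' Specify a complex survey design
#'
#' Records where the stratum, primary-sampling-unit (cluster) and sampling
#' weight of each row live.  Arguments may be one-sided formulas
#' (`~stratum`), column names, or vectors; formulas and names are resolved
#' against the data at fit time.
#'
#' @param strata stratum identifier (formula, column name, or vector).
#' @param cluster PSU identifier within stratum.
#' @param weights positive sampling weights.
#' @return an object of class `"survey_design"`.
#' @export
#' @examples
#' des <- survey_design(~stratum, ~cluster, ~weight)
survey_design <- function(strata, cluster, weights) {
  as_spec <- function(x) {
    if (inherits(x, "formula")) all.vars(x) else x
  }
  structure(list(strata = as_spec(strata), cluster = as_spec(cluster),
                 weights = as_spec(weights)),
            class = "survey_design")
}

resolve_design <- function(design, data, rows = NULL) {
  pull <- function(spec, what) {
    v <- if (is.character(spec) && length(spec) == 1L) {
      if (!spec %in% names(data)) stop("design column not found: ", spec)
      data[[spec]]
    } else spec
    if (length(v) != nrow(data)) stop(what, " has wrong length")
    v
  }
  out <- list(strata = pull(design$strata, "strata"),
              cluster = pull(design$cluster, "cluster"),
              weights = pull(design$weights, "weights"))
  if (!is.null(rows)) out <- lapply(out, `[`, rows)
  if (anyNA(out$strata) || anyNA(out$cluster)) {
    stop("stratum and cluster ids must be non-missing")
  }
  if (anyNA(out$weights) || any(out$weights <= 0)) {
    stop("sampling weights must be strictly positive")
  }
  # each cluster must belong to exactly one stratum
  tab <- unique(data.frame(s = out$strata, c = out$cluster))
  if (anyDuplicated(tab$c)) {
    stop("a cluster id appears in more than one stratum")
  }
  out
}

#' Modified Poisson regression under a complex survey design
#'
#' Fits a log-link Poisson working likelihood to a binary outcome --
#' the "modified Poisson" estimator of the risk ratio -- by weighted IRLS,
#' and computes the design-based linearized sandwich covariance:
#' bread = inverse weighted information; meat = within-stratum
#' between-cluster covariance of weighted score totals with the
#' `n_h/(n_h - 1)` cluster correction, summed over strata.  The Poisson
#' variance is deliberately misspecified for a binary outcome; the sandwich
#' makes the standard errors valid anyway, and exponentiated coefficients
#' are risk ratios.
#'
#' Risks predicted above 1 are permitted during fitting (the working model
#' is not constrained) and only flagged on prediction output.
#'
#' @param formula model formula; the response must be binary 0/1.
#' @param data data.frame containing model and design variables.
#' @param design a [survey_design()]; defaults to
#'   `survey_design("stratum", "cluster", "weight")`.
#' @param single_cluster handling of strata with a single PSU:
#'   `"certainty"` (default; contributes zero variance, with a warning) or
#'   `"fail"`.
#' @param control list: `maxit` (100), `tol` (1e-10, maximum relative
#'   coefficient change), `max_halvings` (10).
#' @return object of class `"mpreg"` with components `coefficients`,
#'   `vcov` (design-based sandwich), `naive_vcov` (inverse information),
#'   `fitted.values`, `converged`, `iter`, `n`, `design_df`
#'   (clusters minus strata), and the usual formula/terms metadata.
#' @references Zou G (2004) A modified Poisson regression approach to
#'   prospective studies with binary data. *Am J Epidemiol* 159(7):702-706.
#' @export
#' @examples
#' d <- data.frame(y = rbinom(200, 1, 0.2), x = rnorm(200),
#'                 stratum = 1, cluster = 1:200, weight = 1)
#' fit <- mpreg(y ~ x, d)
#' summary(fit)
mpreg <- function(formula, data,
                  design = survey_design("stratum", "cluster", "weight"),
                  single_cluster = c("certainty", "fail"),
                  control = list()) {
  single_cluster <- match.arg(single_cluster)
  ctl <- list(maxit = 100L, tol = 1e-10, max_halvings = 10L)
  ctl[names(control)] <- control
  cl <- match.call()

  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  dropped <- attr(mf, "na.action")
  rows <- setdiff(seq_len(nrow(data)), as.integer(dropped))
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate outcome: all responses are ", y[1])
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  des <- resolve_design(design, data, rows)
  w <- des$weights
  n <- length(y)
  p <- ncol(X)

  working_deviance <- function(mu) {
    2 * sum(w * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu)))
  }

  beta <- c(log(sum(w * y) / sum(w)), rep(0, p - 1L))
  if (colnames(X)[1L] != "(Intercept)") beta <- rep(0, p)
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  dev <- working_deviance(mu)
  converged <- FALSE
  trace <- numeric(0)
  iter <- 0L
  for (iter in seq_len(ctl$maxit)) {
    info <- crossprod(X, X * (w * mu))
    score <- crossprod(X, w * (y - mu))
    delta <- tryCatch(solve(info, score), error = function(e) {
      stop("information matrix is singular at iteration ", iter,
           "; a covariate cell with (near-)zero fitted risk usually means ",
           "an empty outcome cell (separation on the log link); ",
           "relative-change trace: ",
           paste(signif(utils::tail(trace, 3), 3), collapse = ", "))
    })
    step <- 1
    for (h in 0:ctl$max_halvings) {
      beta_new <- beta + step * drop(delta)
      mu_new <- exp(drop(X %*% beta_new))
      dev_new <- working_deviance(mu_new)
      if (is.finite(dev_new) && dev_new <= dev + 1e-8) break
      step <- step / 2
    }
    rel <- max(abs(beta_new - beta) / pmax(abs(beta_new), 1e-6))
    beta <- beta_new
    mu <- mu_new
    dev <- dev_new
    trace <- c(trace, rel)
    if (rel < ctl$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf(
      "IRLS did not converge in %d iterations (last relative changes: %s)",
      ctl$maxit, paste(signif(utils::tail(trace, 3), 3), collapse = ", ")))
  }
  names(beta) <- colnames(X)

  info <- crossprod(X, X * (w * mu))
  bread <- solve(info)
  scores <- X * (w * (y - mu))
  vc <- sandwich_meat(scores, des$strata, des$cluster, single_cluster)
  vcov <- bread %*% vc$meat %*% bread
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(colnames(X), colnames(X))

  structure(list(
    coefficients = beta, vcov = vcov, naive_vcov = bread,
    fitted.values = mu, linear.predictors = drop(X %*% beta),
    prior.weights = w, y = y,
    converged = converged, iter = iter, trace = trace,
    n = n, n_clusters = vc$n_clusters, n_strata = vc$n_strata,
    design_df = vc$n_clusters - vc$n_strata,
    formula = formula, terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    contrasts = attr(X, "contrasts"),
    na.action = dropped, call = cl
  ), class = "mpreg")
}

# Design-based meat: between-cluster covariance of weighted score totals,
# within stratum, with the n_h/(n_h - 1) correction.
sandwich_meat <- function(scores, strata, cluster, single_cluster) {
  key <- paste(strata, cluster, sep = "\r")
  totals <- rowsum(scores, key, reorder = FALSE)
  cl_stratum <- strata[!duplicated(key)]
  p <- ncol(scores)
  meat <- matrix(0, p, p)
  strata_ids <- unique(cl_stratum)
  n_single <- 0L
  for (h in strata_ids) {
    idx <- which(cl_stratum == h)
    nh <- length(idx)
    if (nh < 2L) {
      if (single_cluster == "fail") {
        stop("stratum '", h, "' has a single cluster; variance undefined")
      }
      n_single <- n_single + 1L
      next  # certainty stratum: zero contribution
    }
    s <- totals[idx, , drop = FALSE]
    s <- sweep(s, 2L, colMeans(s))
    meat <- meat + crossprod(s) * nh / (nh - 1)
  }
  if (n_single > 0L) {
    warning(n_single, " single-cluster stratum(s) treated as certainty ",
            "strata (zero variance contribution)")
  }
  list(meat = meat, n_clusters = nrow(totals),
       n_strata = length(strata_ids))
}

#' @export
coef.mpreg <- function(object, ...) object$coefficients

#' @export
vcov.mpreg <- function(object, ...) object$vcov

#' @export
print.mpreg <- function(x, ...) {
  cat("Modified Poisson (log-link) survey-weighted fit\n")
  cat(sprintf("  n = %d, %d clusters in %d strata, %d IRLS iterations\n",
              x$n, x$n_clusters, x$n_strata, x$iter))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.mpreg <- function(object, conf.level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  q <- stats::qnorm(1 - (1 - conf.level) / 2)
  tab <- cbind(
    Estimate = object$coefficients, `Robust SE` = se, z = z,
    `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)),
    RR = exp(object$coefficients),
    `RR low` = exp(object$coefficients - q * se),
    `RR high` = exp(object$coefficients + q * se)
  )
  structure(list(coefficients = tab, n = object$n,
                 n_clusters = object$n_clusters, n_strata = object$n_strata,
                 design_df = object$design_df, iter = object$iter,
                 call = object$call),
            class = "summary.mpreg")
}

#' @export
print.summary.mpreg <- function(x, ...) {
  cat("Modified Poisson (log-link) survey-weighted fit\n")
  cat(sprintf("  n = %d, %d clusters in %d strata (design df %d)\n",
              x$n, x$n_clusters, x$n_strata, x$design_df))
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], digits = 4)
  cat("\nRisk ratios:\n")
  print(round(x$coefficients[, 5:7, drop = FALSE], 4))
  invisible(x)
}

#' Predicted risk from a modified Poisson fit
#'
#' @param object an [mpreg()] fit or pooled fit.
#' @param newdata data.frame of covariate profiles; must supply every model
#'   term.
#' @param type `"response"` (risk, `exp(x'beta)`) or `"link"` (log risk).
#' @param ... unused.
#' @return numeric vector; for `type = "response"`, predictions above 1 are
#'   flagged via the `"above_one"` attribute (never clipped).
#' @export
predict.mpreg <- function(object, newdata = NULL,
                          type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    tt <- stats::delete.response(stats::terms(object$terms))
    missing_vars <- setdiff(all.vars(tt), names(newdata))
    if (length(missing_vars)) {
      stop("profile is missing model terms: ",
           paste(missing_vars, collapse = ", "))
    }
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels,
                             na.action = stats::na.fail)
    X <- stats::model.matrix(tt, mf, contrasts.arg = object$contrasts)
    eta <- drop(X %*% object$coefficients[colnames(X)])
  }
  if (type == "link") return(eta)
  risk <- exp(eta)
  if (any(risk > 1)) {
    attr(risk, "above_one") <- which(risk > 1)
    warning(sum(risk > 1), " predicted risk(s) exceed 1 (working model, ",
            "not clipped)")
  }
  risk
}

#' @export
confint.mpreg <- function(object, parm, level = 0.95, ...) {
  co <- object$coefficients
  se <- sqrt(diag(object$vcov))
  if (missing(parm)) parm <- names(co)
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(co[parm] - q * se[parm], co[parm] + q * se[parm])
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}

#' Model formula for the interaction analysis
#'
#' Builds `outcome ~ exposure * race + covariates` with the race factor
#' releveled so the configured referent is the baseline level.
#'
#' @param outcome outcome column name.
#' @param exposure `"elevated"` (binary >= 4 indicator) or `"score"`
#'   (continuous 0-10 summary score).
#' @param covariates character vector of adjustment covariate names.
#' @param interaction include the race interaction (default TRUE).
#' @return a formula.
#' @export
build_model_formula <- function(outcome,
                                exposure = c("elevated", "score"),
                                covariates = default_covariates(),
                                interaction = TRUE) {
  exposure <- match.arg(exposure)
  ev <- if (exposure == "elevated") "elevated_aces" else "ace_score"
  rhs <- if (interaction) paste0(ev, " * race") else paste0(ev, " + race")
  if (length(covariates)) {
    rhs <- paste(rhs, "+", paste(covariates, collapse = " + "))
  }
  stats::as.formula(paste(outcome, "~", rhs), env = globalenv())
}

#' @rdname build_model_formula
#' @export
default_covariates <- function() {
  c("age", "sex", "parental_education_max", "equivalized_income",
    "parental_support_index", "neighborhood_disadvantage")
}
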