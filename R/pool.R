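#' Pool model fits across imputations by Rubin's rules
#'
#' Combines `M` fits of the same model on different completed datasets:
#' pooled coefficients are the mean of the per-imputation coefficients;
#' the total covariance is `T = W + (1 + 1/M) B`, where `W` is the mean
#' within-imputation covariance and `B` the between-imputation sample
#' covariance of the coefficients.  Per-term small-sample degrees of
#' freedom follow the classical formula
#' `nu = (M - 1) (1 + W / ((1 + 1/M) B))^2`; terms whose between-imputation
#' variance is (numerically) zero get infinite df and a normal reference.
#'
#' @param fits list of [mpreg()] fits sharing identical term labels.
#' @param single_ok allow `M = 1` (no between-imputation variance;
#'   `T = W`, normal reference); default FALSE.
#' @return object of class `"mpreg_pooled"` with `coefficients`,
#'   `vcov` (total `T`), `within` (`W`), `between` (`B`), `df`, `m`, plus
#'   the first fit's terms metadata so [predict.mpreg()] machinery applies.
#' @references Rubin DB (1987) *Multiple Imputation for Nonresponse in
#'   Surveys*. Wiley.
#' @export
#' @examples
#' d <- data.frame(y = rbinom(300, 1, 0.3), x = rbinom(300, 1, 0.5),
#'                 stratum = 1, cluster = 1:300, weight = 1)
#' f <- mpreg(y ~ x, d)
#' pooled <- rubin_pool(list(f, f))   # B = 0, T = W
#' summary(pooled)
rubin_pool <- function(fits, single_ok = FALSE) {
  if (inherits(fits, "mpreg")) fits <- list(fits)
  m <- length(fits)
  if (m < 2L && !single_ok) {
    stop("need at least 2 fits to estimate between-imputation variance ",
         "(set single_ok = TRUE for single-imputation mode)")
  }
  labels <- names(stats::coef(fits[[1L]]))
  for (f in fits) {
    if (!identical(names(stats::coef(f)), labels)) {
      stop("all fits must share identical term labels")
    }
  }
  betas <- do.call(rbind, lapply(fits, stats::coef))
  colnames(betas) <- labels
  beta_bar <- colMeans(betas)
  W <- Reduce(`+`, lapply(fits, stats::vcov)) / m
  if (m >= 2L) {
    B <- stats::cov(betas)
  } else {
    B <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
  }
  Tmat <- W + (1 + 1 / m) * B
  Tmat <- (Tmat + t(Tmat)) / 2
  b_diag <- diag(B)
  w_diag <- diag(W)
  df <- ifelse(b_diag > 1e-12 * pmax(w_diag, 1e-300) & m >= 2L,
               (m - 1) * (1 + w_diag / ((1 + 1 / m) * b_diag))^2,
               Inf)
  names(df) <- labels
  structure(list(
    coefficients = beta_bar, vcov = Tmat, within = W, between = B,
    df = df, m = m,
    n = fits[[1L]]$n,
    terms = fits[[1L]]$terms, xlevels = fits[[1L]]$xlevels,
    contrasts = fits[[1L]]$contrasts, formula = fits[[1L]]$formula
  ), class = "mpreg_pooled")
}

#' @export
coef.mpreg_pooled <- function(object, ...) object$coefficients

#' @export
vcov.mpreg_pooled <- function(object, ...) object$vcov

#' @export
print.mpreg_pooled <- function(x, ...) {
  cat(sprintf("Rubin-pooled modified Poisson fit (M = %d imputations)\n", x$m))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.mpreg_pooled <- function(object, conf.level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  stat <- object$coefficients / se
  q <- ifelse(is.finite(object$df),
              stats::qt(1 - (1 - conf.level) / 2, object$df),
              stats::qnorm(1 - (1 - conf.level) / 2))
  p <- ifelse(is.finite(object$df),
              2 * stats::pt(-abs(stat), object$df),
              2 * stats::pnorm(-abs(stat)))
  tab <- cbind(
    Estimate = object$coefficients, `Total SE` = se, statistic = stat,
    df = object$df, `Pr(>|t|)` = p,
    RR = exp(object$coefficients),
    `RR low` = exp(object$coefficients - q * se),
    `RR high` = exp(object$coefficients + q * se)
  )
  structure(list(coefficients = tab, m = object$m, n = object$n),
            class = "summary.mpreg_pooled")
}

#' @export
print.summary.mpreg_pooled <- function(x, ...) {
  cat(sprintf("Rubin-pooled modified Poisson fit (M = %d, n = %d)\n",
              x$m, x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname predict.mpreg
#' @export
predict.mpreg_pooled <- function(object, newdata = NULL,
                                 type = c("response", "link"), ...) {
  if (is.null(newdata)) stop("newdata is required for pooled predictions")
  predict.mpreg(object, newdata = newdata, type = type, ...)
}

#' Serialize / reload a pooled fit (term labels, estimates, covariances)
#'
#' @param pooled an `"mpreg_pooled"` object.
#' @param path YAML file path.
#' @return `write_pooled_fit()` the path invisibly; `read_pooled_fit()` a
#'   reduced pooled object (coefficients and covariances; no terms
#'   metadata, so prediction requires the original fit).
#' @export
write_pooled_fit <- function(pooled, path) {
  yaml::write_yaml(list(
    terms = names(pooled$coefficients),
    coefficients = as.list(pooled$coefficients),
    vcov = apply(pooled$vcov, 1L, as.list),
    within = apply(pooled$within, 1L, as.list),
    between = apply(pooled$between, 1L, as.list),
    df = as.list(pooled$df), m = pooled$m, n = pooled$n
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_pooled_fit
#' @export
read_pooled_fit <- function(path) {
  raw <- yaml::read_yaml(path)
  labels <- unlist(raw$terms)
  as_mat <- function(x) {
    m <- do.call(rbind, lapply(x, function(r) unlist(r)[labels]))
    rownames(m) <- labels
    m
  }
  structure(list(
    coefficients = unlist(raw$coefficients)[labels],
    vcov = as_mat(raw$vcov), within = as_mat(raw$within),
    between = as_mat(raw$between),
    df = unlist(raw$df)[labels], m = raw$m, n = raw$n
  ), class = "mpreg_pooled")
}
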