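#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
# Keeps every generator and resampler a pure function of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(expr)
}

#' Weighted quantile (left-continuous inverse of the weighted empirical CDF)
#'
#' Returns, for each probability `p`, the smallest observed value `x` such
#' that the weighted CDF satisfies `F(x) >= p`.  No interpolation is done:
#' boundaries are always observed data values, so decile membership rules
#' ("top 3 deciles", "bottom 2 deciles") are exact and reproducible.
#'
#' @param x numeric vector of values.
#' @param w numeric vector of positive weights, recycled if length 1.
#' @param probs probabilities in `[0, 1]`.
#' @param na.rm drop missing values (and their weights) first.
#' @return numeric vector of the same length as `probs`.
#' @export
#' @examples
#' weighted_quantile(1:100, 1, probs = 0.7)  # 70
weighted_quantile <- function(x, w = 1, probs, na.rm = FALSE) {
  if (length(w) == 1L) w <- rep(w, length(x))
  stopifnot(length(w) == length(x))
  if (na.rm) {
    keep <- !is.na(x)
    x <- x[keep]; w <- w[keep]
  }
  if (anyNA(x)) stop("missing values in 'x'; use na.rm = TRUE")
  if (length(x) == 0L) stop("no non-missing values")
  if (any(w <= 0)) stop("weights must be strictly positive")
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) {
    if (p <= 0) return(x[1L])
    x[which(cw >= p - 1e-12)[1L]]
  }, numeric(1))
}

# Weighted mean that tolerates missing values.
wmean <- function(x, w, na.rm = TRUE) {
  if (na.rm) {
    keep <- !is.na(x)
    x <- x[keep]; w <- w[keep]
  }
  sum(w * x) / sum(w)
}

# Draw n samples from a multivariate normal via the Cholesky factor.
# `sigma` must be symmetric positive semi-definite; a small jitter is added
# if the Cholesky factorization fails for numerical reasons.
rmvnorm_chol <- function(n, mu, sigma) {
  p <- length(mu)
  ch <- tryCatch(chol(sigma), error = function(e) {
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      stop("covariance matrix is not positive semi-definite")
    }
    chol(sigma + diag(1e-10 * max(diag(sigma), 1), p))
  })
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% ch, 2L, mu, `+`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
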