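#' Generalized extreme value distribution
#'
#' Density, distribution function and quantile function of the generalized
#' extreme value (GEV) distribution with location \eqn{\mu}, scale
#' \eqn{\sigma > 0} and shape \eqn{\xi}, in the standard parameterization
#' \deqn{F(x) = \exp\{-[1 + \xi (x - \mu)/\sigma]^{-1/\xi}\}}
#' on the support where \eqn{1 + \xi (x - \mu)/\sigma > 0}, with the
#' Gumbel limit at \eqn{\xi = 0}.
#'
#' @param x,q,p Vectors of quantiles / probabilities.
#' @param location,scale,shape GEV parameters.
#' @param log Return the log density.
#' @return Numeric vector.
#' @name gev
NULL

#' @rdname gev
#' @export
dgev <- function(x, location = 0, scale = 1, shape = 0, log = FALSE) {
  stopifnot(scale > 0)
  z <- (x - location) / scale
  if (abs(shape) < 1e-10) {
    logd <- -z - exp(-z) - log(scale)
  } else {
    t <- 1 + shape * z
    logd <- ifelse(t > 0,
                   -(1 / shape + 1) * log(pmax(t, .Machine$double.xmin)) -
                     pmax(t, .Machine$double.xmin)^(-1 / shape) - log(scale),
                   -Inf)
  }
  if (log) logd else exp(logd)
}

#' @rdname gev
#' @export
pgev <- function(q, location = 0, scale = 1, shape = 0) {
  stopifnot(scale > 0)
  z <- (q - location) / scale
  if (abs(shape) < 1e-10) return(exp(-exp(-z)))
  t <- 1 + shape * z
  out <- ifelse(t > 0, exp(-t^(-1 / shape)),
                ifelse(shape > 0, 0, 1))
  unname(out)
}

#' @rdname gev
#' @export
qgev <- function(p, location = 0, scale = 1, shape = 0) {
  stopifnot(scale > 0, all(p > 0), all(p < 1))
  if (abs(shape) < 1e-10) {
    return(unname(location - scale * log(-log(p))))
  }
  unname(location + scale * ((-log(p))^(-shape) - 1) / shape)
}

#' Maximum likelihood GEV fit
#'
#' Fits the three-parameter GEV to a sample by direct likelihood
#' maximization (Nelder-Mead over location, log scale and shape), started
#' from moment-based Gumbel estimates. An error is thrown when the
#' optimizer fails to produce a finite likelihood.
#'
#' @param x Numeric sample (at least 5 observations).
#' @return A list with `params` (named location/scale/shape), `loglik` and
#'   `convergence` (0 means the optimizer converged).
#' @export
fit_gev <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5L) stop("need at least 5 finite observations")
  if (stats::sd(x) == 0) stop("degenerate sample: zero variance")
  sigma0 <- stats::sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772156649 * sigma0
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2]); xi <- par[3]
    ll <- dgev(x, mu, sigma, xi, log = TRUE)
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }
  best <- NULL
  for (xi0 in c(0.1, -0.1, 0.5)) {
    opt <- tryCatch(
      stats::optim(c(mu0, log(sigma0), xi0), nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e9 &&
        (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) stop("GEV likelihood maximization failed")
  params <- c(location = best$par[1], scale = exp(best$par[2]),
              shape = best$par[3])
  list(params = params, loglik = -best$value, convergence = best$convergence)
}
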