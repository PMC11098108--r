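#' Gompertz survival function
#'
#' Survival probability under the Gompertz mortality law,
#' \eqn{S(t) = \exp\{-(a/b)(e^{bt} - 1)\}}, the parametric form that describes
#' bacterial replicative-lifespan distributions. The hazard
#' \eqn{\lambda(t) = a e^{bt}} grows exponentially with time; `b` is the aging
#' (hazard-accumulation) rate and `a` the initial hazard. At `b = 0` the law
#' reduces continuously to the exponential distribution \eqn{S(t) = e^{-at}}.
#'
#' @param t Times (h or generations), non-negative, vectorised.
#' @param a Initial hazard (same inverse units as `t`), strictly positive.
#' @param b Aging rate (same inverse units as `t`), non-negative.
#' @return Numeric vector of survival probabilities in `[0, 1]`.
#' @seealso [gompertz_hazard()], [sample_gompertz_lifespans()], [fit_gompertz()]
#' @examples
#' gompertz_survival(c(0, 10, 20), a = 0.01, b = 0.1)
#' @export
gompertz_survival <- function(t, a, b) {
  .check_gompertz_params(a, b)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (b == 0) exp(-a * t) else exp(-(a / b) * expm1(b * t))
}

#' Gompertz hazard function
#'
#' Mortality risk \eqn{\lambda(t) = a e^{bt}}. Strictly increasing in `t` when
#' `b > 0`; the increase with time is the signature of aging.
#'
#' @inheritParams gompertz_survival
#' @return Numeric vector of hazard rates.
#' @export
gompertz_hazard <- function(t, a, b) {
  .check_gompertz_params(a, b)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  a * exp(b * t)
}

#' Inverse Gompertz survival function
#'
#' Solves \eqn{S(t) = u} for `t`: the quantile map used by the inverse-CDF
#' lifespan sampler. `u = 1` maps to `t = 0`.
#'
#' @param u Survival probabilities in `(0, 1]`.
#' @inheritParams gompertz_survival
#' @return Times at which survival equals `u`.
#' @export
gompertz_inverse_survival <- function(u, a, b) {
  .check_gompertz_params(a, b)
  if (any(u <= 0 | u > 1)) stop("`u` must be in (0, 1]", call. = FALSE)
  if (b == 0) -log(u) / a else log1p(-(b / a) * log(u)) / b
}

#' Sample Gompertz-distributed lifespans
#'
#' Draws lifespans by inverse-CDF transformation of uniform variates,
#' \eqn{T = S^{-1}(U)}. Deterministic given `seed`. With `b = 0` the draws are
#' exponential with rate `a` (mean `1/a`).
#'
#' @inheritParams gompertz_survival
#' @param n Number of lifespans to draw.
#' @param seed Optional integer seed; when supplied the RNG is seeded so the
#'   draw is reproducible.
#' @return Numeric vector of `n` lifespans.
#' @examples
#' sample_gompertz_lifespans(a = 0.01, b = 0.2, n = 5, seed = 1)
#' @export
sample_gompertz_lifespans <- function(a, b, n, seed = NULL) {
  .check_gompertz_params(a, b)
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  gompertz_inverse_survival(stats::runif(n), a, b)
}

## residual waiting time to a Gompertz event for a cell already at age `age`:
## P(W > w | age) = exp(-(a/b) e^{b*age} (e^{bw} - 1)); used by the population
## model, draws from the current RNG stream (no reseeding).
.rgompertz_wait <- function(n, a, b, age = 0) {
  if (a == 0) return(rep(Inf, n))
  u <- stats::runif(n)
  if (b == 0) -log(u) / a else log1p(-(b / a) * exp(-b * age) * log(u)) / b
}

.check_gompertz_params <- function(a, b) {
  if (length(a) != 1L || !is.finite(a) || a <= 0) {
    stop("initial hazard `a` must be a single positive number", call. = FALSE)
  }
  if (length(b) != 1L || !is.finite(b) || b < 0) {
    stop("aging rate `b` must be a single non-negative number", call. = FALSE)
  }
  invisible(TRUE)
}
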