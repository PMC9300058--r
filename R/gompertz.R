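#' Fixed-endpoint Gompertz growth curve
#'
#' Sigmoidal growth curve reparameterized so that size equals the hatch
#' size `I` at `t = 0` and approaches the adult asymptote `A` as
#' `t -> Inf`:
#'
#' \deqn{size(t) = A \exp\{\log(I/A)\, e^{-k t}\}}
#'
#' `A` and `I` are fixed a priori from adult and hatchling measurements;
#' only the growth coefficient `k` is estimated when fitting. The time
#' axis `t` may be age in days or accumulated daylight hours, in which
#' case `k` is per day or per daylight hour respectively.
#'
#' @param t time on the chosen axis (days or daylight hours), `>= 0`.
#' @param A asymptotic size (g or mm), `> I`.
#' @param I size at hatch (g or mm), `0 < I < A`.
#' @param k growth coefficient (1/day or 1/daylight-hour). May be a
#'   vector of the same length as `t` (per-observation coefficients,
#'   used internally for random-effects models).
#' @return numeric vector of sizes, same length as `t`.
#' @examples
#' gompertz_size(0, A = 2100, I = 65, k = 0.056)   # = 65
#' gompertz_size(30, A = 2100, I = 65, k = 0.056)
#' @export
gompertz_size <- function(t, A, I, k) {
  if (any(!is.finite(A)) || any(!is.finite(I)) || any(A <= 0) || any(I <= 0))
    stop("A and I must be positive and finite")
  if (any(I >= A))
    stop("hatch size I must be strictly smaller than the asymptote A")
  if (any(t < 0))
    stop("t must be non-negative")
  A * exp(log(I / A) * exp(-k * t))
}

# First and second derivatives of the curve with respect to k, used by
# the Newton steps of the mixed-model fit. b = log(I/A) < 0.
gompertz_dk <- function(t, A, I, k) {
  b <- log(I / A)
  ekt <- exp(-k * t)
  m <- A * exp(b * ekt)
  dm <- -t * b * ekt * m
  d2m <- t^2 * b * ekt * m * (1 + b * ekt)
  list(m = m, dm = dm, d2m = d2m)
}

#' Parameter container for a fixed-endpoint Gompertz curve
#'
#' Validates and bundles the `(A, I, k)` triple.
#'
#' @inheritParams gompertz_size
#' @return a list of class `gompertz_params`.
#' @export
gompertz_params <- function(A, I, k) {
  if (!is.finite(A) || !is.finite(I) || A <= 0 || I <= 0 || I >= A)
    stop("require 0 < I < A, both finite")
  if (!is.finite(k))
    stop("k must be finite")
  structure(list(A = A, I = I, k = k), class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz curve: A = %g, I = %g, k = %g\n", x$A, x$I, x$k))
  invisible(x)
}
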