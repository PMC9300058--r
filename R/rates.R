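#' Number of generations in a period
#'
#' @param period_years period of change in years (`> 0`).
#' @param generation_time_years generation time in years (`> 0`);
#'   7.5 years is the standard value for barnacle geese.
#' @return number of generations `g = period / generation_time`.
#' @examples
#' generations(30, 7.5)   # 4
#' @export
generations <- function(period_years, generation_time_years = 7.5) {
  if (period_years <= 0 || generation_time_years <= 0)
    stop("period and generation time must be positive")
  period_years / generation_time_years
}

#' Haldane rate of phenotypic change
#'
#' Rate of change between two contemporaneous populations (synchronic
#' comparison) in pooled phenotypic standard deviations per generation:
#'
#' \deqn{h = \frac{X_2/S_p - X_1/S_p}{g}}
#'
#' The sign follows `X2 - X1`; `h` is antisymmetric in `(X1, X2)` and
#' scales as `1/Sp`.
#'
#' @param X1,X2 trait means of the two populations (e.g. Gompertz
#'   growth coefficients, 1/day).
#' @param Sp pooled phenotypic standard deviation of the trait (`> 0`).
#' @param g number of generations (`> 0`), see [generations()].
#' @return rate in SD units per generation.
#' @examples
#' haldane(X1 = 1, X2 = 2, Sp = 0.5, g = 4)   # 0.5
#' @export
haldane <- function(X1, X2, Sp, g) {
  if (any(Sp <= 0)) stop("Sp must be positive")
  if (any(g <= 0)) stop("g must be positive")
  (X2 / Sp - X1 / Sp) / g
}

#' Back-solve the pooled SD implied by a haldane rate
#'
#' Algebraic inverse of [haldane()]: the `Sp` for which two trait means
#' and a generation count give rate `h`. Useful for reconstructing the
#' pooled SD behind a published rate when the SD itself is not printed.
#'
#' @inheritParams haldane
#' @param h haldane rate (nonzero; must have the sign of `X2 - X1`).
#' @return implied pooled SD.
#' @export
haldane_implied_sp <- function(X1, X2, g, h) {
  if (any(g <= 0)) stop("g must be positive")
  if (any(h == 0)) stop("h must be nonzero to back-solve Sp")
  sp <- (X2 - X1) / (g * h)
  if (any(sp <= 0)) stop("inconsistent signs: implied Sp not positive")
  sp
}

#' Latitude regression on (mass-corrected) growth coefficients
#'
#' Ordinary least squares of a mass-corrected growth coefficient on
#' breeding latitude, as used to compare intraspecific and
#' interspecific latitudinal gradients. The mass correction itself is
#' taxon-specific and user-supplied.
#'
#' @param points data.frame with columns `latitude_deg` and
#'   `corrected_coefficient` (optionally `taxon`).
#' @return list with `slope`, `intercept`, `model` (the `lm`) and
#'   `band(lat)`, a function returning the fitted value with 95%
#'   confidence band at given latitudes.
#' @export
latitude_regression <- function(points) {
  if (nrow(points) < 3) stop("need at least 3 points")
  if (!all(c("latitude_deg", "corrected_coefficient") %in% names(points)))
    stop("points must have latitude_deg and corrected_coefficient")
  if (any(abs(points$latitude_deg) > 90)) stop("|latitude| must be <= 90")
  if (stats::var(points$latitude_deg) == 0)
    stop("degenerate input: latitudes are collinear (constant)")
  fit <- stats::lm(corrected_coefficient ~ latitude_deg, data = points)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       model = fit,
       band = function(lat) {
         p <- stats::predict(fit,
                             newdata = data.frame(latitude_deg = lat),
                             interval = "confidence", level = 0.95)
         data.frame(latitude_deg = lat, fit = p[, "fit"],
                    lower = p[, "lwr"], upper = p[, "upr"])
       })
}
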