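#' Attach the growth time axis to gosling records
#'
#' Adds a column `t` holding the time coordinate on which growth curves
#' are fitted: age in days, or daylight hours accumulated between each
#' gosling's hatch and capture dates (computed per colony from supplied
#' coordinates).
#'
#' @param records gosling records (see [generate_scenario()] /
#'   [read_gosling_csv()]).
#' @param time_axis `"age_days"` or `"daylight_hours"`.
#' @param coords data.frame with columns `population`, `latitude_deg`,
#'   `longitude_deg` (see [colony_coords()]); required for the daylight
#'   axis.
#' @param threshold_deg dawn/dusk solar altitude, degrees.
#' @return `records` with a numeric `t` column and a `time_axis`
#'   attribute.
#' @export
attach_time_axis <- function(records,
                             time_axis = c("age_days", "daylight_hours"),
                             coords = NULL, threshold_deg = -6) {
  time_axis <- match.arg(time_axis)
  if (time_axis == "age_days") {
    records$t <- as.numeric(records$age_days)
  } else {
    if (is.null(coords))
      stop("colony coordinates are required for the daylight axis")
    records$t <- NA_real_
    for (pop in unique(records$population)) {
      row <- coords[coords$population == pop, , drop = FALSE]
      if (nrow(row) != 1)
        stop("missing coordinates for population: ", pop)
      sel <- records$population == pop
      records$t[sel] <- accumulated_daylight(
        row$latitude_deg, row$longitude_deg,
        records$hatch_date[sel], records$capture_date[sel], threshold_deg)
    }
  }
  attr(records, "time_axis") <- time_axis
  records
}

# Resolve the time column for the requested axis.
fit_time <- function(records, time_axis) {
  if (time_axis == "age_days") return(as.numeric(records$age_days))
  if (!is.null(records[["t"]])) return(as.numeric(records[["t"]]))
  stop("daylight axis requested but no t column attached; ",
       "run attach_time_axis() first")
}

fit_subset <- function(records, trait, sex) {
  if (!trait %in% names(records)) stop("unknown trait column: ", trait)
  sel <- records$sex == sex & is.finite(records[[trait]]) &
    records[[trait]] > 0
  records[sel, , drop = FALSE]
}

#' Fit the fixed-effects-only Gompertz growth model
#'
#' Least-squares estimate of the growth coefficient `k` for one sex and
#' trait, with the asymptote `A` and hatch size `I` fixed a priori. The
#' time variable is internally standardized by its mean, which makes
#' the estimate exactly equivariant under rescaling of the time axis.
#'
#' @param records gosling records.
#' @param trait trait column (`"mass_g"`, `"head_mm"`, `"tarsus_mm"`).
#' @param sex `"male"` or `"female"`; the sexes have different
#'   asymptotes and are fitted separately.
#' @param A,I fixed asymptote and hatch size (g or mm).
#' @param time_axis `"age_days"` or `"daylight_hours"` (the latter
#'   requires [attach_time_axis()] to have been run).
#' @return a `branta_fit` object; see [fit_random_gompertz()] for the
#'   fields.
#' @export
fit_fixed_gompertz <- function(records, trait, sex, A, I,
                               time_axis = c("age_days", "daylight_hours")) {
  time_axis <- match.arg(time_axis)
  d <- fit_subset(records, trait, sex)
  if (nrow(d) < 10)
    stop("need at least 10 records of sex ", sex, " with positive ", trait)
  y <- d[[trait]]
  t_raw <- fit_time(d, time_axis)
  tbar <- mean(t_raw)
  ts <- t_raw / tbar
  rss <- function(ks) sum((y - gompertz_size(ts, A, I, ks))^2)
  # coarse grid then golden-section refinement of the scaled coefficient
  grid <- exp(seq(log(0.05), log(50), length.out = 60))
  k0 <- grid[which.min(vapply(grid, rss, 0))]
  opt <- stats::optimize(rss, interval = c(k0 / 4, k0 * 4), tol = 1e-10)
  ks <- opt$minimum
  k <- ks / tbar
  n <- length(y)
  sigma <- sqrt(opt$objective / n)            # ML residual SD
  # curvature-based SE of k on the original scale
  g <- gompertz_dk(ts, A, I, ks)
  info <- sum(g$dm^2) / sigma^2
  se_k <- sqrt(1 / info) / tbar
  loglik <- -n / 2 * (log(2 * pi * sigma^2) + 1)
  npar <- 2                                    # k and sigma
  new_branta_fit(
    fixed_effects = c(k = k),
    standard_errors = c(k = se_k),
    vcov = matrix(se_k^2, 1, 1, dimnames = list("k", "k")),
    variance_components = c(sd_cohort = NA, sd_nest = NA,
                            sd_residual = sigma),
    loglik = loglik, AIC = -2 * loglik + 2 * npar,
    n_obs = n,
    n_nests = length(unique(d$nest_id)),
    n_cohorts = length(unique(d$cohort)),
    time_axis = time_axis, trait = trait, sex = sex, A = A, I = I,
    convergence = TRUE, random = FALSE)
}

new_branta_fit <- function(...) structure(list(...), class = "branta_fit")

#' @export
print.branta_fit <- function(x, ...) {
  cat(sprintf("Fixed-endpoint Gompertz fit (%s, %s, %s axis)\n",
              x$trait, x$sex, x$time_axis))
  cat(sprintf("  A = %g, I = %g (fixed); n = %d goslings, %d nests, %d cohorts\n",
              x$A, x$I, x$n_obs, x$n_nests, x$n_cohorts))
  est <- x$fixed_effects
  se <- x$standard_errors
  for (nm in names(est))
    cat(sprintf("  %-6s %.5g +/- %.3g\n", nm, est[[nm]], se[[nm]]))
  vc <- x$variance_components
  cat(sprintf("  sd_cohort = %s, sd_nest = %s, sd_residual = %.4g\n",
              format(vc[["sd_cohort"]], digits = 3),
              format(vc[["sd_nest"]], digits = 3),
              vc[["sd_residual"]]))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, converged = %s\n",
              x$loglik, x$AIC, x$convergence))
  invisible(x)
}
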