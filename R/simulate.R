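#' Sample capture ages
#'
#' Capture ages are drawn from a discretized triangular distribution on
#' `[capture_age_min, capture_age_max]` whose mode is placed so that the
#' continuous median equals `capture_age_median`, then rounded to whole
#' days and truncated to the support. This reproduces the skewed
#' capture-age samples seen at ringing drives without modelling the
#' drives themselves.
#'
#' @param config a scenario configuration (see [read_scenario()]).
#' @param n number of ages to draw (`> 0`).
#' @return integer vector of ages in days.
#' @export
sample_capture_ages <- function(config, n) {
  if (n <= 0) stop("n must be positive")
  a <- config$capture_age_min
  b <- config$capture_age_max
  m <- config$capture_age_median
  if (a == b) return(rep(as.integer(a), n))
  # mode c chosen so the triangular median equals m
  if (m >= (a + b) / 2) {
    cc <- a + 2 * (m - a)^2 / (b - a)
  } else {
    cc <- b - 2 * (b - m)^2 / (b - a)
  }
  cc <- min(max(cc, a), b)
  u <- stats::runif(n)
  fc <- (cc - a) / (b - a)
  x <- ifelse(u < fc,
              a + sqrt(u * (b - a) * (cc - a)),
              b - sqrt((1 - u) * (b - a) * (b - cc)))
  pmin(pmax(as.integer(round(x)), as.integer(a)), as.integer(b))
}

#' Instrument rounding of a measurement
#'
#' Emulates the field instruments: spring/hand scales reading to the
#' nearest 5 g below 600 g and nearest 10 g above; callipers to 0.1 mm
#' for tarsus; a ruler to 1 mm for head length. Rounding is
#' half-away-from-zero on the instrument grid.
#'
#' @param trait one of `"mass_g"`, `"head_mm"`, `"tarsus_mm"`.
#' @param value positive measurement(s) in grams or millimetres.
#' @return rounded value(s).
#' @examples
#' apply_measurement_rounding("mass_g", 612.4)   # 610
#' apply_measurement_rounding("mass_g", 597.5)   # 600
#' apply_measurement_rounding("tarsus_mm", 43.26) # 43.3
#' @export
apply_measurement_rounding <- function(trait, value) {
  if (any(value <= 0)) stop("measurements must be positive")
  grid_round <- function(x, g) {
    # half-away-from-zero; epsilon guards binary representation of x/g
    sign(x) * floor(abs(x) / g + 0.5 + 1e-9) * g
  }
  switch(trait,
         mass_g = ifelse(value < 600,
                         grid_round(value, 5), grid_round(value, 10)),
         tarsus_mm = grid_round(value, 0.1),
         head_mm = grid_round(value, 1),
         stop("unknown trait: ", trait))
}

#' Generate a synthetic cross-sectional gosling dataset
#'
#' Draws a colony-scale dataset with the structure the growth analysis
#' assumes: goslings clustered in nests within annual cohorts; a
#' nest-level hatch date around the (jittered) cohort mean; one capture
#' per gosling at a triangular-sampled age; trait values on the
#' fixed-endpoint Gompertz curve with Gaussian, mean-zero cohort and
#' nest random effects on the growth coefficient; an additive linear
#' hatch-date effect on size; optional across-year drift; Gaussian
#' residual noise; and instrument rounding.
#'
#' With `axis = "daylight"` the growth clock is accumulated
#' dawn-to-dusk daylight between hatch and capture (computed from the
#' colony coordinates) and the generating coefficients are the
#' daylight-axis entries of `true_k`; random-effect SDs, stored per day,
#' are rescaled by the daylight/age coefficient ratio so relative
#' between-cohort and between-nest variation is axis-invariant.
#'
#' @param config a scenario configuration (see [read_scenario()]).
#' @param axis growth clock: `"age"` (days) or `"daylight"` (hours).
#' @param seed integer seed; defaults to the scenario's `seed` field.
#' @param threshold_deg dawn/dusk solar altitude for the daylight clock.
#' @return a data.frame of gosling records with columns `gosling_id`,
#'   `population`, `sex`, `cohort`, `nest_id`, `hatch_date`,
#'   `capture_date`, `age_days`, `mass_g`, `head_mm`, `tarsus_mm`, and
#'   attributes `cohort_means` (realized colony-wide mean hatch
#'   day-of-year per cohort) and `scenario`.
#' @examples
#' cfg <- scenario_preset("barents")
#' cfg$n_goslings_target <- 60  # desk-scale example
#' head(generate_scenario(cfg, seed = 1))
#' @export
generate_scenario <- function(config, axis = c("age", "daylight"),
                              seed = config$seed, threshold_deg = -6) {
  config <- validate_scenario(unclass(config))
  axis <- match.arg(axis)
  set.seed(seed)

  years <- config$cohort_years
  n_cohorts <- config$n_cohorts
  target <- config$n_goslings_target
  # per-cohort gosling quotas summing exactly to the target
  quota <- diff(round(seq(0, target, length.out = n_cohorts + 1)))
  shift <- stats::rnorm(n_cohorts, 0, config$cohort_hatch_shift_sd)
  cohort_means <- data.frame(population = config$population,
                             cohort = years,
                             mean_hatch_doy = config$mean_hatch_doy + shift)

  pop_tag <- config$population
  rows <- vector("list", n_cohorts)
  for (i in seq_len(n_cohorts)) {
    # fill nests (mean brood size ~ brood_size_mean, at least 1 gosling)
    broods <- integer(0)
    while (sum(broods) < quota[i]) {
      extra <- 1L + stats::rpois(config$nests_per_cohort,
                                 max(config$brood_size_mean - 1, 0))
      broods <- c(broods, extra)
    }
    keep <- which(cumsum(broods) >= quota[i])[1]
    broods <- broods[seq_len(keep)]
    broods[keep] <- broods[keep] - (sum(broods) - quota[i])
    broods <- broods[broods > 0]
    n_nests <- length(broods)
    nest_ids <- sprintf("%s-%d-N%02d", pop_tag, years[i], seq_len(n_nests))
    nest_hatch_doy <- round(stats::rnorm(
      n_nests, config$mean_hatch_doy + shift[i], config$hatch_sd_days))
    rows[[i]] <- data.frame(
      cohort = years[i],
      nest_id = rep(nest_ids, broods),
      hatch_doy = rep(nest_hatch_doy, broods),
      cohort_mean_doy = config$mean_hatch_doy + shift[i])
  }
  df <- do.call(rbind, rows)
  n <- nrow(df)
  df$population <- config$population
  df$gosling_id <- sprintf("%s-%05d", pop_tag, seq_len(n))
  df$sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  df$age_days <- sample_capture_ages(config, n)
  jan1 <- as.Date(paste0(df$cohort, "-01-01"))
  df$hatch_date <- jan1 + df$hatch_doy - 1
  df$capture_date <- df$hatch_date + df$age_days

  if (axis == "age") {
    tvec <- df$age_days
  } else {
    tvec <- accumulated_daylight(config$latitude_deg, config$longitude_deg,
                                 df$hatch_date, df$capture_date,
                                 threshold_deg)
  }

  nests <- unique(df$nest_id)
  year_center <- mean(years)
  true_effects <- list()
  for (tr in TRAITS) {
    k_age <- config$true_k$age[[tr]]
    k_ax <- config$true_k[[axis]][[tr]]
    # random effects stored in 1/day; rescale for the daylight clock
    re_scale <- if (axis == "age") 1 else
      mean(unlist(k_ax)) / mean(unlist(k_age))
    u_cohort <- stats::rnorm(n_cohorts, 0, config$sd_cohort[[tr]] * re_scale)
    u_nest <- stats::rnorm(length(nests), 0, config$sd_nest[[tr]] * re_scale)
    true_effects[[tr]] <- list(cohort = stats::setNames(u_cohort, years),
                               nest = stats::setNames(u_nest, nests))
    eps <- stats::rnorm(n, 0, config$sd_residual[[tr]])
    k_i <- u_cohort[match(df$cohort, years)]
    k_ij <- u_nest[match(df$nest_id, nests)]
    k_fix <- ifelse(df$sex == "male", k_ax$male, k_ax$female)
    A <- ifelse(df$sex == "male",
                config$adult_A[[tr]]$male, config$adult_A[[tr]]$female)
    I <- config$hatch_I[[tr]]
    size <- gompertz_size(tvec, A, I, k_fix + k_i + k_ij) +
      config$hatchdate_slope[[tr]] * (df$hatch_doy - df$cohort_mean_doy) +
      config$year_trend[[tr]] * (df$cohort - year_center) +
      eps
    if (config$apply_rounding) {
      size <- pmax(size, config$hatch_I[[tr]] * 0.05)  # keep sizes positive
      size <- apply_measurement_rounding(tr, size)
    }
    df[[tr]] <- size
  }

  out <- df[, c("gosling_id", "population", "sex", "cohort", "nest_id",
                "hatch_date", "capture_date", "age_days", TRAITS)]
  rownames(out) <- NULL
  attr(out, "cohort_means") <- cohort_means
  attr(out, "scenario") <- config
  attr(out, "axis") <- axis
  attr(out, "true_effects") <- true_effects
  out
}
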