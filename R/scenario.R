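TRAITS <- c("mass_g", "head_mm", "tarsus_mm")
SEXES <- c("male", "female")

#' Read and validate a colony scenario configuration
#'
#' A scenario describes one breeding colony for the synthetic-data
#' generator: coordinates, cohort/nest structure, hatch phenology,
#' capture-age distribution, the generating Gompertz parameters per
#' trait and sex on both time axes, random-effect and residual standard
#' deviations, hatch-date effects and instrument set-up.
#'
#' @param path path to a YAML scenario file.
#' @return a validated scenario list of class `branta_scenario`.
#' @seealso [scenario_preset()] for the shipped colony presets.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  validate_scenario(yaml::read_yaml(path))
}

#' Shipped colony presets
#'
#' @param name one of `"barents"`, `"baltic"`, `"northsea"`.
#' @return a validated scenario list.
#' @examples
#' cfg <- scenario_preset("barents")
#' cfg$n_goslings_target
#' @export
scenario_preset <- function(name = c("barents", "baltic", "northsea")) {
  name <- match.arg(name)
  read_scenario(system.file("extdata", "scenarios",
                            paste0(name, ".yaml"), package = "branta",
                            mustWork = TRUE))
}

#' @rdname read_scenario
#' @param config a scenario list to validate.
#' @export
validate_scenario <- function(config) {
  req <- c("population", "latitude_deg", "longitude_deg", "n_cohorts",
           "cohort_years", "nests_per_cohort", "brood_size_mean",
           "n_goslings_target", "mean_hatch_doy", "hatch_sd_days",
           "capture_age_median", "capture_age_min", "capture_age_max",
           "true_k", "sd_cohort", "sd_nest", "sd_residual",
           "hatchdate_slope", "adult_A", "hatch_I", "seed")
  missing <- setdiff(req, names(config))
  if (length(missing))
    stop("scenario configuration error: missing fields ",
         paste(missing, collapse = ", "))
  if (abs(config$latitude_deg) > 90) stop("configuration error: |latitude| > 90")
  if (length(config$cohort_years) != config$n_cohorts)
    stop("configuration error: cohort_years must have n_cohorts entries")
  with(config, {
    if (!(capture_age_min <= capture_age_median &&
          capture_age_median <= capture_age_max))
      stop("configuration error: need capture_age_min <= median <= max")
  })
  for (tr in TRAITS) {
    for (sx in SEXES) {
      for (ax in c("age", "daylight")) {
        k <- config$true_k[[ax]][[tr]][[sx]]
        if (is.null(k) || k <= 0)
          stop("configuration error: true_k$", ax, "$", tr, "$", sx,
               " must be > 0")
      }
      A <- config$adult_A[[tr]][[sx]]
      I <- config$hatch_I[[tr]]
      if (is.null(A) || is.null(I) || !(0 < I && I < A))
        stop("configuration error: need 0 < hatch_I < adult_A for ", tr)
    }
    for (f in c("sd_cohort", "sd_nest", "sd_residual"))
      if (config[[f]][[tr]] < 0)
        stop("configuration error: ", f, "$", tr, " must be >= 0")
  }
  if (is.null(config$cohort_hatch_shift_sd)) config$cohort_hatch_shift_sd <- 0
  if (is.null(config$year_trend))
    config$year_trend <- stats::setNames(as.list(rep(0, length(TRAITS))), TRAITS)
  if (is.null(config$apply_rounding)) config$apply_rounding <- TRUE
  class(config) <- c("branta_scenario", "list")
  config
}

#' Colony coordinate table from one or more scenarios
#'
#' Convenience for [attach_time_axis()]: builds the
#' population/latitude/longitude lookup from scenario configs.
#'
#' @param ... scenario lists (e.g. from [scenario_preset()]).
#' @return data.frame with columns `population`, `latitude_deg`,
#'   `longitude_deg`.
#' @export
colony_coords <- function(...) {
  cfgs <- list(...)
  do.call(rbind, lapply(cfgs, function(cf)
    data.frame(population = cf$population,
               latitude_deg = cf$latitude_deg,
               longitude_deg = cf$longitude_deg)))
}
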