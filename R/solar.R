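#' Solar declination and equation of time
#'
#' Low-precision solar ephemeris (NOAA/Spencer Fourier series on the
#' fractional year), accurate to a few hundredths of a degree in
#' declination and well under a minute in the equation of time --
#' ample for daylight-duration work.
#'
#' @param date a `Date` vector (evaluated at solar noon).
#' @return a data.frame with columns `date`, `declination_deg`
#'   (in `[-23.45, +23.45]` up to series error) and `eqtime_min`
#'   (minutes, within about +/-17).
#' @export
solar_position <- function(date) {
  date <- as.Date(date)
  if (any(is.na(date))) stop("invalid date")
  doy <- as.integer(format(date, "%j"))
  yr <- as.integer(format(date, "%Y"))
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  year_len <- ifelse(leap, 366, 365)
  # fractional year, radians, at local solar noon
  g <- 2 * pi / year_len * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  data.frame(date = date,
             declination_deg = decl * 180 / pi,
             eqtime_min = eqtime)
}

#' Daylight duration for one or more dates
#'
#' Hours between dawn and dusk at a site, where dawn/dusk are defined by
#' the sun's centre crossing `threshold_deg`. The default `-6` (civil
#' twilight) treats the whole dawn-to-dusk period as daylight, the
#' convention under which goslings can feed; use `-0.8333` for
#' conventional sunrise/sunset (including refraction).
#'
#' Returns 24 when the sun never drops below the threshold (polar day)
#' and 0 when it never rises above it (polar night). Longitude does not
#' affect the duration and is accepted only for interface symmetry.
#'
#' @param lat,lon site coordinates in decimal degrees (`|lat| <= 90`).
#' @param date `Date` vector.
#' @param threshold_deg solar altitude defining dawn/dusk, degrees.
#' @return numeric vector of daylight hours in `[0, 24]`.
#' @export
daylight_duration <- function(lat, lon = 0, date, threshold_deg = -6) {
  if (abs(lat) > 90) stop("|lat| must be <= 90")
  sp <- solar_position(date)
  decl <- sp$declination_deg * pi / 180
  phi <- lat * pi / 180
  h0 <- threshold_deg * pi / 180
  cos_ha <- (sin(h0) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  cos_ha <- pmin(pmax(cos_ha, -1), 1)
  ha <- acos(cos_ha)                 # half the daylight arc, radians
  24 * ha / pi
}

#' Daily and accumulated daylight over a date range
#'
#' @inheritParams daylight_duration
#' @param start,end first and last calendar date (inclusive).
#' @return a data.frame of class `daylight_profile` with columns `date`,
#'   `daylight_h` and `accumulated_h` (running sum, starting at the
#'   first day's duration).
#' @export
daylight_profile <- function(lat, lon = 0, start, end, threshold_deg = -6) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("end must be >= start")
  dates <- seq(start, end, by = "day")
  dl <- daylight_duration(lat, lon, dates, threshold_deg)
  structure(data.frame(date = dates, daylight_h = dl,
                       accumulated_h = cumsum(dl)),
            class = c("daylight_profile", "data.frame"),
            lat = lat, lon = lon, threshold_deg = threshold_deg)
}

#' Daylight hours accumulated between hatching and capture
#'
#' Sums daily daylight over whole days in `[hatch_date, capture_date)`:
#' the hatch day counts, the capture day does not, and coincident dates
#' give 0. All arguments are vectorized (recycled to a common length).
#'
#' @inheritParams daylight_duration
#' @param hatch_date,capture_date `Date` vectors, `capture >= hatch`.
#' @return numeric vector of accumulated daylight hours.
#' @export
accumulated_daylight <- function(lat, lon = 0, hatch_date, capture_date,
                                 threshold_deg = -6) {
  hatch_date <- as.Date(hatch_date); capture_date <- as.Date(capture_date)
  n <- max(length(hatch_date), length(capture_date))
  hatch_date <- rep_len(hatch_date, n)
  capture_date <- rep_len(capture_date, n)
  if (any(capture_date < hatch_date))
    stop("capture_date must not precede hatch_date")
  rng <- range(c(hatch_date, capture_date))
  dates <- seq(rng[1], rng[2], by = "day")
  dl <- daylight_duration(lat, lon, dates, threshold_deg)
  # cumulative daylight before each calendar day
  cum0 <- c(0, cumsum(dl))
  idx <- function(d) as.integer(d - rng[1]) + 1L
  cum0[idx(capture_date)] - cum0[idx(hatch_date)]
}

#' Mean daily daylight over a colony's rearing window
#'
#' The default rearing window of a colony runs from its mean hatch date
#' to that date plus the median capture age: the period over which the
#' typical gosling in the sample grew.
#'
#' @param config a scenario configuration (see [read_scenario()]).
#' @param year calendar year used to anchor day-of-year dates.
#' @param threshold_deg dawn/dusk solar altitude, degrees.
#' @return mean daily daylight in hours.
#' @export
rearing_window_daylight <- function(config, year = 2010, threshold_deg = -6) {
  start <- as.Date(paste0(year, "-01-01")) + config$mean_hatch_doy - 1
  end <- start + config$capture_age_median
  mean(daylight_duration(config$latitude_deg, config$longitude_deg,
                         seq(start, end, by = "day"), threshold_deg))
}
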