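test_that("declination hits the solstice/equinox anchor points", {
  sp <- solar_position(as.Date(c("2010-06-21", "2010-03-20",
                                 "2010-12-21")))
  expect_equal(sp$declination_deg[1], 23.44, tolerance = 0.02)
  expect_lt(abs(sp$declination_deg[2]), 0.7)
  expect_equal(sp$declination_deg[3], -23.44, tolerance = 0.02)
})

test_that("declination is seasonally antisymmetric and eqtime bounded", {
  dates <- seq(as.Date("2011-01-01"), as.Date("2011-12-31"), by = "day")
  sp <- solar_position(dates)
  expect_true(all(abs(sp$declination_deg) <= 23.45 + 0.05))
  expect_true(all(abs(sp$eqtime_min) <= 17))
  # half a year later the declination roughly flips sign; the orbit's
  # ellipticity makes the seasons unequal, so the flip is only good to
  # ~2 degrees near the equinoxes (true for the real sun as well)
  sp2 <- solar_position(dates + 183)
  expect_true(all(abs(sp$declination_deg + sp2$declination_deg) < 2))
})

test_that("daylight handles polar day, polar night and the equator", {
  expect_equal(daylight_duration(68.583, 52.333, as.Date("2010-06-21"),
                                 -6), 24)
  # at 68.6N the midwinter sun never rises but does exceed -6 degrees,
  # so civil polar night needs a higher latitude or the sunrise line
  expect_equal(daylight_duration(68.583, 52.333, as.Date("2010-12-21"),
                                 -0.8333), 0)
  expect_equal(daylight_duration(85, 0, as.Date("2010-12-21"), -6), 0)
  expect_gt(daylight_duration(68.583, 52.333, as.Date("2010-12-21"), -6),
            0)
  expect_equal(daylight_duration(0, 0, as.Date("2010-03-20"), 0),
               12, tolerance = 0.1)
  expect_error(daylight_duration(91, 0, as.Date("2010-06-01")), "lat")
})

test_that("durations agree with an independent ephemeris model", {
  # geosphere::daylength is the Forsythe et al. model at -0.8333 deg
  skip_if_not_installed("geosphere")
  dates <- seq(as.Date("2010-03-01"), as.Date("2010-09-30"), by = "day")
  for (lat in c(51.667, 57.417, 40, 10)) {
    ours <- daylight_duration(lat, 0, dates, threshold_deg = -0.8333)
    ref <- geosphere::daylength(lat, as.integer(format(dates, "%j")))
    expect_lt(max(abs(ours - ref)), 5 / 60)   # within 5 minutes
  }
})

test_that("daylight is symmetric about the June solstice", {
  solstice <- as.Date("2010-06-21")
  for (off in c(10, 30, 60)) {
    d1 <- daylight_duration(51.667, 0, solstice - off, -6)
    d2 <- daylight_duration(51.667, 0, solstice + off, -6)
    expect_lt(abs(d1 - d2) * 60, 10)          # within 10 minutes
  }
})

test_that("accumulated daylight sums whole days, hatch-inclusive", {
  d0 <- as.Date("2010-06-01")
  expect_equal(accumulated_daylight(68.583, 52.333, d0, d0), 0)
  # polar day: 10 full days at 24 h
  expect_equal(accumulated_daylight(80, 0, d0, d0 + 10), 240)
  expect_error(accumulated_daylight(51, 0, d0, d0 - 1), "precede")
})

test_that("accumulated daylight equals a brute-force day-by-day sum", {
  skip_if_not_installed("geosphere")
  hatch <- as.Date("2010-05-25")
  days <- hatch + 0:29
  brute <- sum(geosphere::daylength(51.667,
                                    as.integer(format(days, "%j"))))
  ours <- accumulated_daylight(51.667, 4.233, hatch, hatch + 30,
                               threshold_deg = -0.8333)
  expect_lt(abs(ours - brute), 0.5)
})

test_that("daylight profile is bounded and its accumulation monotone", {
  pr <- daylight_profile(57.417, 18.883, "2010-04-01", "2010-10-01")
  expect_true(all(pr$daylight_h >= 0 & pr$daylight_h <= 24))
  expect_true(all(diff(pr$accumulated_h) >= 0))
  expect_equal(pr$accumulated_h, cumsum(pr$daylight_h))
})
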