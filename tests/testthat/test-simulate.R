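test_that("noise-free generation places every record on its curve", {
  cfg <- noise_free("barents")
  d <- generate_scenario(cfg, seed = 11)
  for (sx in c("male", "female")) {
    sel <- d$sex == sx
    for (tr in c("mass_g", "head_mm", "tarsus_mm")) {
      expected <- gompertz_size(d$age_days[sel],
                                A = cfg$adult_A[[tr]][[sx]],
                                I = cfg$hatch_I[[tr]],
                                k = cfg$true_k$age[[tr]][[sx]])
      expect_equal(d[[tr]][sel], expected, tolerance = 1e-12)
    }
  }
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- preset("baltic", n_goslings_target = 150)
  d1 <- generate_scenario(cfg, seed = 42)
  d2 <- generate_scenario(cfg, seed = 42)
  expect_identical(d1, d2)
  d3 <- generate_scenario(cfg, seed = 43)
  expect_false(identical(d1$mass_g, d3$mass_g))
})

test_that("generated structure matches the scenario", {
  cfg <- scenario_preset("barents")
  d <- generate_scenario(cfg, seed = 5)
  expect_equal(nrow(d), cfg$n_goslings_target)
  expect_setequal(unique(d$cohort), cfg$cohort_years)
  expect_true(all(d$capture_date - d$hatch_date == d$age_days))
  expect_true(all(d$age_days >= cfg$capture_age_min &
                    d$age_days <= cfg$capture_age_max))
  expect_true(all(d$mass_g > 0 & d$head_mm > 0 & d$tarsus_mm > 0))
  # nest ids do not straddle cohorts
  expect_true(all(rowSums(table(d$nest_id, d$cohort) > 0) == 1))
  # sexes near 50/50
  expect_gt(mean(d$sex == "male"), 0.35)
  expect_lt(mean(d$sex == "male"), 0.65)
})

test_that("capture-age sampler reproduces the configured median", {
  cfg <- scenario_preset("barents")
  set.seed(1)
  ages <- sample_capture_ages(cfg, 10000)
  expect_true(all(ages >= 5 & ages <= 42))
  expect_lt(abs(median(ages) - 29), 2)

  cfgB <- scenario_preset("baltic")
  ages <- sample_capture_ages(cfgB, 10000)
  expect_lt(abs(median(ages) - 46), 2)

  degenerate <- preset("barents", capture_age_min = 10,
                       capture_age_median = 10, capture_age_max = 10)
  expect_equal(sample_capture_ages(degenerate, 50), rep(10L, 50))
  expect_error(sample_capture_ages(cfg, 0), "positive")
})

test_that("instrument rounding follows the field protocol", {
  expect_equal(apply_measurement_rounding("mass_g", 612.4), 610)
  expect_equal(apply_measurement_rounding("mass_g", 597.5), 600)
  expect_equal(apply_measurement_rounding("mass_g", 123), 125)
  expect_equal(apply_measurement_rounding("mass_g", 122.4), 120)
  expect_equal(apply_measurement_rounding("tarsus_mm", 43.26), 43.3)
  expect_equal(apply_measurement_rounding("tarsus_mm", 43.24), 43.2)
  expect_equal(apply_measurement_rounding("head_mm", 77.5), 78)
  expect_equal(apply_measurement_rounding("head_mm", 77.49), 77)
  expect_error(apply_measurement_rounding("wing_mm", 100), "unknown trait")
  expect_error(apply_measurement_rounding("mass_g", -5), "positive")
})

test_that("invalid configurations are rejected", {
  bad <- preset("barents")
  bad$hatch_I$mass_g <- 3000          # I >= A
  expect_error(generate_scenario(bad, seed = 1), "hatch_I < adult_A")
  bad2 <- preset("barents")
  bad2$sd_nest$mass_g <- -1
  expect_error(generate_scenario(bad2, seed = 1), "sd_nest")
  bad3 <- preset("barents", capture_age_median = 50)  # median > max
  expect_error(generate_scenario(bad3, seed = 1), "median")
})

test_that("between-nest spread grows with the nest SD", {
  spread <- sapply(c(0.000, 0.005, 0.02), function(sn) {
    cfg <- preset("barents", n_goslings_target = 250,
                  sd_cohort = zero_by_trait,
                  sd_nest = list(mass_g = sn, head_mm = 0, tarsus_mm = 0),
                  sd_residual = list(mass_g = 10, head_mm = 1,
                                     tarsus_mm = 1),
                  hatchdate_slope = zero_by_trait,
                  apply_rounding = FALSE)
    d <- generate_scenario(cfg, seed = 99)
    # per-nest mean deviation from the sex/age expectation
    exp_mass <- gompertz_size(d$age_days, 2100, 65, 0.056)
    exp_mass[d$sex == "female"] <-
      gompertz_size(d$age_days[d$sex == "female"], 1900, 65, 0.059)
    dev <- d$mass_g - exp_mass
    sd(tapply(dev, d$nest_id, mean))
  })
  expect_true(all(diff(spread) > 0))
})

test_that("relative hatch dates recover the configured distribution", {
  cfg <- preset("barents", n_goslings_target = 500)
  d <- generate_scenario(cfg, seed = 21)
  r <- relative_hatch_date(d, attr(d, "cohort_means"))
  expect_lt(abs(mean(r$relative_hatch_date)), 1)
})
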