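res_fixture <- function(seed = 1, n = 400, pops = c("barents", "baltic"),
                        slopes = NULL) {
  datasets <- lapply(seq_along(pops), function(i) {
    cfg <- preset(pops[i], n_goslings_target = round(n / length(pops)))
    if (!is.null(slopes))
      cfg$hatchdate_slope <- list(mass_g = slopes[i], head_mm = 0,
                                  tarsus_mm = 0)
    generate_scenario(cfg, seed = seed + 31 * i)
  })
  d <- do.call(rbind, datasets)
  means <- do.call(rbind, lapply(datasets,
                                 function(x) attr(x, "cohort_means")))
  fx <- lapply(setNames(c("male", "female"), c("male", "female")),
               function(sx)
                 fit_fixed_gompertz(d, "mass_g", sx,
                                    A = if (sx == "male") 2100 else 1900,
                                    I = 65))
  res <- compute_residuals(d, fx, "mass_g")
  relative_hatch_date(res, means)
}

test_that("points on the fitted curve give zero residual, offsets shift it", {
  cfg <- noise_free("barents")
  d <- generate_scenario(cfg, seed = 2)
  fx <- list(male = fit_fixed_gompertz(d, "mass_g", "male", 2100, 65),
             female = fit_fixed_gompertz(d, "mass_g", "female", 1900, 65))
  res <- compute_residuals(d, fx, "mass_g")
  expect_lt(max(abs(res$residual)), 1e-4)
  # translate one gosling by +50 g
  d2 <- d
  d2$mass_g[7] <- d2$mass_g[7] + 50
  res2 <- compute_residuals(d2, fx, "mass_g")
  expect_equal(res2$residual[7] - res$residual[7], 50)
})

test_that("a missing per-sex fit is an error", {
  cfg <- desk("barents", n = 60)
  d <- generate_scenario(cfg, seed = 3)
  fx <- list(male = fit_fixed_gompertz(d, "mass_g", "male", 2100, 65))
  expect_error(compute_residuals(d, fx, "mass_g"), "female")
})

test_that("relative hatch dates are differences from supplied means", {
  d <- data.frame(population = "barents", cohort = 2003,
                  hatch_date = as.Date("2003-07-10") + c(0, 5, -3))
  means <- data.frame(population = "barents", cohort = 2003,
                      mean_hatch_doy = 191)  # 2003-07-10
  r <- relative_hatch_date(d, means)
  expect_equal(r$relative_hatch_date, c(0, 5, -3))
  expect_error(relative_hatch_date(
    data.frame(population = "barents", cohort = 1999,
               hatch_date = as.Date("1999-07-01")), means), "1999")
})

test_that("residual LMM recovers injected hatch-date slopes", {
  r <- res_fixture(seed = 5, n = 700, slopes = c(-8.85, -3.91))
  m <- fit_residual_lmm(r)
  sl <- hatchdate_slopes(m)
  for (case in list(c("barents", -8.85), c("baltic", -3.91))) {
    row <- sl[sl$population == case[1], ]
    expect_lt(row$slope, 0)
    expect_lt(abs(row$slope - as.numeric(case[2])), 3 * row$se)
  }
  # marginal F table covers all fixed terms
  expect_setequal(m$anova$term,
                  c("population", "relative_hatch_date", "sex",
                    "population:relative_hatch_date"))
})

test_that("LMM coefficients match a direct GLS solve", {
  r <- res_fixture(seed = 9, n = 300)
  m <- fit_residual_lmm(r, include_interaction = FALSE,
                        include_sex = FALSE)
  vc <- as.data.frame(lme4::VarCorr(m$model))
  s2 <- setNames(vc$vcov, vc$grp)
  X <- stats::model.matrix(m$model)
  Zc <- stats::model.matrix(~ 0 + factor(paste(population, cohort)), r)
  Zn <- stats::model.matrix(~ 0 + factor(nest_id), r)
  beta <- gls_solve(X, r$residual, Zc, Zn,
                    s2[["cohort_grp"]], s2[["cohort_grp:nest_id"]],
                    s2[["Residual"]])
  expect_equal(unname(lme4::fixef(m$model)), unname(drop(beta)),
               tolerance = 1e-6)
})

test_that("backward AIC keeps strong interactions and drops pure noise", {
  r_sig <- res_fixture(seed = 13, n = 800, slopes = c(-12, 6))
  sel <- backward_aic_select(r_sig)
  expect_true("population:relative_hatch_date" %in% sel$fixed_terms)

  # pure noise: no hatch-date effect, no population difference
  cfg <- preset("barents", n_goslings_target = 300,
                hatchdate_slope = zero_by_trait)
  d <- generate_scenario(cfg, seed = 17)
  fx <- list(male = fit_fixed_gompertz(d, "mass_g", "male", 2100, 65),
             female = fit_fixed_gompertz(d, "mass_g", "female", 1900, 65))
  res <- relative_hatch_date(compute_residuals(d, fx, "mass_g"),
                             attr(d, "cohort_means"))
  sel0 <- backward_aic_select(res)
  expect_false("relative_hatch_date" %in% sel0$fixed_terms &&
                 length(sel0$fixed_terms) == 4)
})

test_that("interaction F test holds its size when no slopes exist", {
  nrep <- 30
  reject <- logical(nrep)
  for (i in seq_len(nrep)) {
    r <- res_fixture(seed = 4000 + i, n = 300, slopes = c(0, 0))
    # occasional replicates estimate a ~0 variance component (warned)
    m <- suppressWarnings(fit_residual_lmm(r))
    pv <- m$anova$p_value[m$anova$term ==
                            "population:relative_hatch_date"]
    reject[i] <- pv < 0.05
  }
  # nominal 5% test; allow binomial slack at 30 replicates
  expect_lte(mean(reject), 0.2)
})

test_that("AIC trace equals -2 logLik + 2 npar for every visited model", {
  r <- res_fixture(seed = 21, n = 300)
  sel <- backward_aic_select(r)
  for (i in seq_len(nrow(sel$trace))) {
    terms <- strsplit(sel$trace$model[i], " \\+ ")[[1]]
    terms <- terms[terms != ""]
    m <- branta:::fit_resid_model(r, terms)
    npar <- length(lme4::fixef(m$model)) + 3  # 2 RE variances + residual
    expect_equal(sel$trace$AIC[i], -2 * m$loglik + 2 * npar,
                 tolerance = 1e-8)
  }
})

test_that("selection respects marginality", {
  terms <- c("population", "relative_hatch_date",
             "population:relative_hatch_date", "sex")
  expect_setequal(branta:::removable_terms(terms),
                  c("population:relative_hatch_date", "sex"))
  expect_setequal(branta:::removable_terms(
    c("population", "relative_hatch_date", "sex")),
    c("population", "relative_hatch_date", "sex"))
})

test_that("slopes are invariant to translating all hatch dates", {
  r <- res_fixture(seed = 25, n = 300)
  m1 <- fit_residual_lmm(r)
  # a constant added to every hatch date shifts the regressor only;
  # the slope estimates must not move
  r2 <- r
  r2$relative_hatch_date <- r2$relative_hatch_date + 10
  m2 <- fit_residual_lmm(r2)
  expect_equal(hatchdate_slopes(m1)$slope, hatchdate_slopes(m2)$slope,
               tolerance = 1e-6)
})

test_that("annual trend recovers an injected drift", {
  cfg <- preset("baltic", n_goslings_target = 600)
  cfg$year_trend <- list(mass_g = -5.6, head_mm = 0, tarsus_mm = 0)
  d <- generate_scenario(cfg, seed = 29)
  fx <- list(male = fit_fixed_gompertz(d, "mass_g", "male", 2100, 65),
             female = fit_fixed_gompertz(d, "mass_g", "female", 1900, 65))
  res <- compute_residuals(d, fx, "mass_g")
  tr <- annual_trend(res)
  expect_equal(tr$n_cohorts, 15)
  expect_true(tr$lower <= -5.6 && -5.6 <= tr$upper)
  # slope x span consistency with the configured total drift
  expect_equal(tr$slope * 15, -5.6 * 15, tolerance = 0.35 * 15)
  expect_error(annual_trend(res[res$cohort %in% 1986:1987, ]),
               "3 distinct cohorts")
})
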