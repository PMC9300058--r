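#' Residuals from the non-random Gompertz fits
#'
#' Subtracts the expected size at each gosling's age (or daylight time)
#' under the sex-specific fixed-effects Gompertz fit from the observed
#' size. Residuals of males and females are returned together and are
#' analysed collectively downstream.
#'
#' @param records gosling records.
#' @param fits_by_sex named list with elements `male` and/or `female`,
#'   each a `branta_fit` from [fit_fixed_gompertz()] for the same trait.
#' @param trait trait column name.
#' @return a data.frame of residual records: clustering keys, dates,
#'   `fitted` and `residual` (observed - predicted, g or mm).
#' @export
compute_residuals <- function(records, fits_by_sex, trait) {
  sexes <- unique(records$sex)
  missing_fit <- setdiff(sexes, names(fits_by_sex))
  if (length(missing_fit))
    stop("no fitted model for sex present in data: ",
         paste(missing_fit, collapse = ", "))
  out <- records[, c("gosling_id", "population", "sex", "cohort",
                     "nest_id", "hatch_date", "capture_date", "age_days")]
  out$fitted <- NA_real_
  for (sx in sexes) {
    f <- fits_by_sex[[sx]]
    sel <- records$sex == sx
    tvec <- fit_time(records[sel, , drop = FALSE], f$time_axis)
    out$fitted[sel] <- gompertz_size(tvec, f$A, f$I,
                                     f$fixed_effects[["k"]])
  }
  out$residual <- records[[trait]] - out$fitted
  attr(out, "trait") <- trait
  out
}

#' Relative hatch date
#'
#' Centralizes hatch dates within each cohort against the colony-wide
#' mean hatch date for that cohort (supplied, e.g. from nest
#' monitoring or the generating scenario -- not recomputed from the
#' captured sample).
#'
#' @param records records with `population`, `cohort` and `hatch_date`.
#' @param cohort_means data.frame with columns `population`, `cohort`,
#'   `mean_hatch_doy` (day of year).
#' @return `records` with a `relative_hatch_date` column in days.
#' @export
relative_hatch_date <- function(records, cohort_means) {
  key <- paste(records$population, records$cohort)
  mkey <- paste(cohort_means$population, cohort_means$cohort)
  idx <- match(key, mkey)
  if (any(is.na(idx)))
    stop("missing colony mean hatch date for cohort(s): ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  doy <- as.integer(format(as.Date(records$hatch_date), "%j"))
  records$relative_hatch_date <- doy - cohort_means$mean_hatch_doy[idx]
  records
}

resid_formula <- function(fixed_terms) {
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ")
  else "1"
  stats::as.formula(paste("residual ~", rhs,
                          "+ (1 | cohort_grp) + (1 | cohort_grp:nest_id)"))
}

#' Linear mixed model for residual size
#'
#' Models residual size against population, relative hatch date, their
#' interaction and sex (fixed effects), with random intercepts for
#' cohort and for nest nested in cohort, fitted by maximum likelihood
#' through \pkg{lme4}. Marginal Wald F tests for the fixed terms use
#' containment denominator degrees of freedom (number of nests minus
#' the rank of the fixed-effects design).
#'
#' @param resids residual records with a `relative_hatch_date` column
#'   (see [compute_residuals()] and [relative_hatch_date()]).
#' @param include_interaction,include_sex include the
#'   population-by-hatch-date interaction / the sex main effect.
#' @return a list of class `branta_rlmm`: `model` (the merMod),
#'   `coefficients` (estimate/SE/t), `anova` (marginal F table),
#'   `AIC`, `loglik`, `formula`.
#' @export
fit_residual_lmm <- function(resids, include_interaction = TRUE,
                             include_sex = TRUE) {
  n_pop <- length(unique(resids$population))
  if (include_interaction && n_pop < 2)
    stop("interaction models need records from at least 2 populations")
  terms <- c(if (n_pop > 1) "population", "relative_hatch_date",
             if (include_interaction && n_pop > 1)
               "population:relative_hatch_date",
             if (include_sex) "sex")
  fit_resid_model(resids, terms)
}

fit_resid_model <- function(resids, fixed_terms) {
  # a cohort is a colony-year; qualify the grouping by population
  resids$cohort_grp <- paste(resids$population, resids$cohort)
  form <- resid_formula(fixed_terms)
  model <- suppressMessages(lme4::lmer(form, data = resids, REML = FALSE))
  if (lme4::isSingular(model, tol = 1e-5))
    warning("singular random-effects fit (a variance component is ~0)")
  beta <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  se <- sqrt(diag(V))
  X <- stats::model.matrix(model)
  df_den <- length(unique(resids$nest_id)) - qr(X)$rank
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), t = unname(beta / se),
                      df = df_den,
                      p_value = unname(2 * stats::pt(-abs(beta / se), df_den)))
  # marginal Wald F per fixed term
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(model), "term.labels")
  ftab <- NULL
  for (j in seq_along(labels)) {
    cols <- which(asgn == j)
    if (!length(cols)) next
    b <- beta[cols]
    Fval <- drop(t(b) %*% solve(V[cols, cols, drop = FALSE], b)) / length(cols)
    ftab <- rbind(ftab, data.frame(
      term = labels[j], df_num = length(cols), df_den = df_den,
      F = Fval, p_value = stats::pf(Fval, length(cols), df_den,
                                    lower.tail = FALSE)))
  }
  structure(list(model = model, coefficients = coefs, anova = ftab,
                 AIC = stats::AIC(model),
                 loglik = as.numeric(stats::logLik(model)),
                 formula = form, fixed_terms = fixed_terms),
            class = "branta_rlmm")
}

#' @export
print.branta_rlmm <- function(x, ...) {
  cat("Residual-size linear mixed model (ML)\n  ")
  print(x$formula)
  print(x$coefficients, digits = 4)
  if (!is.null(x$anova)) {
    cat("Marginal F tests (containment df):\n")
    print(x$anova, digits = 4)
  }
  cat(sprintf("logLik = %.3f, AIC = %.3f\n", x$loglik, x$AIC))
  invisible(x)
}

#' Per-population hatch-date slopes from a residual model
#'
#' Combines the hatch-date main effect and interaction coefficients of
#' a fitted residual model into one slope per population (trait units
#' per day), with delta-method standard errors and Wald 95% CIs.
#'
#' @param rlmm a `branta_rlmm` from [fit_residual_lmm()].
#' @return data.frame with `population`, `slope`, `se`, `lower`,
#'   `upper`.
#' @export
hatchdate_slopes <- function(rlmm) {
  beta <- lme4::fixef(rlmm$model)
  V <- as.matrix(stats::vcov(rlmm$model))
  pops <- levels(factor(rlmm$model@frame$population))
  out <- NULL
  for (pop in pops) {
    L <- stats::setNames(numeric(length(beta)), names(beta))
    L["relative_hatch_date"] <- 1
    inter <- paste0("population", pop, ":relative_hatch_date")
    if (inter %in% names(beta)) L[inter] <- 1
    slope <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    out <- rbind(out, data.frame(population = pop, slope = slope, se = se,
                                 lower = slope - 1.96 * se,
                                 upper = slope + 1.96 * se))
  }
  rownames(out) <- NULL
  out
}

#' Backward AIC selection for the residual model
#'
#' Starts from the full model `population * relative_hatch_date + sex`
#' (plus nested random intercepts) and iteratively removes the term
#' whose removal lowers AIC the most, respecting marginality (the
#' interaction is removed before its main effects); stops when no
#' removal lowers AIC.
#'
#' @param resids residual records (see [fit_residual_lmm()]).
#' @param include_sex include sex in the full model.
#' @return list with `model` (the selected `branta_rlmm`),
#'   `fixed_terms` and `trace` (a data.frame of every model visited:
#'   step, dropped term, fixed terms, AIC).
#' @export
backward_aic_select <- function(resids, include_sex = TRUE) {
  n_pop <- length(unique(resids$population))
  terms <- c(if (n_pop > 1) "population", "relative_hatch_date",
             if (n_pop > 1) "population:relative_hatch_date",
             if (include_sex) "sex")
  current <- fit_resid_model(resids, terms)
  trace <- data.frame(step = 0L, dropped = "",
                      model = paste(terms, collapse = " + "),
                      AIC = current$AIC)
  step <- 0L
  repeat {
    step <- step + 1L
    droppable <- removable_terms(current$fixed_terms)
    if (!length(droppable)) break
    cands <- lapply(droppable, function(tm)
      fit_resid_model(resids, setdiff(current$fixed_terms, tm)))
    aics <- vapply(cands, function(x) x$AIC, 0)
    for (i in seq_along(droppable))
      trace <- rbind(trace, data.frame(
        step = step, dropped = droppable[i],
        model = paste(cands[[i]]$fixed_terms, collapse = " + "),
        AIC = aics[i]))
    best <- which.min(aics)
    if (aics[best] >= current$AIC) break
    current <- cands[[best]]
  }
  list(model = current, fixed_terms = current$fixed_terms, trace = trace)
}

# terms that can be dropped without violating marginality
removable_terms <- function(terms) {
  out <- character(0)
  for (tm in terms) {
    if (grepl(":", tm)) { out <- c(out, tm); next }
    parents <- terms[grepl(":", terms)]
    involved <- any(vapply(parents, function(p)
      tm %in% strsplit(p, ":")[[1]], TRUE))
    if (!involved) out <- c(out, tm)
  }
  out
}

#' Across-year trend in residual size
#'
#' Linear regression of residual size on cohort year with nest-level
#' random intercepts; the slope is the annual change in trait units
#' per year.
#'
#' @param resids residual records spanning at least 3 distinct cohorts.
#' @return list with `slope`, `se`, `lower`, `upper` (Wald 95% CI),
#'   `n_cohorts` and the fitted `model`.
#' @export
annual_trend <- function(resids) {
  years <- unique(resids$cohort)
  if (length(years) < 3)
    stop("annual trend needs at least 3 distinct cohorts")
  resids$year_c <- resids$cohort - mean(years)
  model <- suppressMessages(
    lme4::lmer(residual ~ year_c + (1 | nest_id), data = resids,
               REML = FALSE))
  beta <- lme4::fixef(model)[["year_c"]]
  se <- sqrt(diag(as.matrix(stats::vcov(model))))[[2]]
  list(slope = beta, se = se,
       lower = beta - 1.96 * se, upper = beta + 1.96 * se,
       n_cohorts = length(years), model = model)
}
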