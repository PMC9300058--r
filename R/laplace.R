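# Laplace-approximated maximum likelihood for the fixed-endpoint
# Gompertz model with Gaussian, mean-zero random effects on the growth
# coefficient: k_total = k (+ population dummies) + k_i (cohort) +
# k_ij (nest within cohort). The marginal likelihood integrates the
# random effects out with a Laplace approximation at their joint mode;
# modes are found per cohort (blocks are independent given the fixed
# parameters) by damped Newton steps with the exact Hessian of the
# penalized least-squares criterion.

# One inner solve for a cohort block. v = (u_cohort, u_nest[1..J]).
# Returns the mode, the penalized criterion at the mode and log det of
# the Hessian (all on the scaled time axis).
newton_block <- function(y, ts, A, I, kfix, nest_idx, J, v, sc2, sn2, se2) {
  pen <- function(v) {
    ktot <- kfix + v[1] + v[1 + nest_idx]
    r <- y - gompertz_size(ts, A, I, ktot)
    out <- sum(r^2) / (2 * se2) + v[1]^2 / (2 * sc2) +
      sum(v[-1]^2) / (2 * sn2)
    if (!is.finite(out)) Inf else out
  }
  # penalized-criterion Hessian at v (exact, with Gauss-Newton and then
  # ridge fallbacks when not positive definite); returns the Cholesky too
  hess_at <- function(v) {
    ktot <- kfix + v[1] + v[1 + nest_idx]
    g <- gompertz_dk(ts, A, I, ktot)
    r <- y - g$m
    build <- function(h_obs) {
      hn <- rowsum(h_obs, nest_idx, reorder = TRUE)[, 1]
      H <- matrix(0, 1 + J, 1 + J)
      H[1, 1] <- sum(h_obs) + 1 / sc2
      diag(H)[-1] <- hn + 1 / sn2
      H[1, -1] <- H[-1, 1] <- hn
      H
    }
    H <- build((g$dm^2 - r * g$d2m) / se2)
    ch <- if (all(is.finite(H)))
      tryCatch(chol(H), error = function(e) NULL) else NULL
    if (is.null(ch)) {                      # fall back to Gauss-Newton
      H <- build(g$dm^2 / se2)
      ch <- if (all(is.finite(H)))
        tryCatch(chol(H), error = function(e) NULL) else NULL
    }
    if (is.null(ch)) {                      # last resort: drop couplings
      H <- diag(c(1 / sc2, rep(1 / sn2, J)), 1 + J)
      ch <- chol(H)
    }
    gn <- rowsum(-r * g$dm / se2, nest_idx, reorder = TRUE)[, 1]
    grad <- c(sum(-r * g$dm / se2) + v[1] / sc2, gn + v[-1] / sn2)
    list(H = H, ch = ch, grad = grad)
  }
  f0 <- pen(v)
  if (!is.finite(f0)) { v <- rep(0, 1 + J); f0 <- pen(v) }
  hh <- hess_at(v)
  for (iter in 1:60) {
    if (any(!is.finite(hh$grad))) break
    delta <- backsolve(hh$ch, forwardsolve(t(hh$ch), hh$grad))
    if (any(!is.finite(delta))) break
    step <- 1
    accepted <- FALSE
    repeat {
      v_new <- v - step * delta
      f_new <- pen(v_new)
      if (is.finite(f_new) && f_new <= f0 + 1e-12) {
        accepted <- TRUE
        break
      }
      step <- step / 2
      if (step < 1e-6) break
    }
    if (!accepted) break                    # keep the last good mode
    moved <- max(abs(step * delta))
    v <- v_new; f0 <- f_new
    hh <- hess_at(v)
    if (moved < 1e-10) break
  }
  list(v = v, f = f0, logdet = 2 * sum(log(diag(hh$ch))))
}

# Negative marginal log-likelihood factory; warm-starts the inner modes
# across outer evaluations.
laplace_nll_factory <- function(y, ts, A, I, X, cohort, nest) {
  cohort_f <- factor(cohort)
  blocks <- lapply(split(seq_along(y), cohort_f), function(idx) {
    nest_f <- factor(nest[idx])
    list(idx = idx, y = y[idx], ts = ts[idx],
         A = if (length(A) > 1) A[idx] else rep(A, length(idx)),
         X = X[idx, , drop = FALSE],
         nest_idx = as.integer(nest_f), J = nlevels(nest_f))
  })
  warm <- lapply(blocks, function(b) rep(0, 1 + b$J))
  p <- ncol(X)
  n <- length(y)
  function(theta) {
    kvec <- theta[seq_len(p)]
    sc2 <- exp(2 * theta[p + 1])
    sn2 <- exp(2 * theta[p + 2])
    se2 <- exp(2 * theta[p + 3])
    nll <- n / 2 * log(2 * pi * se2)
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      kfix <- drop(b$X %*% kvec)
      sol <- newton_block(b$y, b$ts, b$A, I, kfix, b$nest_idx, b$J,
                          warm[[bi]], sc2, sn2, se2)
      warm[[bi]] <<- sol$v
      q <- 1 + b$J
      nll <- nll + sol$f +
        0.5 * log(2 * pi * sc2) + b$J / 2 * log(2 * pi * sn2) -
        q / 2 * log(2 * pi) + 0.5 * sol$logdet
    }
    nll
  }
}

#' Fit the Gompertz model with nested cohort/nest random effects
#'
#' Maximum-likelihood fit of the fixed-endpoint Gompertz curve with
#' Gaussian, mean-zero random effects on the growth coefficient for
#' cohort and for nest nested within cohort. The marginal likelihood is
#' Laplace-approximated: random-effect modes are found per cohort by
#' damped Newton iterations (penalized least squares), and the outer
#' optimization runs bounded quasi-Newton over the fixed coefficient(s)
#' and the log standard deviations. Standard errors come from the
#' numerical Hessian of the marginal log-likelihood.
#'
#' The time variable is standardized by its mean internally, so
#' estimates transform exactly under rescaling of the time axis.
#'
#' @inheritParams fit_fixed_gompertz
#' @return an object of class `branta_fit`: a list with elements
#'   `fixed_effects`, `standard_errors`, `vcov`, `variance_components`
#'   (`sd_cohort`, `sd_nest`, `sd_residual`), `loglik`, `AIC`, `n_obs`,
#'   `n_nests`, `n_cohorts`, `time_axis`, `convergence` and
#'   `boundary` (TRUE when a variance component collapsed to the lower
#'   boundary).
#' @examples
#' cfg <- scenario_preset("barents")
#' cfg$n_goslings_target <- 120
#' d <- generate_scenario(cfg, seed = 1)
#' fit_random_gompertz(d, "mass_g", "male", A = 2100, I = 65)
#' @export
fit_random_gompertz <- function(records, trait, sex, A, I,
                                time_axis = c("age_days", "daylight_hours")) {
  time_axis <- match.arg(time_axis)
  d <- fit_subset(records, trait, sex)
  if (length(unique(d$cohort)) < 2)
    stop("need at least 2 cohorts for the nested random-effects model")
  fit_laplace_engine(d, trait, sex, A, I, time_axis, contrast = FALSE)
}

# Shared engine for the single-population and population-contrast fits.
fit_laplace_engine <- function(d, trait, sex, A, I, time_axis,
                               contrast, reference = NULL) {
  y <- d[[trait]]
  t_raw <- fit_time(d, time_axis)
  tbar <- mean(t_raw)
  ts <- t_raw / tbar
  n <- length(y)

  if (contrast) {
    pops <- c(reference, sort(setdiff(unique(d$population), reference)))
    X <- cbind(k = rep(1, n))
    for (pop in pops[-1])
      X <- cbind(X, as.numeric(d$population == pop))
    colnames(X) <- c("k", paste0("dk_", pops[-1]))
  } else {
    X <- cbind(k = rep(1, n))
  }
  p <- ncol(X)

  # starting values from the fixed-effects fit on the reference data
  ref_d <- if (contrast) d[d$population == reference, , drop = FALSE] else d
  Aref <- if (length(A) > 1) A[1] else A
  f0 <- fit_fixed_gompertz(ref_d, trait, sex, Aref, I, time_axis)
  k0s <- f0$fixed_effects[["k"]] * tbar
  Avec <- if (length(A) > 1) A else rep(A, n)
  # starting residual SD from the start model over the full data (the
  # reference fit alone is degenerate when other populations misfit or
  # the data are noise-free); floored away from zero
  sig0 <- max(sqrt(mean((y - gompertz_size(ts, Avec, I, k0s))^2)),
              1e-6 * mean(abs(y)))
  start <- c(k0s, rep(0, p - 1), log(0.1 * k0s), log(0.1 * k0s), log(sig0))
  # a cohort is a colony-year: qualify grouping keys by population so
  # multi-population data never shares clusters across colonies
  cohort_key <- paste(d$population, d$cohort)
  nest_key <- paste(d$population, d$nest_id)
  nll <- laplace_nll_factory(y, ts, Avec, I, X, cohort_key, nest_key)
  lower <- c(rep(-Inf, p), log(1e-6 * k0s), log(1e-6 * k0s),
             log(1e-4 * sig0))
  upper <- c(rep(Inf, p), log(10 * k0s), log(10 * k0s), log(100 * sig0))
  opt <- stats::nlminb(start, nll, lower = lower, upper = upper,
                       control = list(rel.tol = 1e-10, iter.max = 400))
  theta <- opt$par
  boundary <- any(theta[(p + 1):(p + 2)] < lower[(p + 1):(p + 2)] + 0.5)

  vc <- c(sd_cohort = exp(theta[p + 1]) / tbar,
          sd_nest = exp(theta[p + 2]) / tbar,
          sd_residual = exp(theta[p + 3]))

  # SEs from the numerical Hessian over interior parameters only: a
  # variance component pinned at its lower boundary is not an interior
  # ML estimate and would make the full Hessian singular
  at_bound <- theta[(p + 1):(p + 3)] < lower[(p + 1):(p + 3)] + 0.5
  free <- c(seq_len(p), p + which(!at_bound))
  nll_free <- function(th) {
    full <- theta
    full[free] <- th
    nll(full)
  }
  H <- tryCatch(pracma::hessian(nll_free, theta[free]),
                error = function(e) NULL)
  Vf <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  V <- NULL
  if (!is.null(Vf)) {
    V <- matrix(NA_real_, p + 3, p + 3)
    V[free, free] <- Vf
  }
  dV <- if (is.null(V)) NA_real_ else diag(V)[seq_len(p)]
  if (any(!is.finite(dV)) || any(dV < 0)) {
    warning("singular Hessian: standard errors reported as missing")
    se_fix <- rep(NA_real_, p)
    vcov_fix <- matrix(NA_real_, p, p)
  } else {
    vcov_fix <- V[seq_len(p), seq_len(p), drop = FALSE] / tbar^2
    se_fix <- sqrt(diag(vcov_fix))
  }
  est <- theta[seq_len(p)] / tbar
  names(est) <- names(se_fix) <- colnames(X)
  dimnames(vcov_fix) <- list(colnames(X), colnames(X))

  loglik <- -opt$objective
  npar <- p + 3
  out <- new_branta_fit(
    fixed_effects = est, standard_errors = se_fix, vcov = vcov_fix,
    variance_components = vc,
    loglik = loglik, AIC = -2 * loglik + 2 * npar,
    n_obs = n,
    n_nests = length(unique(nest_key)),
    n_cohorts = length(unique(cohort_key)),
    time_axis = time_axis, trait = trait, sex = sex,
    A = if (length(A) > 1) unique(A) else A, I = I,
    convergence = opt$convergence == 0, random = TRUE,
    boundary = boundary)
  if (contrast) out$populations <- pops
  out
}

#' Joint population-contrast Gompertz fit
#'
#' Fits all populations jointly with dummy-coded differences in the
#' growth coefficient relative to a reference population (the random
#' effects structure of [fit_random_gompertz()] is retained). Each
#' dummy coefficient is the difference between that population's growth
#' coefficient and the reference's; Wald t statistics use containment
#' degrees of freedom (number of nests minus number of fixed effects).
#'
#' @inheritParams fit_fixed_gompertz
#' @param reference reference population label (default `"barents"`).
#' @param populations populations expected in the data; any that are
#'   absent have their dummy dropped with a warning.
#' @return a list with elements `fit` (a `branta_fit`) and `contrasts`
#'   (a data.frame of all ordered pairwise differences in `k`, with
#'   `estimate`, `se`, `t`, `df` and `p_value`).
#' @export
fit_population_contrast <- function(records, trait, sex, A, I,
                                    time_axis = c("age_days",
                                                  "daylight_hours"),
                                    reference = "barents",
                                    populations = NULL) {
  time_axis <- match.arg(time_axis)
  d <- fit_subset(records, trait, sex)
  pops_present <- unique(d$population)
  if (!is.null(populations)) {
    absent <- setdiff(populations, pops_present)
    if (length(absent))
      warning("population(s) absent from data, dummy dropped: ",
              paste(absent, collapse = ", "))
  }
  if (!reference %in% pops_present)
    stop("reference population ", reference, " absent from data")
  if (length(pops_present) < 2)
    stop("need records from at least 2 populations")
  fit <- fit_laplace_engine(d, trait, sex, A, I, time_axis,
                            contrast = TRUE, reference = reference)
  pops <- fit$populations
  # per-population k and full covariance on the (k, dk...) scale
  p <- length(pops)
  L <- rbind(ref = c(1, rep(0, p - 1)))
  if (p > 1) for (j in 2:p) {
    row <- c(1, rep(0, p - 1)); row[j] <- 1
    L <- rbind(L, row)
  }
  rownames(L) <- pops
  k_pop <- drop(L %*% fit$fixed_effects)
  V_pop <- L %*% fit$vcov %*% t(L)
  df <- fit$n_nests - length(fit$fixed_effects)
  pairs <- expand.grid(pop1 = pops, pop2 = pops,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$pop1 != pairs$pop2, ]
  est <- k_pop[pairs$pop1] - k_pop[pairs$pop2]
  se <- sqrt(diag(V_pop)[pairs$pop1] + diag(V_pop)[pairs$pop2] -
               2 * V_pop[cbind(pairs$pop1, pairs$pop2)])
  tval <- est / se
  contrasts <- data.frame(pairs, estimate = unname(est), se = unname(se),
                          t = unname(tval), df = df,
                          p_value = unname(2 * stats::pt(-abs(tval), df)),
                          row.names = NULL)
  list(fit = fit, contrasts = contrasts)
}
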