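# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Golden-section minimizer (no stats::optimize) for 1-D least squares.
golden_min <- function(f, lo, hi, tol = 1e-12) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c); fd <- f(d)
  while (abs(b - a) > tol * (abs(a) + abs(b))) {
    if (fc < fd) { b <- d; d <- c; fd <- fc
      c <- b - gr * (b - a); fc <- f(c)
    } else { a <- c; c <- d; fc <- fd
      d <- a + gr * (b - a); fd <- f(d) }
  }
  (a + b) / 2
}

# Exact marginal log-likelihood of the nested random-effects Gompertz
# model by brute-force nested adaptive quadrature: for each cohort,
# integrate the cohort effect; inside, each nest's effect is integrated
# independently. Feasible only for tiny instances.
quadrature_loglik <- function(d, trait, A, I, k, sd_c, sd_n, sd_e,
                              half_width = 8) {
  y_all <- d[[trait]]
  t_all <- d$age_days
  ll <- 0
  for (ch in unique(d$cohort)) {
    sel <- d$cohort == ch
    dd <- d[sel, , drop = FALSE]
    nest_lik <- function(u_c, nest) {
      i <- dd$nest_id == nest
      y <- dd[[trait]][i]; t <- dd$age_days[i]
      f <- function(u_n) {
        vapply(u_n, function(u) {
          mu <- A * exp(log(I / A) * exp(-(k + u_c + u) * t))
          prod(stats::dnorm(y, mu, sd_e)) * stats::dnorm(u, 0, sd_n)
        }, 0)
      }
      stats::integrate(f, -half_width * sd_n, half_width * sd_n,
                       rel.tol = 1e-10)$value
    }
    outer_f <- function(u_c) {
      vapply(u_c, function(u) {
        prod(vapply(unique(dd$nest_id), function(ns) nest_lik(u, ns), 0)) *
          stats::dnorm(u, 0, sd_c)
      }, 0)
    }
    Lc <- stats::integrate(outer_f, -half_width * sd_c,
                           half_width * sd_c, rel.tol = 1e-9)$value
    ll <- ll + log(Lc)
  }
  ll
}

# Direct GLS solve for a Gaussian mixed model with known variance
# components: beta = (X' V^-1 X)^-1 X' V^-1 y.
gls_solve <- function(X, y, Zc, Zn, s2c, s2n, s2e) {
  V <- s2e * diag(length(y)) + s2c * Zc %*% t(Zc) + s2n * Zn %*% t(Zn)
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}
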