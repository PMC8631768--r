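# Shared fixtures and independent oracles.
#
# The oracles deliberately avoid the package's closed-form paths: they solve
# the same physical statements by bisection so that estimator equivalence is
# a genuine cross-check.

default_params <- function(...) leaf_phys_params(...)
example_params <- function() {
  # the worked-example parameter set used in several fixtures
  leaf_phys_params(vcmax = 80, jmax = 140, rd = 1, gamma_star = 40,
                   kc = 404, ko = 278, o2 = 210, theta_j = 0.9, alpha_j = 0.3)
}
std_env <- function(...) environment_state(...)

# Bisection on f over [lo, hi]; assumes a sign change.
bisect <- function(f, lo, hi, tol = 1e-12, maxit = 300) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# Oracle 1: steady-state Cc by bisection on the supply/demand residual.
oracle_steady_cc <- function(params, gsc, gm, env) {
  gtot <- 1 / (1 / gsc + 1 / gm)
  j <- j_light_response(env$ppfd, params$jmax, params$alpha_j, params$theta_j)
  km <- params$kc * (1 + params$o2 / params$ko)
  f <- function(cc) {
    ac <- params$vcmax * (cc - params$gamma_star) / (cc + km)
    aj <- j * (cc - params$gamma_star) / (4 * cc + 8 * params$gamma_star)
    gtot * (env$ca - cc) - (min(ac, aj) - params$rd)
  }
  bisect(f, 1e-9, env$ca + params$rd / gtot + 50)
}

# Oracle 2: variable-J gm by solving Aj(Cc) = Pn + Rd for Cc by bisection,
# then gm = Pn / (Ci - Cc).
oracle_variable_j_gm <- function(pn, ci, j, rd, gamma_star) {
  f <- function(cc) {
    j * (cc - gamma_star) / (4 * cc + 8 * gamma_star) - (pn + rd)
  }
  # Aj is increasing in cc with asymptote j/4 > pn + rd guaranteed by caller
  cc <- bisect(f, gamma_star + 1e-9, 1e7, tol = 1e-10)
  pn / (ci - cc)
}

# Analytic dAc/dCc of the Rubisco-limited branch.
analytic_dac_dcc <- function(cc, params) {
  km <- params$kc * (1 + params$o2 / params$ko)
  params$vcmax * (params$gamma_star + km) / (cc + km)^2
}
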