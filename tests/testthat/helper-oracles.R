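# Independent numeric oracles used across tests.

# truncated-normal mean by adaptive quadrature (independent of the
# Mills-ratio implementation under test)
quad_trunc_mean <- function(mu, sigma, lo, hi) {
  lo_f <- max(lo, mu - 12 * sigma)
  hi_f <- min(hi, mu + 12 * sigma)
  z <- stats::integrate(function(x) stats::dnorm(x, mu, sigma), lo_f, hi_f,
                        rel.tol = 1e-10)$value
  m <- stats::integrate(function(x) x * stats::dnorm(x, mu, sigma), lo_f, hi_f,
                        rel.tol = 1e-10)$value
  m / z
}

# truncated-normal skewness by adaptive quadrature
quad_trunc_skew <- function(mu, sigma, lo, hi) {
  lo_f <- max(lo, mu - 12 * sigma)
  hi_f <- min(hi, mu + 12 * sigma)
  z <- stats::integrate(function(x) stats::dnorm(x, mu, sigma), lo_f, hi_f,
                        rel.tol = 1e-11)$value
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mu, sigma), lo_f, hi_f,
                         rel.tol = 1e-11)$value / z
  m2 <- stats::integrate(function(x) (x - m1)^2 * stats::dnorm(x, mu, sigma),
                         lo_f, hi_f, rel.tol = 1e-11)$value / z
  m3 <- stats::integrate(function(x) (x - m1)^3 * stats::dnorm(x, mu, sigma),
                         lo_f, hi_f, rel.tol = 1e-11)$value / z
  m3 / m2^1.5
}

# small experiment configuration for fast pipeline tests
tiny_config <- function(n_participants = 10, ...) {
  experiment_config(n_participants = n_participants, ...)
}
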