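# Studentized-range upper tail by direct numerical quadrature: the range
# CDF of k standard normals evaluated at q*s, integrated over the density
# of s = sqrt(chisq_df / df). Reference for the Tukey HSD adjusted p values.
oracle_srange_upper <- function(q, k, df) {
  range_cdf <- function(w) {
    if (w <= 0) return(0)
    f <- function(z) k * dnorm(z) * (pnorm(z) - pnorm(z - w))^(k - 1)
    integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-13)$value
  }
  dens_s <- function(s) exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
                              (df - 1) * log(s) - df * s^2 / 2)
  integrand <- function(s) vapply(s, function(si) dens_s(si) * range_cdf(q * si),
                                  numeric(1))
  1 - integrate(integrand, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-13)$value
}
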