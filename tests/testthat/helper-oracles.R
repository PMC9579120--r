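# Independent numerical oracles used to freeze expected values.

# Modified Bessel function of the first kind by its power series,
# independent of base R's besselI.
bessel_i_series <- function(x, nu, terms = 80) {
  k <- 0:(terms - 1)
  sum((x / 2)^(2 * k + nu) / (factorial(k) * gamma(k + nu + 1)))
}

# von Mises density straight from its definition
vm_density_oracle <- function(x, mu, kappa) {
  exp(kappa * cos(x - mu)) / (2 * pi * bessel_i_series(kappa, 0))
}

# mean resultant length A(kappa) = I1/I0 from the series oracle
bessel_ratio_oracle <- function(kappa) {
  if (kappa == 0) return(0)
  bessel_i_series(kappa, 1) / bessel_i_series(kappa, 0)
}

# quadrature of a density over one full circle
circle_integral <- function(f, ...) {
  integrate(f, -pi, pi, ..., rel.tol = 1e-10, subdivisions = 500L)$value
}

# small synthetic trial table with explicit values, no simulator involved
tiny_trials <- function(response, target, nts = NULL) {
  df <- data.frame(id = 1, response = response, target = target)
  if (!is.null(nts)) for (j in seq_len(ncol(nts))) df[[paste0("non_target_", j)]] <- nts[, j]
  df
}
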