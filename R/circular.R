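#' Wrap angles onto the circle
#'
#' Maps arbitrary angles (radians) onto the canonical interval (-pi, pi].
#' All internal computation in circmix uses this convention.
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector of the same length with values in (-pi, pi].
#' @examples
#' wrap_angle(c(0, 3 * pi, -3 * pi / 2))
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x)) stop("angles must be numeric", call. = FALSE)
  bad <- !is.finite(x) & !is.na(x)
  if (any(bad)) stop("non-finite angle value(s) at position(s): ",
                     paste(which(bad), collapse = ", "), call. = FALSE)
  out <- x - 2 * pi * floor(x / (2 * pi) + 0.5)
  # floor-based reduction lands on [-pi, pi); move -pi to +pi for (-pi, pi]
  out[!is.na(out) & out <= -pi] <- pi
  out
}

#' Convert angular data to canonical radians
#'
#' Converts values expressed in one of the three supported angular units to
#' radians wrapped onto (-pi, pi]. `"degrees"` covers a full circle (1-360);
#' `"degrees_180"` is for axial data such as bar orientations (1-180) and is
#' doubled onto the full circle before conversion, the standard treatment of
#' axial data (fitted concentrations then live in the doubled space);
#' `"radians"` accepts either 0 to 2*pi or -pi to pi and is wrapped.
#'
#' @param values Numeric vector in the declared unit.
#' @param unit One of `"degrees"`, `"degrees_180"`, `"radians"`.
#' @return Numeric vector of radians in (-pi, pi].
#' @examples
#' convert_to_radians(180, "degrees")
#' convert_to_radians(90, "degrees_180")
#' @export
convert_to_radians <- function(values, unit = c("degrees", "degrees_180", "radians")) {
  unit <- match.arg(unit)
  v <- values
  rng <- switch(unit,
    degrees = c(0, 360),
    degrees_180 = c(-180, 180),
    radians = c(-pi, 2 * pi)
  )
  out_of_range <- !is.na(v) & (v < rng[1] | v > rng[2])
  if (any(out_of_range)) {
    warning(sum(out_of_range), " value(s) outside the declared '", unit,
            "' range; wrapping onto the circle", call. = FALSE)
  }
  switch(unit,
    degrees = wrap_angle(v * pi / 180),
    degrees_180 = wrap_angle(v * 2 * pi / 180),
    radians = wrap_angle(v)
  )
}

#' von Mises probability density
#'
#' Density of the von Mises distribution, the circular analogue of the normal:
#' `exp(kappa * cos(x - mu)) / (2 * pi * I0(kappa))`. Evaluated through
#' exponentially scaled Bessel functions so that concentrations of several
#' hundred (routine in fitting) do not overflow.
#'
#' @param x Numeric vector of angles (radians).
#' @param mu Mean direction (radians). Default 0.
#' @param kappa Concentration parameter, `kappa >= 0`. `kappa = 0` gives the
#'   circular uniform density `1 / (2 * pi)`.
#' @param log Return the log density?
#' @return Numeric vector of densities (or log densities).
#' @examples
#' dvonmises(0, 0, 0)       # 1 / (2 * pi)
#' dvonmises(0, 0, 8)
#' @export
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  if (any(!is.finite(kappa)) || any(kappa < 0))
    stop("kappa must be finite and >= 0", call. = FALSE)
  # log I0(kappa) via the exponentially scaled Bessel function
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  ld <- kappa * cos(x - mu) - log(2 * pi) - log_i0
  if (log) ld else exp(ld)
}

#' Sample from the von Mises distribution
#'
#' Draws i.i.d. angles by the Best-Fisher (1979) wrapped-Cauchy envelope
#' rejection method; `kappa = 0` falls back to uniform sampling on the circle.
#'
#' @param n Number of draws (`n >= 1`).
#' @param mu Mean direction (radians).
#' @param kappa Concentration, `kappa >= 0`.
#' @return Numeric vector of `n` angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be finite and >= 0", call. = FALSE)
  n <- as.integer(n)
  if (kappa == 0) return(wrap_angle(runif(n, -pi, pi)))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    m <- ceiling(m * 1.3)  # modest oversampling to limit loop rounds
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    keep <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    theta <- sign(u3[keep] - 0.5) * acos(f[keep])
    out <- c(out, theta)
  }
  wrap_angle(mu + out[seq_len(n)])
}

#' Circular moments of a sample of angles
#'
#' First trigonometric moment of a sample: mean direction, resultant vector
#' length `R` (1 = all angles identical, 0 = fully dispersed) and the circular
#' standard deviation `sqrt(-2 * log(R))`. When `R` is numerically zero the
#' standard deviation is reported as `Inf` (legitimately reached by uniform
#' data) rather than raising an error.
#'
#' @param angles Numeric vector of angles (radians); at least one value.
#' @return A list with components `mean` (radians in (-pi, pi]), `R` in `[0, 1]`
#'   and `sd` (radians, possibly `Inf`).
#' @examples
#' circular_moments(c(0, pi / 2))
#' @export
circular_moments <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0L) stop("at least one angle is required", call. = FALSE)
  s <- mean(sin(angles)); c <- mean(cos(angles))
  R <- min(sqrt(s^2 + c^2), 1)
  list(
    mean = wrap_angle(atan2(s, c)),
    R = R,
    # a resultant at numerical zero (symmetric/uniform configurations) is
    # flagged as infinite dispersion rather than an error
    sd = if (R <= 1e-12) Inf else sqrt(-2 * log(R))
  )
}

# Mean resultant length of a von Mises distribution: A(kappa) = I1(kappa)/I0(kappa).
# Scaled Bessel ratio is exact (the exp(kappa) factors cancel).
bessel_ratio <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Convert between von Mises concentration and circular standard deviation
#'
#' `kappa_to_sd()` maps a concentration to the circular standard deviation of
#' the corresponding von Mises distribution, `sqrt(-2 * log(A(kappa)))` with
#' `A(kappa) = I1(kappa) / I0(kappa)`. `sd_to_kappa()` is its numerical inverse
#' (monotone root-finding to 1e-10); the two are exact round-trip inverses to
#' within 1e-6. Used by the slots-plus-averaging model, where storing an item
#' in `m` slots divides the representational standard deviation by `sqrt(m)`.
#'
#' @param kappa Concentration, `kappa >= 0`.
#' @param sd Circular standard deviation, `sd > 0`.
#' @return A numeric vector.
#' @examples
#' kappa_to_sd(8)
#' sd_to_kappa(kappa_to_sd(5))   # 5
#' @export
kappa_to_sd <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  R <- bessel_ratio(kappa)
  ifelse(R <= 0, Inf, sqrt(-2 * log(R)))
}

#' @rdname kappa_to_sd
#' @export
sd_to_kappa <- function(sd) {
  if (any(!is.finite(sd)) || any(sd <= 0)) stop("sd must be finite and > 0", call. = FALSE)
  vapply(sd, function(s) {
    R_target <- exp(-s^2 / 2)
    if (R_target >= 1) return(Inf)
    f <- function(k) bessel_ratio(k) - R_target
    upper <- 1
    while (f(upper) < 0 && upper < 1e8) upper <- upper * 10
    if (f(upper) < 0) stop("failed to bracket kappa during inversion", call. = FALSE)
    uniroot(f, c(0, upper), tol = 1e-10)$root
  }, numeric(1))
}
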