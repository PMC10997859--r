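# Analytic fixtures used across the suite.  All are built in code; nothing is
# read from disk.

# Narrow triangular line at E0: grid (E0-h, E0, E0+h), fluence (0, peak, 0).
# Under the package's Simpson rule the integrated fluence is exactly
# 4*h/3 * peak, so monoenergetic closed forms hold to the (tiny) variation of
# the coefficients over +/- h.
mono_spectrum <- function(E0, peak = 1e6, h = 0.02) {
  energy_spectrum(c(E0 - h, E0, E0 + h), c(0, peak, 0))
}

mono_fluence <- function(peak = 1e6, h = 0.02) 4 * h / 3 * peak

# Two narrow lines on a single 7-point grid arranged so that the Simpson
# pairing isolates each line: triples (1,2,3), (3,4,5), (5,6,7) with the
# middle triple identically zero.  Line masses are 4*h/3 * peak each.
two_line_spectrum <- function(E1, E2, peak1 = 1e6, peak2 = 1e6, h = 0.02) {
  stopifnot(E2 - E1 > 4 * h)
  energy_spectrum(
    c(E1 - h, E1, E1 + h, (E1 + E2) / 2, E2 - h, E2, E2 + h),
    c(0, peak1, 0, 0, 0, peak2, 0)
  )
}

air_mutr_at <- function(E) interpolate_coefficient(air_energy_transfer(), E)
al_mu_at <- function(E) interpolate_coefficient(al_attenuation(), E)

ugy_const <- function() rqbeam:::UGY_PER_KEV_CM2G_MM2

# Closed-form attenuated kerma of a two-line beam: K(t) = A1 e^(-mu1 t) +
# A2 e^(-mu2 t) in the narrow-line limit (coefficients frozen at the line
# energies).
two_line_kerma <- function(E1, E2, peak1, peak2, h = 0.02) {
  A <- c(
    mono_fluence(peak1, h) * E1 * air_mutr_at(E1),
    mono_fluence(peak2, h) * E2 * air_mutr_at(E2)
  ) * ugy_const()
  mu <- c(al_mu_at(E1), al_mu_at(E2))
  function(t) sum(A * exp(-mu * t))
}

# First HVL of a closed-form kerma function by bisection, independent of the
# package's solver.
bisect_hvl <- function(kerma_fun, t0 = 0, lower = 0, upper = 64,
                       iter = 200) {
  target <- kerma_fun(t0) / 2
  f <- function(s) kerma_fun(t0 + s) - target
  for (i in seq_len(iter)) {
    mid <- (lower + upper) / 2
    if (f(mid) > 0) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

# Trapezoidal quadrature of a function with one Richardson extrapolation
# step: an independent oracle for the package's Simpson integration.
richardson_trapezoid <- function(f, a, b, n = 4096) {
  trap <- function(m) {
    x <- seq(a, b, length.out = m + 1)
    y <- f(x)
    sum((y[-1] + y[-(m + 1)]) / 2 * diff(x))
  }
  t1 <- trap(n)
  t2 <- trap(2 * n)
  (4 * t2 - t1) / 3
}

# Continuous integrand of an RQR-like filtered bremsstrahlung kerma at 70 kV,
# evaluable at arbitrary energies (not only grid nodes).
rqr_like_integrand <- function(t_al = 3) {
  function(E) {
    phi <- (70 - E) / E
    phi * exp(-al_mu_at(E) * t_al) * E * air_mutr_at(E) * ugy_const()
  }
}
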