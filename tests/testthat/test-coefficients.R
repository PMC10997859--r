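test_that("coefficient table constructor enforces its invariants", {
  expect_s3_class(coefficient_table(c(1, 2, 4), c(3, 2, 1)), "coefficient_table")
  expect_error(coefficient_table(c(2, 1), c(1, 1)), "increasing")
  expect_error(coefficient_table(c(1, 2), c(1, -1)), "> 0")
  expect_error(coefficient_table(c(1, 2), c(0, 1)), "> 0")
  expect_error(coefficient_table(1, 1), "at least 2")
  expect_error(coefficient_table(c(-1, 2), c(1, 1)), "> 0")
})

test_that("packaged tables load with the required span and edge segments", {
  air <- air_energy_transfer()
  al <- al_attenuation()
  for (tab in list(air, al)) {
    expect_lte(min(tab$energies), 1)
    expect_gte(max(tab$energies), 160)
    expect_true(all(diff(tab$energies) > 0))
    expect_true(all(tab$values > 0))
  }
  # one absorption edge each: Ar K in air, Al K in aluminium
  expect_identical(max(air$segment), 2L)
  expect_identical(max(al$segment), 2L)
  # Al file carries mass coefficients; loader converts to 1/mm:
  # 1185 cm2/g * 2.699 g/cm3 * 0.1 cm/mm at 1 keV
  expect_equal(al$values[1], 1185 * 2.699 * 0.1, tolerance = 1e-12)
})

test_that("log-log quadratic interpolation reproduces tabulated nodes exactly", {
  for (tab in list(air_energy_transfer(), al_attenuation())) {
    got <- interpolate_coefficient(tab, tab$energies)
    expect_equal(got, tab$values, tolerance = 1e-12)
  }
})

test_that("interpolation is exact for pure power laws", {
  e <- exp(seq(log(2), log(200), length.out = 12))
  p <- -2.7
  tab <- coefficient_table(e, 5.3 * e^p)
  q <- sqrt(e[-1] * e[-length(e)])  # geometric midpoints
  expect_equal(interpolate_coefficient(tab, q), 5.3 * q^p, tolerance = 1e-12)
})

test_that("quadratic interpolation of the air table tracks a log-linear oracle", {
  tab <- air_energy_transfer()
  e <- tab$energies
  inside <- e > 3.5 & e < 900  # stay clear of the Ar edge segment boundary
  i <- which(inside[-length(e)] & inside[-1])
  q <- sqrt(e[i] * e[i + 1])
  # oracle: dense piecewise-linear interpolation on the log-log scale
  oracle <- exp(approx(log(e), log(tab$values), xout = log(q))$y)
  expect_lt(max(abs(interpolate_coefficient(tab, q) / oracle - 1)), 0.005)
})

test_that("interpolation refuses to extrapolate", {
  tab <- air_energy_transfer()
  expect_error(interpolate_coefficient(tab, 0.5), "out of table range")
  expect_error(interpolate_coefficient(tab, 1500), "out of table range")
})

test_that("interpolation windows do not straddle the aluminium K edge", {
  al <- al_attenuation()
  below <- interpolate_coefficient(al, 1.55)
  above <- interpolate_coefficient(al, 1.57)
  # branch values stay close to the adjacent tabulated nodes, with the
  # edge jump (factor ~11) preserved between them
  expect_gt(above / below, 5)
  expect_lt(below / (402.2 * 0.2699), 1.2)
  expect_gt(below / (362.1 * 0.2699), 0.8)
})

test_that("Simpson integration is exact for constants and quadratics", {
  # constant 1 on [1, 3], deliberately non-uniform grid
  g <- c(1, 1.2, 1.7, 1.9, 2.4, 3)
  expect_equal(integrate_spectrum(rep(1, length(g)), g), 2, tolerance = 1e-14)
  # quadratic on a uniform grid: Simpson is exact
  x <- seq(1, 5, by = 0.5)
  f <- 2 * x^2 - 3 * x + 1
  expect_equal(integrate_spectrum(f, x),
               2 / 3 * (5^3 - 1) - 3 / 2 * (5^2 - 1) + 4, tolerance = 1e-13)
})

test_that("Simpson integration validates its inputs and clips below 1 keV", {
  expect_error(integrate_spectrum(c(1, 1), c(1, 2)), "at least 3")
  # samples below 1 keV are discarded before integration
  x <- c(0.25, 0.5, seq(1, 3, by = 0.5))
  v <- rep(1, length(x))
  expect_equal(integrate_spectrum(v, x), 2, tolerance = 1e-14)
})

test_that("Simpson integration is non-negative and additive over subintervals", {
  set.seed(42)
  x <- seq(1, 9, by = 0.5)  # 17 points; split at an odd index keeps pairing
  v <- runif(length(x))
  expect_gte(integrate_spectrum(v, x), 0)
  whole <- integrate_spectrum(v, x)
  left <- integrate_spectrum(v[1:9], x[1:9])
  right <- integrate_spectrum(v[9:17], x[9:17])
  expect_equal(whole, left + right, tolerance = 1e-10)
})

test_that("Simpson matches a Richardson-extrapolated trapezoid oracle", {
  f <- rqr_like_integrand(t_al = 3)
  grid <- seq(1, 70, by = 0.25)
  got <- integrate_spectrum(f(grid), grid)
  want <- richardson_trapezoid(f, 1, 70)
  expect_lt(abs(got / want - 1), 1e-4)
})
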