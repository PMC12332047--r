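test_that("parameter containers reject non-physical constants", {
  expect_error(device_params(R_t = -1, lambda = 0.1, L = 1, eta = 1, q = 1,
                             C_th = 1, kappa = 1),
               class = "tn_param_error")
  expect_error(device_params(R_t = 1, lambda = 0, L = 1, eta = 1, q = 1,
                             C_th = 1, kappa = 1),
               class = "tn_param_error")
  expect_error(device_params(R_t = 1, lambda = 0.1, L = 1, eta = 1, q = 1,
                             C_th = 1, kappa = 1, n_particles = 3),
               class = "tn_param_error")
  expect_error(circuit_params(R_ext = 0, C = 1), class = "tn_param_error")
  expect_error(circuit_params(R_ext = 1, C = 1, D_V = -1),
               class = "tn_param_error")
  expect_error(drive_protocol(temperature = list(kind = "const", T0 = -1)),
               class = "tn_param_error")
  expect_error(drive_protocol(
    temperature = list(kind = "ac", T_star = 1, a_T = 1.2, period = 1)),
    class = "tn_config_error")
})

test_that("circuit time constant is R_ext * C exactly", {
  circ <- circuit_params(R_ext = 3.5, C = 0.4)
  expect_identical(circ$tau, 3.5 * 0.4)
})

test_that("one-particle resistance follows the cosh law", {
  p <- device_params(R_t = 1, lambda = 0.1, L = 1, eta = 1, q = 1,
                     C_th = 1, kappa = 1)
  R0 <- 2 * exp(1 / (2 * 0.1))
  expect_equal(resistance_one(0, p), R0)
  # even symmetry
  xs <- c(0.05, 0.17, 0.33, 0.499)
  expect_equal(resistance_one(xs, p), resistance_one(-xs, p))
  # R(lambda)/R(0) = cosh(1) for L = 10 lambda
  expect_equal(resistance_one(0.1, p) / resistance_one(0, p), cosh(1),
               tolerance = 1e-12)
  # minimum at the gap centre
  expect_true(all(resistance_one(xs, p) > R0))
  expect_error(resistance_one(0.51, p), class = "tn_domain_error")
  expect_error(resistance_one(-0.51, p), class = "tn_domain_error")
})

test_that("two-particle resistance is the three-gap series sum", {
  p <- device_params(R_t = 1, lambda = 0.1, L = 1, eta = 1, q = 1,
                     C_th = 1, kappa = 1, n_particles = 2)
  # (L = 10 lambda, x1 = -2 lambda, x2 = 3 lambda)
  expect_equal(resistance_two(-0.2, 0.3, p), exp(3) + exp(5) + exp(2))
  # x1 = x2 = 0: middle gap contributes exp(0) = 1
  expect_equal(resistance_two(0, 0, p), 2 * exp(5) + 1)
  expect_equal(resistance_two(0, 0, p) - resistance_one(0, p), 1)
  # mirror symmetry (x1, x2) -> (-x2, -x1)
  expect_equal(resistance_two(-0.1, 0.35, p),
               resistance_two(-0.35, 0.1, p))
  expect_error(resistance_two(0.2, -0.2, p), class = "tn_order_error")
})

test_that("resistance gradient matches a central-difference oracle", {
  p <- device_params(R_t = 0.3, lambda = 0.07, L = 1, eta = 1, q = 1,
                     C_th = 1, kappa = 1)
  expect_equal(resistance_gradient(0, p), 0)
  xs <- c(0.05, 0.2, 0.4)
  expect_equal(resistance_gradient(-xs, p), -resistance_gradient(xs, p))
  for (x in xs) {
    num <- oracle_cdiff(function(z) resistance_one(z, p), x)
    expect_equal(resistance_gradient(x, p), num, tolerance = 1e-7)
  }
})

test_that("potential force is minus the potential gradient", {
  # harmonic: U = k x^2 / 2 -> force -k x
  spec <- potential_spec("polynomial", coefficients = c(0, 0, 4 / 2),
                         well_position = 0)
  expect_equal(potential_force(0.3, spec), -4 * 0.3)
  expect_equal(potential_force(spec$well_position, spec), 0)
  # default polynomial against the numerical derivative of U
  dflt <- default_potential(1)
  for (x in c(-0.35, -0.2, 0.1, 0.4)) {
    num <- -oracle_cdiff(function(z) potential_energy(z, dflt), x)
    expect_equal(potential_force(x, dflt), num, tolerance = 1e-5)
  }
  # force vanishes at the well minimum
  expect_equal(potential_force(dflt$well_position, dflt), 0,
               tolerance = 1e-10)
})

test_that("tabulated potentials interpolate and check their grid", {
  dflt <- default_potential(1)
  xg <- seq(-0.5, 0.5, length.out = 400)
  tab <- potential_spec("tabulated", x = xg,
                        U = potential_energy(xg, dflt),
                        well_position = -0.4)
  for (x in c(-0.3, -0.1, 0.2)) {
    expect_equal(potential_force(x, tab), potential_force(x, dflt),
                 tolerance = 1e-3)
  }
  # grid not covering the gap is a configuration error at device build
  short <- potential_spec("tabulated", x = seq(-0.3, 0.3, length.out = 50),
                          U = potential_energy(
                            seq(-0.3, 0.3, length.out = 50), dflt),
                          well_position = -0.29)
  expect_error(device_params(R_t = 1, lambda = 0.1, L = 1, eta = 1, q = 1,
                             C_th = 1, kappa = 1, potential = short),
               class = "tn_config_error")
})

test_that("a potential without a minimum at the well is rejected", {
  ramp <- potential_spec("polynomial", coefficients = c(0, 1, 1e-9),
                         well_position = 0)
  expect_error(device_params(R_t = 1, lambda = 0.1, L = 1, eta = 1, q = 1,
                             C_th = 1, kappa = 1, potential = ramp),
               class = "tn_config_error")
})

test_that("normalised conductance is bounded and monotone in |x|", {
  p <- device_params(R_t = 1, lambda = 0.1, L = 1, eta = 1, q = 1,
                     C_th = 1, kappa = 1)
  expect_equal(conductance(0, p, normalise = TRUE), 1)
  expect_equal(conductance(0.5, p, normalise = TRUE), 1 / cosh(5))
  xs <- seq(0, 0.5, length.out = 60)
  g <- conductance(xs, p, normalise = TRUE)
  expect_true(all(g > 0 & g <= 1))
  expect_true(all(diff(g) < 0))
  # mirror side decreases identically
  expect_equal(conductance(-xs, p, normalise = TRUE), g)
})

test_that("drive protocols evaluate DC, ramp and AC forms", {
  pr <- drive_protocol(voltage = list(kind = "ramp", V_start = 0,
                                      V_end = 2, duration = 4),
                       temperature = list(kind = "const", T0 = 0.3))
  expect_equal(protocol_voltage(pr, c(0, 1, 4, 10)), c(0, 0.5, 2, 2))
  expect_equal(protocol_temperature(pr, c(0, 7)), c(0.3, 0.3))
  ac <- drive_protocol(
    voltage = list(kind = "ac", V_DC = 1, V_AC = 0.5, period = 2,
                   fun = "cos"),
    temperature = list(kind = "ac", T_star = 0.2, a_T = 0.5, period = 2,
                       phase = pi))
  expect_equal(protocol_voltage(ac, 0), 1.5)
  expect_equal(protocol_voltage(ac, 1), 0.5)
  expect_equal(protocol_temperature(ac, 0.5),
               0.2 * (1 + 0.5 * sin(pi / 2 * 1 + pi)))
})

test_that("configurations round-trip through YAML", {
  ref <- reference_params(1L)
  pr <- drive_protocol(voltage = list(kind = "dc", V = 1.1),
                       temperature = list(kind = "const", T0 = ref$T0))
  path <- tempfile(fileext = ".yaml")
  write_config(ref$device, ref$circuit, pr, path)
  back <- read_config(path)
  expect_equal(back$device$R_t, ref$device$R_t)
  expect_equal(back$device$potential$coefficients,
               ref$device$potential$coefficients)
  expect_equal(back$circuit$tau, ref$circuit$tau)
  expect_equal(protocol_voltage(back$drive, 3), 1.1)
  expect_error(read_config(tempfile()), class = "tn_config_error")
  unlink(path)
})
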