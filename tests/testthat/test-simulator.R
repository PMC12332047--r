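test_that("frozen-particle steady state matches the voltage divider", {
  dev <- toy_device()
  circ <- circuit_params(R_ext = 1, C = 1)
  pr <- drive_protocol(voltage = list(kind = "dc", V = 2),
                       temperature = list(kind = "const", T0 = 0.5))
  tr <- simulate_neuron(dev, circ, pr,
                        sim_config(t_max = 60, dt = 1e-3, seed = 1,
                                   freeze_particles = TRUE,
                                   initial_state = list(x = 0.2, T = 0.5,
                                                        V = 0)))
  R <- resistance_one(0.2, dev)
  V_inf <- 2 * R / (R + 1)
  expect_equal(tail(tr$V, 1), V_inf, tolerance = 1e-6)
  # temperature settles at T0 + V^2 / (C_th R kappa)
  expect_equal(tail(tr$T, 1), 0.5 + V_inf^2 / (dev$C_th * R * dev$kappa),
               tolerance = 1e-5)
})

test_that("harmonic-well stationary variance matches k_B T0 / k", {
  k <- 50
  dev <- toy_device(q = 0, eta = 1, k_B = 1, k_spring = k)
  circ <- circuit_params(R_ext = 1, C = 1)
  pr <- drive_protocol(voltage = list(kind = "dc", V = 0),
                       temperature = list(kind = "const", T0 = 0.2))
  tr <- simulate_neuron(dev, circ, pr,
                        sim_config(t_max = 400, dt = 2e-4, seed = 42,
                                   record_stride = 4L,
                                   clamp_temperature = TRUE))
  burn <- tr$t > 20
  v <- var(tr$x[burn])
  expect_equal(v, 0.2 / k, tolerance = 0.02)
})

test_that("reflection folds arbitrary excursions into the gap", {
  dev <- toy_device()
  h <- dev$L / 2
  set.seed(7)
  xs <- runif(300, -6, 6)
  folded <- enforce_boundaries_and_order(xs, dev)
  expect_true(all(folded >= -h & folded <= h))
  expect_equal(sort(vapply(xs, oracle_reflect, numeric(1), h = h)),
               folded)
  # simple one-wall case and ordering
  expect_equal(enforce_boundaries_and_order(h + 0.1, dev), h - 0.1)
  expect_equal(enforce_boundaries_and_order(c(0.3, -0.1), dev),
               c(-0.1, 0.3))
})

test_that("identical seeds give bit-identical traces", {
  ref <- reference_params(1L)
  pr <- drive_protocol(voltage = list(kind = "dc", V = 0.95),
                       temperature = list(kind = "const", T0 = ref$T0))
  cfg <- sim_config(t_max = 5, dt = 5e-4, seed = 11, record_stride = 4L)
  a <- simulate_neuron(ref$device, ref$circuit, pr, cfg)
  b <- simulate_neuron(ref$device, ref$circuit, pr, cfg)
  expect_identical(a$x, b$x)
  expect_identical(a$V, b$V)
  cfg2 <- sim_config(t_max = 5, dt = 5e-4, seed = 12, record_stride = 4L)
  c2 <- simulate_neuron(ref$device, ref$circuit, pr, cfg2)
  expect_false(identical(a$x, c2$x))
})

test_that("trace invariants hold on a spiking run", {
  ref <- reference_params(2L)
  pr <- drive_protocol(voltage = list(kind = "dc", V = 3.3),
                       temperature = list(kind = "const", T0 = ref$T0))
  tr <- simulate_neuron(ref$device, ref$circuit, pr,
                        sim_config(t_max = 40, dt = 5e-4, seed = 3,
                                   record_stride = 4L))
  expect_true(all(diff(tr$t) > 0))
  expect_true(all(tr$T > 0))
  expect_true(all(tr$x1 >= -0.5 & tr$x1 <= 0.5))
  expect_true(all(tr$x2 >= -0.5 & tr$x2 <= 0.5))
  expect_true(all(tr$x1 <= tr$x2))
  expect_true(all(tr$G_norm > 0 & tr$G_norm <= 1))
})

test_that("near-zero noise below threshold stays quiescent", {
  ref <- reference_params(1L, k_B = 1e-12)
  pr <- drive_protocol(voltage = list(kind = "dc", V = 0.5),
                       temperature = list(kind = "const", T0 = 1e-6))
  tr <- simulate_neuron(ref$device, ref$circuit, pr,
                        sim_config(t_max = 60, dt = 5e-4, seed = 1,
                                   record_stride = 4L))
  st <- detect_spikes(tr, signal = "G_norm", mode = "log")
  expect_length(st$timestamps, 0)
  # V settles to the DC divider value at the resting position
  xf <- tail(tr$x, 1)
  R <- resistance_one(xf, ref$device)
  expect_equal(tail(tr$V, 1), 0.5 * R / (R + 1), tolerance = 1e-3)
})

test_that("the compiled step agrees with the reference R step", {
  dev <- toy_device(q = 3, eta = 2, k_spring = 20)
  circ <- circuit_params(R_ext = 1, C = 1)
  pr <- drive_protocol(voltage = list(kind = "dc", V = 1),
                       temperature = list(kind = "const", T0 = 0.3))
  # deterministic comparison: zero noise via clamped tiny temperature
  dev0 <- dev; dev0$k_B <- 1e-30
  state <- list(x = 0.1, T = 0.3, V = 0.4)
  dt <- 1e-3
  n <- 200L
  s <- state
  for (i in seq_len(n)) {
    s <- sde_step(s, (i - 1) * dt, dev0, circ, pr, dt,
                  noise = list(xi = 0, zeta_V = 0))
  }
  tr <- simulate_neuron(dev0, circ, pr,
                        sim_config(t_max = n * dt, dt = dt, seed = 1,
                                   clamp_temperature = FALSE,
                                   initial_state = state))
  expect_equal(tail(tr$x, 1), s$x, tolerance = 1e-10)
  expect_equal(tail(tr$V, 1), s$V, tolerance = 1e-10)
  expect_equal(tail(tr$T, 1), s$T, tolerance = 1e-10)
})

test_that("ramp protocols reduce to DC when flat and sweep otherwise", {
  ref <- reference_params(1L)
  cfg <- sim_config(t_max = 20, dt = 5e-4, seed = 5, record_stride = 4L)
  flat <- ramp_response(ref$device, ref$circuit, 0.95, 0.95, 20, cfg,
                        temperature = list(kind = "const", T0 = ref$T0))
  expect_true(all(flat$V_ext == 0.95))
  up <- ramp_response(ref$device, ref$circuit, 0.5, 1.5, 20, cfg,
                      temperature = list(kind = "const", T0 = ref$T0))
  expect_equal(range(up$V_ext), c(0.5, 1.5), tolerance = 1e-6)
  expect_true(all(diff(up$V_ext) >= 0))
})

test_that("halving the step changes the firing rate by < 5%", {
  ref <- reference_params(1L)
  pr <- drive_protocol(voltage = list(kind = "dc", V = 0.95),
                       temperature = list(kind = "const", T0 = ref$T0))
  rate_at <- function(dt) {
    n <- vapply(1:3, function(s) {
      tr <- simulate_neuron(ref$device, ref$circuit, pr,
                            sim_config(t_max = 150, dt = dt, seed = s,
                                       record_stride = round(4e-3 / dt)))
      length(detect_spikes(tr, signal = "G_norm",
                           mode = "log")$timestamps)
    }, numeric(1))
    sum(n) / (3 * 150)
  }
  r1 <- rate_at(5e-4)
  r2 <- rate_at(2.5e-4)
  expect_lt(abs(r2 - r1) / r1, 0.05)
})

test_that("traces round-trip through CSV with a JSON sidecar", {
  ref <- reference_params(1L)
  pr <- drive_protocol(voltage = list(kind = "dc", V = 0.95),
                       temperature = list(kind = "const", T0 = ref$T0))
  tr <- simulate_neuron(ref$device, ref$circuit, pr,
                        sim_config(t_max = 2, dt = 1e-3, seed = 2,
                                   record_stride = 10L))
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$x, tr$x, tolerance = 1e-12)
  meta <- attr(back, "meta")
  expect_equal(meta$seed, 2)
  expect_equal(meta$dt, 1e-3)
  unlink(c(path, paste0(path, ".json")))
})
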