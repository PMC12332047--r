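#' Simulation configuration
#'
#' @param t_max total simulated duration (time units of `tau`).
#' @param dt integration step; default `tau/2000` of the circuit it is used
#'   with (resolved inside [simulate_neuron()] when left `NULL`), small enough to
#'   resolve the fastest cluster relaxation of the reference device.
#' @param seed RNG seed; identical (parameters, protocol, config, seed)
#'   produce bit-identical traces.
#' @param record_stride keep every `record_stride`-th sample in the output.
#' @param initial_state optional named list with entries `x` (positions),
#'   `T` (device temperature), `V` (voltage across the memristor); missing
#'   entries fall back to the resting state under the protocol at `t = 0`.
#' @param freeze_particles diagnostic switch: hold the cluster positions
#'   fixed (the `eta -> Inf` limit), isolating the thermal/electrical
#'   subsystems.
#' @param clamp_temperature diagnostic switch: slave the device temperature
#'   to the bath, `T(t) = T0(t)`.
#' @return an object of class `tn_sim_config`.
#' @export
sim_config <- function(t_max, dt = NULL, seed = 1L, record_stride = 1L,
                       initial_state = NULL, freeze_particles = FALSE,
                       clamp_temperature = FALSE) {
  check_positive(t_max, "t_max")
  if (!is.null(dt)) check_positive(dt, "dt")
  if (record_stride < 1L) {
    stop_tn("'record_stride' must be >= 1", class = "tn_param_error")
  }
  structure(list(t_max = t_max, dt = dt, seed = as.integer(seed),
                 record_stride = as.integer(record_stride),
                 initial_state = initial_state,
                 freeze_particles = isTRUE(freeze_particles),
                 clamp_temperature = isTRUE(clamp_temperature)),
            class = "tn_sim_config")
}

voltage_code <- function(v) {
  switch(v$kind,
         dc = list(kind = 0L, par = c(v$V, 0, 0, 0)),
         ramp = list(kind = 1L, par = c(v$V_start, v$V_end, v$duration, 0)),
         ac = list(kind = if (v$fun == "cos") 2L else 3L,
                   par = c(v$V_DC, v$V_AC, v$omega, v$phase)))
}

temperature_code <- function(tm) {
  switch(tm$kind,
         const = list(kind = 0L, par = c(tm$T0, 0, 0, 0)),
         ac = list(kind = 1L, par = c(tm$T_star, tm$a_T, tm$omega,
                                      tm$phase)))
}

potential_code <- function(spec, L) {
  if (spec$kind == "polynomial") {
    list(kind = 0L, coef = spec$coefficients, well = spec$well_position,
         grid_x0_dx = c(0, 1), grid_F = 0)
  } else {
    xg <- seq(-L / 2, L / 2, length.out = 2001L)
    list(kind = 1L, coef = 0, well = spec$well_position,
         grid_x0_dx = c(xg[1], xg[2] - xg[1]),
         grid_F = potential_force(xg, spec))
  }
}

resting_state <- function(device, circuit, protocol) {
  x <- if (device$n_particles == 2L) {
    c(device$potential$well_position,
      min(device$potential$well_position + 0.1 * device$L,
          device$L / 2))
  } else {
    device$potential$well_position
  }
  R <- if (device$n_particles == 2L) {
    resistance_two(x[1], x[2], device)
  } else {
    resistance_one(x, device)
  }
  V0 <- protocol_voltage(protocol, 0) * R / (R + circuit$R_ext)
  T0 <- protocol_temperature(protocol, 0)
  list(x = x, T = T0 + V0^2 / (device$C_th * R * max(device$kappa, 1e-12)),
       V = V0)
}

#' Integrate the stochastic neuron model
#'
#' Advances the coupled Langevin system (cluster positions, device
#' temperature, memristor voltage) with an explicit Euler-Maruyama scheme:
#' reflecting walls confine the cluster(s) to the gap, two-particle runs
#' renumber clusters so `x1 <= x2` at every step, Brownian forcing has
#' variance `2 k_B T(t)` (Ito convention, temperature taken at the current
#' step), Joule heating relaxes against the bath through Newton cooling, and
#' the voltage obeys the Kirchhoff current law of the RC readout with
#' optional external voltage noise of intensity `D_V`.
#'
#' @param device a [device_params()].
#' @param circuit a [circuit_params()].
#' @param protocol a [drive_protocol()].
#' @param config a [sim_config()].
#' @return a `tn_trace`: a data frame with columns `t`, `x` (or `x1`, `x2`),
#'   `T`, `V`, `I`, `G_norm`, `V_ext`, `T0`, carrying the run's parameters,
#'   seed and step in its attributes.
#' @export
simulate_neuron <- function(device, circuit, protocol, config) {
  stopifnot(inherits(device, "tn_device"), inherits(circuit, "tn_circuit"),
            inherits(protocol, "tn_protocol"),
            inherits(config, "tn_sim_config"))
  dt <- config$dt %||% (circuit$tau / 2000)
  if (config$t_max <= dt) {
    stop_tn("'t_max' must exceed dt", class = "tn_param_error")
  }
  n_steps <- as.integer(round(config$t_max / dt))
  rest <- resting_state(device, circuit, protocol)
  init <- config$initial_state %||% list()
  x0 <- init$x %||% rest$x
  T0 <- init$T %||% rest$T
  V0 <- init$V %||% rest$V
  if (length(x0) != device$n_particles) {
    stop_tn("initial state has %d position(s) for %d particle(s)",
            length(x0), device$n_particles, class = "tn_param_error")
  }
  vcode <- voltage_code(protocol$voltage)
  tcode <- temperature_code(protocol$temperature)
  pcode <- potential_code(device$potential, device$L)

  set.seed(config$seed)
  raw <- .sde_core(as.numeric(x0), T0, V0, dt, n_steps,
                   config$record_stride,
                   device$R_t, device$lambda, device$L, device$eta,
                   device$q, device$C_th, device$kappa, device$k_B,
                   device$field_sign,
                   pcode$kind, pcode$coef, pcode$well, pcode$grid_x0_dx,
                   pcode$grid_F,
                   circuit$R_ext, circuit$tau, circuit$D_V,
                   vcode$kind, vcode$par, tcode$kind, tcode$par,
                   config$freeze_particles, config$clamp_temperature)

  df <- data.frame(t = raw$t)
  if (device$n_particles == 2L) {
    df$x1 <- raw$x[, 1]; df$x2 <- raw$x[, 2]
  } else {
    df$x <- raw$x[, 1]
  }
  df$T <- raw$T; df$V <- raw$V; df$I <- raw$I; df$G_norm <- raw$G_norm
  df$V_ext <- raw$V_ext; df$T0 <- raw$T0
  structure(df,
            class = c("tn_trace", "data.frame"),
            device = device, circuit = circuit, protocol = protocol,
            config = config, dt = dt)
}

#' Single Euler-Maruyama step (reference implementation)
#'
#' Advances one integration step in plain R.  The compiled core used by
#' [simulate_neuron()] follows the same update; this reference path is exposed for
#' inspection and for step-level testing.
#'
#' @param state named list with `x` (positions), `T`, `V`.
#' @param t current time.
#' @param device,circuit,protocol model objects.
#' @param dt step size.
#' @param noise optional list with pre-drawn standard-normal deviates
#'   `xi` (length `n_particles`) and `zeta_V` (length 1); drawn from the
#'   session RNG when omitted.
#' @return the updated state list.
#' @export
sde_step <- function(state, t, device, circuit, protocol, dt,
                     noise = NULL) {
  np <- device$n_particles
  xi <- noise$xi %||% rnorm(np)
  zv <- noise$zeta_V %||% rnorm(1)
  R <- if (np == 2L) resistance_two(state$x[1], state$x[2], device)
       else resistance_one(state$x, device)
  Vext <- protocol_voltage(protocol, t)
  T0 <- protocol_temperature(protocol, t)
  sig <- sqrt(2 * device$k_B * max(state$T, 0) / device$eta)
  drift <- (potential_force(state$x, device$potential) +
            device$field_sign * device$q * state$V / device$L) / device$eta
  x_new <- state$x + drift * dt + sig * sqrt(dt) * xi
  x_new <- enforce_boundaries_and_order(x_new, device)
  T_new <- state$T + (state$V^2 / (device$C_th * R) -
                      device$kappa * (state$T - T0)) * dt
  V_new <- state$V +
    (Vext - (1 + circuit$R_ext / R) * state$V) / circuit$tau * dt +
    sqrt(circuit$D_V) / circuit$tau * sqrt(dt) * zv
  if (!all(is.finite(c(x_new, T_new, V_new)))) {
    stop_tn("integration failure at t = %g (x = %s, T = %g, V = %g)",
            t, paste(format(state$x), collapse = ","), state$T, state$V,
            class = "tn_integration_error")
  }
  list(x = x_new, T = T_new, V = V_new)
}

#' Reflect positions into the gap and renumber particles
#'
#' Applies reflecting walls at `x = -L/2` and `x = +L/2` (folding repeatedly
#' so arbitrarily large excursions land inside the gap) and sorts particle
#' labels ascending so `x1 <= x2` always holds.
#'
#' @param x numeric vector of candidate positions.
#' @param device a [device_params()].
#' @return reflected, sorted positions.
#' @export
enforce_boundaries_and_order <- function(x, device) {
  h <- device$L / 2
  period <- 4 * h
  x <- (x + h) %% period
  x <- ifelse(x <= 2 * h, x - h, 3 * h - x)
  sort(x)
}

#' Response to a slow voltage ramp
#'
#' Runs [simulate_neuron()] under a linear `V_ext` ramp from `V_start` to `V_end`;
#' used to inspect regime transitions and hysteresis (run an up-ramp and a
#' down-ramp and compare paths).
#'
#' @inheritParams simulate_neuron
#' @param V_start,V_end ramp endpoints.
#' @param duration ramp duration; the protocol holds `V_end` afterwards.
#' @param temperature bath-temperature part of the protocol (defaults to
#'   constant `T0 = 1`).
#' @return a `tn_trace`.
#' @export
ramp_response <- function(device, circuit, V_start, V_end, duration,
                          config,
                          temperature = list(kind = "const", T0 = 1)) {
  protocol <- drive_protocol(
    voltage = list(kind = "ramp", V_start = V_start, V_end = V_end,
                   duration = duration),
    temperature = temperature)
  simulate_neuron(device, circuit, protocol, config)
}

#' Write or read a trace
#'
#' Traces are stored as a plain CSV of the sample columns plus a JSON
#' sidecar (`<path>.json`) carrying the run parameters, seed and step so a
#' stored trace can be re-run bit-identically.
#'
#' @param trace a `tn_trace`.
#' @param path CSV path.
#' @return `read_trace()` returns the trace data frame (sidecar metadata, if
#'   found, in attribute `meta`); `write_trace()` returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  cfg <- attr(trace, "config")
  device <- attr(trace, "device")
  circuit <- attr(trace, "circuit")
  meta <- list(
    seed = cfg$seed, dt = attr(trace, "dt"),
    t_max = cfg$t_max, record_stride = cfg$record_stride,
    n_particles = device$n_particles,
    device = device[c("R_t", "lambda", "L", "eta", "q", "q_T", "C_th",
                      "kappa", "k_B", "field_sign")],
    circuit = circuit[c("R_ext", "C", "tau", "D_V")],
    package_version = as.character(utils::packageVersion("transneuron")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  structure(df, class = c("tn_trace", "data.frame"), meta = meta)
}
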