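#' @useDynLib transneuron, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats splinefun rnorm rexp rgamma runif sd fft var median
#'   quantile uniroot approx optimize
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tn <- function(fmt, ..., class = "tn_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

check_positive <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0) {
    stop_tn("'%s' must be a single positive finite number (got %s)",
            name, paste(format(value), collapse = ", "),
            class = "tn_param_error")
  }
  invisible(value)
}

check_nonnegative <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value < 0) {
    stop_tn("'%s' must be a single non-negative finite number",
            name, class = "tn_param_error")
  }
  invisible(value)
}

#' Physical parameters of the diffusive memristor
#'
#' Bundles the device constants of the memristive gap: the tunnelling
#' resistance amplitude and length, the gap size, the viscosity felt by the
#' diffusing Ag cluster(s), the induced cluster charge, the thermal charge
#' coupling the thermophoretic force to the temperature gradient, the thermal
#' capacitance and Newton-cooling rate, and the Boltzmann constant that fixes
#' the thermal-noise scale.  All quantities are expressed in the package's
#' dimensionless scheme (see the methods vignette): lengths in units of the
#' gap `L`, time in units of the circuit constant `tau = R_ext * C`,
#' resistance in units of `R_ext`, and `k_B = 1` so temperature is measured
#' in energy units.
#'
#' @param R_t tunnelling resistance amplitude (resistance units), > 0.
#' @param lambda effective tunnelling length (length units), > 0.
#' @param L gap size (length units), > 0; the cluster coordinate spans
#'   `[-L/2, L/2]` with the filament tip at `-L/2`.
#' @param eta viscosity coefficient (force * time / length), > 0.
#' @param q induced effective cluster charge; the electric force on a cluster
#'   is `field_sign * q * V / L`.
#' @param q_T thermal charge: couples the thermophoretic force to the
#'   temperature gradient in the deterministic companion model.
#' @param C_th thermal capacitance (energy / temperature), > 0.
#' @param kappa Newton-cooling rate constant (1 / time), >= 0.
#' @param k_B Boltzmann-like constant fixing the noise scale, > 0.
#' @param n_particles number of mobile Ag clusters in the gap, 1 or 2.
#' @param potential a [potential_spec()] describing the electro-chemical
#'   potential in the gap.
#' @param field_sign +1 or -1; orientation of the electric force relative to
#'   the coordinate axis.  The default +1, together with the default well on
#'   the filament-tip side, makes a positive applied voltage pull the cluster
#'   away from the well.
#' @return an object of class `tn_device`.
#' @export
device_params <- function(R_t, lambda, L = 1, eta, q, q_T = 0, C_th,
                          kappa, k_B = 1, n_particles = 1,
                          potential = NULL, field_sign = 1) {
  check_positive(R_t, "R_t"); check_positive(lambda, "lambda")
  check_positive(L, "L"); check_positive(eta, "eta")
  check_positive(C_th, "C_th"); check_nonnegative(kappa, "kappa")
  check_positive(k_B, "k_B")
  if (!n_particles %in% c(1L, 2L)) {
    stop_tn("'n_particles' must be 1 or 2", class = "tn_param_error")
  }
  if (!field_sign %in% c(-1, 1)) {
    stop_tn("'field_sign' must be +1 or -1", class = "tn_param_error")
  }
  if (is.null(potential)) {
    potential <- default_potential(L)
  }
  stopifnot(inherits(potential, "tn_potential"))
  validate_potential(potential, L)
  structure(list(R_t = R_t, lambda = lambda, L = L, eta = eta, q = q,
                 q_T = q_T, C_th = C_th, kappa = kappa, k_B = k_B,
                 n_particles = as.integer(n_particles),
                 potential = potential, field_sign = field_sign),
            class = "tn_device")
}

#' @export
print.tn_device <- function(x, ...) {
  cat("<tn_device>", x$n_particles, "particle(s); gap L =", x$L,
      "; lambda =", x$lambda, "; R_t =", x$R_t, "\n")
  cat("  eta =", x$eta, " q =", x$q, " q_T =", x$q_T,
      " C_th =", x$C_th, " kappa =", x$kappa, "\n")
  invisible(x)
}

#' Electro-chemical potential in the gap
#'
#' The potential `U(x)` confines the mobile Ag cluster(s): it has a single
#' well near the filament tip and rises toward both gap edges.  Two
#' parameterisations are supported: a polynomial in `(x - well_position)`
#' (coefficients in increasing powers, constant term first) or a tabulated
#' `(x, U)` sample interpolated with a cubic spline.
#'
#' @param kind `"polynomial"` or `"tabulated"`.
#' @param coefficients polynomial coefficients `c0, c1, c2, ...` of
#'   `U(x) = sum_k c_k (x - well_position)^k` (polynomial kind).
#' @param x,U grid samples covering the gap (tabulated kind).
#' @param well_position location of the potential minimum (length units).
#' @return an object of class `tn_potential`.
#' @export
potential_spec <- function(kind = c("polynomial", "tabulated"),
                           coefficients = NULL, x = NULL, U = NULL,
                           well_position = NULL) {
  kind <- match.arg(kind)
  if (kind == "polynomial") {
    if (is.null(coefficients) || length(coefficients) < 3L) {
      stop_tn("polynomial potential needs coefficients up to order >= 2",
              class = "tn_config_error")
    }
    if (is.null(well_position)) {
      stop_tn("'well_position' is required", class = "tn_config_error")
    }
    obj <- list(kind = kind, coefficients = as.numeric(coefficients),
                well_position = well_position)
  } else {
    if (is.null(x) || is.null(U) || length(x) != length(U) ||
        length(x) < 8L) {
      stop_tn("tabulated potential needs matching x/U grids (>= 8 points)",
              class = "tn_config_error")
    }
    if (any(!is.finite(U))) {
      stop_tn("tabulated potential must be finite on its grid",
              class = "tn_config_error")
    }
    ord <- order(x)
    x <- x[ord]; U <- U[ord]
    if (is.null(well_position)) well_position <- x[which.min(U)]
    obj <- list(kind = kind, x = x, U = U, well_position = well_position,
                spline = splinefun(x, U, method = "natural"))
  }
  structure(obj, class = "tn_potential")
}

validate_potential <- function(spec, L) {
  if (spec$kind == "tabulated") {
    if (min(spec$x) > -L / 2 || max(spec$x) < L / 2) {
      stop_tn(paste0("tabulated potential grid [", min(spec$x), ", ",
                     max(spec$x), "] does not cover the gap [",
                     -L / 2, ", ", L / 2, "]"), class = "tn_config_error")
    }
  }
  if (abs(spec$well_position) > L / 2) {
    stop_tn("well_position lies outside the gap", class = "tn_config_error")
  }
  # the well must be a local minimum
  h <- 1e-4 * L
  u0 <- potential_energy(spec$well_position, spec)
  if (potential_energy(spec$well_position + h, spec) <= u0 ||
      potential_energy(spec$well_position - h, spec) <= u0) {
    stop_tn("potential has no local minimum at well_position",
            class = "tn_config_error")
  }
  invisible(spec)
}

#' Default confinement potential
#'
#' A single-well degree-six polynomial with its minimum at `-0.4 * L` (the
#' filament-tip side) and a flank carrying two soft shoulders — intervals of
#' negative curvature — on the way toward the counter-electrode.  The
#' curvature is constructed as `U''(s) = A (s - k1)(s - k2)(s - k3)(s - k4)`
#' in the offset `s = x - well_position`, with the four knees `k` placed at
#' `(0.05, 0.12, 0.16, 0.27) * L`; the force `U'` therefore rises off the
#' well, sags over each shoulder, and stays positive throughout (a single
#' well).  The shoulders are what make the device excitable: the electric
#' pull can park the cluster on a flank segment where the confinement
#' stiffness is negative, so the coupled cluster-circuit dynamics
#' destabilises into relaxation oscillations over two distinct
#' applied-voltage windows.  `A` is scaled so the force maximum at the first
#' knee equals `8 * depth / L`.
#'
#' @param L gap size; coefficients scale so the shape is invariant in `x/L`.
#' @param depth energy scale of the well (energy units); default 1.
#' @return a polynomial [potential_spec()].
#' @export
default_potential <- function(L = 1, depth = 1) {
  knees <- c(0.05, 0.12, 0.16, 0.27) * L
  p <- c(1)
  for (k in knees) p <- c(0, p) - k * c(p, 0)
  u1 <- function(s, A = 1) A * sum((p / (1:5)) * s^(1:5))
  A <- 8 * depth / L / u1(0.05 * L)
  potential_spec("polynomial",
                 coefficients = c(0, 0, A * p / ((1:5) * (2:6))),
                 well_position = -0.4 * L)
}

#' Potential energy and force
#'
#' `potential_energy()` evaluates `U(x)`; `potential_force()` evaluates the
#' mechanical force `-dU/dx` acting on a cluster at `x`.
#'
#' @param x position(s) within the gap.
#' @param spec a [potential_spec()].
#' @return numeric vector of the same length as `x`.
#' @export
potential_force <- function(x, spec) {
  stopifnot(inherits(spec, "tn_potential"))
  if (spec$kind == "polynomial") {
    s <- x - spec$well_position
    k <- seq_along(spec$coefficients) - 1L
    dU <- rep(0, length(x))
    for (j in seq_along(k)[-1]) {
      dU <- dU + k[j] * spec$coefficients[j] * s^(k[j] - 1L)
    }
    -dU
  } else {
    if (any(x < min(spec$x) | x > max(spec$x))) {
      stop_tn("position outside the tabulated potential grid",
              class = "tn_config_error")
    }
    -spec$spline(x, deriv = 1)
  }
}

#' @rdname potential_force
#' @export
potential_energy <- function(x, spec) {
  stopifnot(inherits(spec, "tn_potential"))
  if (spec$kind == "polynomial") {
    s <- x - spec$well_position
    k <- seq_along(spec$coefficients) - 1L
    U <- rep(0, length(x))
    for (j in seq_along(k)) U <- U + spec$coefficients[j] * s^k[j]
    U
  } else {
    spec$spline(x)
  }
}

#' External circuit parameters
#'
#' The memristor is read out through a series load resistor `R_ext` and a
#' parallel capacitor `C`; the circuit time constant is `tau = R_ext * C`.
#' `D_V` sets the intensity of external voltage fluctuations (voltage^2 *
#' time), mimicking synaptic noise arriving from a surrounding network.
#'
#' @param R_ext load resistance, > 0 (resistance unit of the scheme).
#' @param C capacitance, > 0.
#' @param D_V voltage-noise intensity, >= 0.
#' @return an object of class `tn_circuit` with fields `R_ext`, `C`, `tau`,
#'   `D_V`.
#' @export
circuit_params <- function(R_ext = 1, C = 1, D_V = 0) {
  check_positive(R_ext, "R_ext"); check_positive(C, "C")
  check_nonnegative(D_V, "D_V")
  structure(list(R_ext = R_ext, C = C, tau = R_ext * C, D_V = D_V),
            class = "tn_circuit")
}

#' Stimulation protocol
#'
#' Time courses of the applied voltage `V_ext(t)` and the bath temperature
#' `T0(t)`.  Voltage can be a DC level, a linear ramp, or a sinusoid
#' `V_DC + V_AC * cos(omega t + phase)` (or `sin`); temperature is either
#' constant or a sinusoid `T_star * (1 + a_T * sin(omega t + phase))`.
#'
#' @param voltage list describing the voltage drive; one of
#'   `list(kind = "dc", V = ...)`,
#'   `list(kind = "ramp", V_start = , V_end = , duration = )`,
#'   `list(kind = "ac", V_DC = , V_AC = , period = or omega = , phase = 0,
#'          fun = "cos"|"sin")`.
#' @param temperature list describing the bath temperature; one of
#'   `list(kind = "const", T0 = ...)`,
#'   `list(kind = "ac", T_star = , a_T = , period = or omega = , phase = 0)`
#'   with `|a_T| < 1` so the temperature stays positive.
#' @return an object of class `tn_protocol`.
#' @export
drive_protocol <- function(voltage = list(kind = "dc", V = 0),
                           temperature = list(kind = "const", T0 = 1)) {
  voltage$kind <- match.arg(voltage$kind, c("dc", "ramp", "ac"))
  temperature$kind <- match.arg(temperature$kind, c("const", "ac"))
  if (voltage$kind == "ac") {
    if (is.null(voltage$omega)) {
      check_positive(voltage$period, "voltage$period")
      voltage$omega <- 2 * pi / voltage$period
    }
    voltage$period <- 2 * pi / voltage$omega
    voltage$phase <- voltage$phase %||% 0
    voltage$fun <- match.arg(voltage$fun %||% "cos", c("cos", "sin"))
  }
  if (voltage$kind == "ramp") check_positive(voltage$duration, "duration")
  if (temperature$kind == "const") {
    check_positive(temperature$T0, "T0")
  } else {
    check_positive(temperature$T_star, "T_star")
    if (abs(temperature$a_T) >= 1) {
      stop_tn("|a_T| must be < 1 to keep T0(t) > 0",
              class = "tn_config_error")
    }
    if (is.null(temperature$omega)) {
      check_positive(temperature$period, "temperature$period")
      temperature$omega <- 2 * pi / temperature$period
    }
    temperature$period <- 2 * pi / temperature$omega
    temperature$phase <- temperature$phase %||% 0
  }
  structure(list(voltage = voltage, temperature = temperature),
            class = "tn_protocol")
}

#' Evaluate a protocol's drive signals
#'
#' @param protocol a [drive_protocol()].
#' @param t time(s), >= 0.
#' @return numeric vector: the applied voltage or bath temperature at `t`.
#' @export
protocol_voltage <- function(protocol, t) {
  v <- protocol$voltage
  switch(v$kind,
         dc = rep(v$V, length(t)),
         ramp = v$V_start + (v$V_end - v$V_start) *
           pmin(pmax(t / v$duration, 0), 1),
         ac = v$V_DC + v$V_AC *
           (if (v$fun == "cos") cos(v$omega * t + v$phase)
            else sin(v$omega * t + v$phase)))
}

#' @rdname protocol_voltage
#' @export
protocol_temperature <- function(protocol, t) {
  tm <- protocol$temperature
  switch(tm$kind,
         const = rep(tm$T0, length(t)),
         ac = tm$T_star * (1 + tm$a_T * sin(tm$omega * t + tm$phase)))
}
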