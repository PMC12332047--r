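#' Reference parameter set
#'
#' A calibrated one-particle device/circuit pair, in the package's
#' dimensionless units, for which increasing the applied DC voltage
#' traverses the canonical regime sequence: quiescence, regular
#' (self-sustained) spiking, sparse noise-induced spiking, and intermittent
#' bursting.  The deterministic companion model with these parameters shows
#' two Andronov-Hopf bifurcations bracketing the low-voltage spiking
#' branch, and a multistability window where a stable fixed point coexists
#' with the spiking limit cycle.  The calibration is a repository artefact:
#' the values were chosen for this phenomenology, not measured on hardware.
#'
#' @param n_particles 1 (default) or 2.  The two-particle variant keeps the
#'   same gap, potential and circuit but pairs them with a stronger thermal
#'   noise scale (`k_B = 0.01` instead of `0.003`): with two clusters
#'   sharing the gap the second cluster's excursions are gated by the slow
#'   diffusive wandering of the first, and the higher noise level makes the
#'   resulting intermittent (bursting) regime accessible at high drive.
#' @param D_V external voltage-noise intensity (default 0: all
#'   stochasticity is thermal).
#' @param k_B override the paired noise scale.
#' @return list with elements `device` (a [device_params()]), `circuit`
#'   (a [circuit_params()]), `T0` (operating bath temperature), and
#'   `V_range` (voltage span covering all regimes).
#' @export
reference_params <- function(n_particles = 1L, D_V = 0, k_B = NULL) {
  potential <- default_potential(L = 1, depth = 1)
  k_B <- k_B %||% (if (n_particles == 2L) 0.01 else 0.003)
  device <- device_params(
    R_t = 0.0025 / (2 * exp(10)),  # R(0) = 0.0025 R_ext
    lambda = 0.05, L = 1,
    eta = 3, q = 20, q_T = 1,
    C_th = 5, kappa = 0.5, k_B = k_B,
    n_particles = n_particles,
    potential = potential, field_sign = 1)
  circuit <- circuit_params(R_ext = 1, C = 1, D_V = D_V)
  list(device = device, circuit = circuit, T0 = 0.05,
       V_range = c(0.6, 4.5))
}
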