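#' Memristor resistance laws
#'
#' Electron tunnelling through the Ag cluster(s) bridging the gap gives the
#' memristor resistance.  For one mobile cluster at position `x` the two
#' tunnelling gaps (filament tip to cluster, cluster to electrode) act in
#' series and the resistance collapses to
#' `R(x) = R0 * cosh(x / lambda)` with `R0 = 2 R_t exp(L / (2 lambda))`,
#' minimal when the cluster sits mid-gap.  For two clusters at `x1 <= x2`
#' three gaps act in series:
#' `R = R_t (exp((L/2 + x1)/lambda) + exp((x2 - x1)/lambda) +
#'           exp((L/2 - x2)/lambda))`.
#'
#' @param x,x1,x2 cluster position(s), within `[-L/2, L/2]`; for two
#'   clusters `x1 <= x2` is required (renumber first).
#' @param p a [device_params()].
#' @return resistance in the resistance units of `p` (same units as `R_t`).
#' @export
resistance_one <- function(x, p) {
  stopifnot(inherits(p, "tn_device"))
  bad_lo <- x < -p$L / 2
  bad_hi <- x > p$L / 2
  if (any(bad_lo)) {
    stop_tn("position x = %g below the gap lower bound -L/2 = %g",
            x[bad_lo][1], -p$L / 2, class = "tn_domain_error")
  }
  if (any(bad_hi)) {
    stop_tn("position x = %g above the gap upper bound L/2 = %g",
            x[bad_hi][1], p$L / 2, class = "tn_domain_error")
  }
  r0_of(p) * cosh(x / p$lambda)
}

r0_of <- function(p) 2 * p$R_t * exp(p$L / (2 * p$lambda))

#' @rdname resistance_one
#' @export
resistance_two <- function(x1, x2, p) {
  stopifnot(inherits(p, "tn_device"))
  if (any(x1 > x2)) {
    stop_tn("particle ordering violated (x1 > x2); renumber particles first",
            class = "tn_order_error")
  }
  if (any(x1 < -p$L / 2) || any(x2 > p$L / 2)) {
    stop_tn("particle position outside the gap [-L/2, L/2]",
            class = "tn_domain_error")
  }
  p$R_t * (exp((p$L / 2 + x1) / p$lambda) +
           exp((x2 - x1) / p$lambda) +
           exp((p$L / 2 - x2) / p$lambda))
}

#' Spatial derivative of the one-particle resistance
#'
#' `dR/dx = (R0 / lambda) * sinh(x / lambda)`; antisymmetric in `x` and zero
#' mid-gap.  Needed by the deterministic companion model, where the gradient
#' subsystem sources are proportional to `R'(x)`.
#'
#' @inheritParams resistance_one
#' @return derivative of resistance with respect to position.
#' @export
resistance_gradient <- function(x, p) {
  stopifnot(inherits(p, "tn_device"))
  if (any(x < -p$L / 2 | x > p$L / 2)) {
    stop_tn("position outside the gap [-L/2, L/2]",
            class = "tn_domain_error")
  }
  r0_of(p) / p$lambda * sinh(x / p$lambda)
}

#' Memristor conductance
#'
#' `G = 1/R`; with `normalise = TRUE` the conductance is reported relative
#' to the device maximum `G_max = 1/R_min` (`R_min = R(0)` for one particle,
#' `R(0, 0)` for two), so `0 < G/G_max <= 1`.
#'
#' @param x for one particle, a position vector; for two particles, a
#'   two-column matrix of ordered positions.  A `tn_trace` may be passed
#'   instead, in which case its position columns are used.
#' @param p a [device_params()].
#' @param normalise report `G / G_max` instead of `G`.
#' @return numeric vector of conductances.
#' @export
conductance <- function(x, p, normalise = FALSE) {
  stopifnot(inherits(p, "tn_device"))
  if (inherits(x, "tn_trace")) {
    x <- if (p$n_particles == 2L) cbind(x$x1, x$x2) else x$x
  }
  R <- if (p$n_particles == 2L) {
    x <- as.matrix(x)
    resistance_two(x[, 1], x[, 2], p)
  } else {
    resistance_one(x, p)
  }
  G <- 1 / R
  if (normalise) G / (1 / r_min_of(p)) else G
}

r_min_of <- function(p) {
  if (p$n_particles == 2L) {
    p$R_t * (2 * exp(p$L / (2 * p$lambda)) + 1)
  } else {
    r0_of(p)
  }
}
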