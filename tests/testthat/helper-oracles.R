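# Brute-force oracles kept independent of the implementation paths they
# check.

# Ray-casting point-in-polygon (even-odd rule); boundary treated as inside
# via a small epsilon on the crossing test.
oracle_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    if ((yi > py) != (yj > py)) {
      x_cross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < x_cross) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_hull_coverage <- function(reference, cloud) {
  hull_idx <- grDevices::chull(cloud)
  hx <- cloud[hull_idx, 1]; hy <- cloud[hull_idx, 2]
  mean(vapply(seq_len(nrow(reference)), function(k) {
    oracle_in_polygon(reference[k, 1], reference[k, 2], hx, hy)
  }, logical(1)))
}

# Central finite difference of a scalar function.
oracle_cdiff <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# Iterative (one-wall-at-a-time) reflection into [-h, h].
oracle_reflect <- function(x, h) {
  while (x > h || x < -h) {
    if (x > h) x <- 2 * h - x
    if (x < -h) x <- -2 * h - x
  }
  x
}

# Tiny devices used across tests.
toy_device <- function(q = 0, q_T = 0, eta = 1, k_B = 1, k_spring = 50,
                       kappa = 1, C_th = 1, n_particles = 1) {
  device_params(R_t = 1, lambda = 0.1, L = 1, eta = eta, q = q, q_T = q_T,
                C_th = C_th, kappa = kappa, k_B = k_B,
                n_particles = n_particles,
                potential = potential_spec(
                  "polynomial", coefficients = c(0, 0, k_spring / 2),
                  well_position = 0))
}
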