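#' Right-hand side of the deterministic thermo-electric model
#'
#' Noise-free companion of the stochastic model in which thermal
#' fluctuations are replaced by deterministic thermophoretic/thermoelectric
#' forces.  The state is `(x, T', V, V')` where `T'` and `V'` are the
#' thermal and electric gradients across the gap:
#' \deqn{\eta \dot x = -U'(x) + s\,qV/L - q_T T'}
#' \deqn{\dot T' = (2 V V' R - V^2 R') / (C_{th} R^2) - \kappa T'}
#' \deqn{\tau \dot V = V_{ext} - (1 + R_{ext}/R) V}
#' \deqn{\tau \dot V' = -(1 + R_{ext}/R) V' + (R_{ext} R'/R^2) V}
#' with `s` the configured field sign and `R = R(x)`, `R' = dR/dx` the
#' one-particle resistance law.
#'
#' @param state numeric length-4 vector `(x, T_prime, V, V_prime)`.
#' @param device a one-particle [device_params()].
#' @param circuit a [circuit_params()].
#' @param V_ext applied voltage (scalar).
#' @return numeric length-4 derivative vector.
#' @export
det_rhs <- function(state, device, circuit, V_ext) {
  x <- state[1]; Tp <- state[2]; V <- state[3]; Vp <- state[4]
  R0 <- r0_of(device)
  R <- R0 * cosh(x / device$lambda)
  Rp <- R0 / device$lambda * sinh(x / device$lambda)
  load <- 1 + circuit$R_ext / R
  c(
    (potential_force(x, device$potential) +
       device$field_sign * device$q * V / device$L -
       device$q_T * Tp) / device$eta,
    (2 * V * Vp * R - V^2 * Rp) / (device$C_th * R^2) - device$kappa * Tp,
    (V_ext - load * V) / circuit$tau,
    (-load * Vp + circuit$R_ext * Rp / R^2 * V) / circuit$tau
  )
}

det_rhs_desolve <- function(t, y, parms) {
  V_ext <- if (is.function(parms$V_ext)) parms$V_ext(t) else parms$V_ext
  list(det_rhs(y, parms$device, parms$circuit, V_ext))
}

#' Numerical Jacobian of the deterministic model
#'
#' Central finite differences (step `h`) of [det_rhs()].
#'
#' @inheritParams det_rhs
#' @param h finite-difference step in scaled units.
#' @return 4 x 4 Jacobian matrix.
#' @export
det_jacobian <- function(state, device, circuit, V_ext, h = 1e-6) {
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    up <- dn <- state
    up[j] <- up[j] + h; dn[j] <- dn[j] - h
    J[, j] <- (det_rhs(up, device, circuit, V_ext) -
               det_rhs(dn, device, circuit, V_ext)) / (2 * h)
  }
  J
}

# Frozen-x steady state of the gradient/voltage subsystem; reduces the
# fixed-point problem to a scalar equation in x.
frozen_x_steady <- function(x, device, circuit, V_ext) {
  R0 <- r0_of(device)
  R <- R0 * cosh(x / device$lambda)
  Rp <- R0 / device$lambda * sinh(x / device$lambda)
  V <- V_ext * R / (R + circuit$R_ext)
  Vp <- circuit$R_ext * Rp * V / (R * (R + circuit$R_ext))
  Tp <- if (device$kappa > 0) {
    (2 * V * Vp * R - V^2 * Rp) / (device$kappa * device$C_th * R^2)
  } else 0
  list(R = R, Rp = Rp, V = V, Vp = Vp, Tp = Tp)
}

fixed_point_residual <- function(x, device, circuit, V_ext) {
  st <- frozen_x_steady(x, device, circuit, V_ext)
  potential_force(x, device$potential) +
    device$field_sign * device$q * st$V / device$L -
    device$q_T * st$Tp
}

#' Fixed points of the deterministic model
#'
#' Scans `x_grid` for sign changes of the reduced scalar equilibrium
#' equation (the gradient and voltage subsystems are linear in `T'`, `V`,
#' `V'` at frozen `x` and are eliminated analytically), polishes each
#' bracket with [stats::uniroot()], deduplicates, and classifies stability
#' from the eigenvalues of the numerical Jacobian.
#'
#' @param V_ext applied voltage.
#' @param device,circuit model objects (one-particle device).
#' @param x_grid positions to scan; defaults to 400 points spanning the gap.
#' @param dedup_tol roots closer than this collapse to one.
#' @return data frame with one row per fixed point: `x`, `T_prime`, `V`,
#'   `V_prime`, `stable`, `re_max` (largest eigenvalue real part),
#'   `re_complex`, `im_complex` (leading complex pair, `NA` if none),
#'   `residual`.
#' @export
find_fixed_points <- function(V_ext, device, circuit, x_grid = NULL,
                              dedup_tol = 1e-5) {
  if (device$n_particles != 1L) {
    stop_tn("deterministic analysis supports the one-particle model",
            class = "tn_config_error")
  }
  half <- device$L / 2
  if (is.null(x_grid)) {
    x_grid <- seq(-half * 0.999, half * 0.999, length.out = 400L)
  }
  g <- vapply(x_grid, fixed_point_residual, numeric(1),
              device = device, circuit = circuit, V_ext = V_ext)
  roots <- numeric(0)
  for (i in seq_len(length(x_grid) - 1L)) {
    if (!is.finite(g[i]) || !is.finite(g[i + 1])) next
    if (g[i] == 0) roots <- c(roots, x_grid[i])
    if (g[i] * g[i + 1] < 0) {
      r <- tryCatch(
        uniroot(fixed_point_residual, c(x_grid[i], x_grid[i + 1]),
                device = device, circuit = circuit, V_ext = V_ext,
                tol = 1e-12)$root,
        error = function(e) NA_real_)
      if (is.finite(r)) roots <- c(roots, r)
    }
  }
  if (length(g) && g[length(g)] == 0) {
    roots <- c(roots, x_grid[length(x_grid)])
  }
  if (!length(roots)) {
    warning("no fixed point found on the supplied grid (V_ext = ",
            format(V_ext), ")")
    return(data.frame(x = numeric(0), T_prime = numeric(0),
                      V = numeric(0), V_prime = numeric(0),
                      stable = logical(0), re_max = numeric(0),
                      re_complex = numeric(0), im_complex = numeric(0),
                      residual = numeric(0)))
  }
  roots <- sort(roots)
  keep <- c(TRUE, diff(roots) > dedup_tol * device$L)
  roots <- roots[keep]
  out <- lapply(roots, function(r) {
    st <- frozen_x_steady(r, device, circuit, V_ext)
    state <- c(r, st$Tp, st$V, st$Vp)
    J <- det_jacobian(state, device, circuit, V_ext)
    ev <- eigen(J, only.values = TRUE)$values
    cplx <- ev[abs(Im(ev)) > 1e-9]
    lead <- if (length(cplx)) cplx[which.max(Re(cplx))] else NA_complex_
    data.frame(x = r, T_prime = st$Tp, V = st$V, V_prime = st$Vp,
               stable = all(Re(ev) < 0), re_max = max(Re(ev)),
               re_complex = if (length(cplx)) Re(lead) else NA_real_,
               im_complex = if (length(cplx)) abs(Im(lead)) else NA_real_,
               residual = sqrt(sum(det_rhs(state, device, circuit,
                                           V_ext)^2)))
  })
  do.call(rbind, out)
}

#' Integrate the deterministic model
#'
#' Adaptive stiff-capable integration (`deSolve::ode`, `lsoda`) of the
#' four-dimensional deterministic system, optionally under a time-varying
#' `V_ext(t)`.
#'
#' @param state0 initial `(x, T_prime, V, V_prime)`.
#' @param times output times.
#' @param device,circuit model objects.
#' @param V_ext scalar voltage or a function of time.
#' @param rtol,atol integration tolerances.
#' @return matrix of class `deSolve` with columns `time`, `x`, `T_prime`,
#'   `V`, `V_prime`.
#' @export
det_integrate <- function(state0, times, device, circuit, V_ext,
                          rtol = 1e-8, atol = 1e-10) {
  out <- deSolve::ode(y = c(x = state0[1], T_prime = state0[2],
                            V = state0[3], V_prime = state0[4]),
                      times = times, func = det_rhs_desolve,
                      parms = list(device = device, circuit = circuit,
                                   V_ext = V_ext),
                      method = "lsoda", rtol = rtol, atol = atol)
  out
}

# Detect a sustained oscillation of x in the tail of a deterministic run.
cycle_from_run <- function(out, floor_amp) {
  n <- nrow(out)
  tail_idx <- out[, "time"] >= out[n, "time"] -
    0.2 * (out[n, "time"] - out[1, "time"])
  xs <- out[tail_idx, "x"]
  amp <- max(xs) - min(xs)
  if (amp > floor_amp) {
    list(spiking = TRUE, x_min = min(xs), x_max = max(xs), amp = amp)
  } else {
    list(spiking = FALSE, x_min = NA_real_, x_max = NA_real_, amp = amp)
  }
}

find_limit_cycle <- function(V_ext, device, circuit, starts = NULL,
                             t_max = 400, floor_amp = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  floor_amp <- floor_amp %||% (1e-3 * device$L)
  half <- device$L / 2
  if (is.null(starts)) {
    starts <- c(device$potential$well_position, 0, 0.35 * device$L)
  }
  for (x0 in starts) {
    st <- frozen_x_steady(x0, device, circuit, V_ext)
    out <- det_integrate(c(x0, st$Tp, st$V, st$Vp),
                         seq(0, t_max, length.out = 2000L),
                         device, circuit, V_ext, rtol = rtol, atol = atol)
    res <- cycle_from_run(out, floor_amp)
    if (res$spiking) return(res)
  }
  list(spiking = FALSE, x_min = NA_real_, x_max = NA_real_, amp = 0)
}

refine_hopf <- function(V_lo, V_hi, x_near, device, circuit,
                        tol = 1e-6, max_iter = 60L) {
  re_at <- function(V) {
    fp <- find_fixed_points(V, device, circuit)
    if (!nrow(fp)) return(NA_real_)
    fp <- fp[which.min(abs(fp$x - x_near)), ]
    fp$re_complex
  }
  r_lo <- re_at(V_lo); r_hi <- re_at(V_hi)
  if (!is.finite(r_lo) || !is.finite(r_hi) || r_lo * r_hi > 0) {
    return(list(V = (V_lo + V_hi) / 2, re = NA_real_))
  }
  for (i in seq_len(max_iter)) {
    V_mid <- (V_lo + V_hi) / 2
    r_mid <- re_at(V_mid)
    if (!is.finite(r_mid)) break
    if (abs(r_mid) < tol) return(list(V = V_mid, re = r_mid))
    if (r_lo * r_mid <= 0) {
      V_hi <- V_mid; r_hi <- r_mid
    } else {
      V_lo <- V_mid; r_lo <- r_mid
    }
  }
  list(V = (V_lo + V_hi) / 2, re = re_at((V_lo + V_hi) / 2))
}

#' Bifurcation diagram over an applied-voltage sweep
#'
#' Tracks fixed-point branches over a monotone `V_ext` grid, flags
#' Andronov-Hopf candidates where the leading complex eigenvalue pair's
#' real part changes sign between grid points (refined by bisection), scans
#' for stable limit cycles by long transient-discarding integration from
#' perturbed starts, and reports windows where a stable fixed point
#' coexists with a stable cycle (dynamical multistability).
#'
#' @param device,circuit model objects (one-particle device).
#' @param V_grid monotone grid of applied voltages.
#' @param cycle_t_max integration horizon for cycle detection.
#' @param floor_amp oscillation-amplitude floor distinguishing spiking from
#'   decay (default `1e-3 * L`).
#' @param hopf_tol bisection tolerance on the eigenvalue real part.
#' @param find_cycles set `FALSE` to skip the (slower) cycle scan.
#' @return an object of class `tn_bifurcation`: list with `fixed_points`
#'   (tidy data frame over the grid), `hopf` (data frame `V_ext`, `x`,
#'   `re`), `cycles` (data frame `V_ext`, `x_min`, `x_max`, `spiking`),
#'   `coexistence` (data frame `V_lo`, `V_hi`), and `V_grid`.
#' @export
continue_branches <- function(device, circuit, V_grid,
                              cycle_t_max = 400, floor_amp = NULL,
                              hopf_tol = 1e-6, find_cycles = TRUE) {
  if (is.unsorted(V_grid)) {
    stop_tn("'V_grid' must be monotone increasing",
            class = "tn_config_error")
  }
  fps <- lapply(V_grid, function(V) {
    fp <- find_fixed_points(V, device, circuit)
    if (nrow(fp)) fp$V_ext <- V
    fp
  })
  fp_all <- do.call(rbind, fps[vapply(fps, nrow, 1L) > 0])
  # Hopf candidates: sign change of the leading complex pair between
  # consecutive grid points, matching branches by nearest x.
  hopf <- list()
  for (i in seq_len(length(V_grid) - 1L)) {
    a <- fps[[i]]; b <- fps[[i + 1L]]
    if (!nrow(a) || !nrow(b)) next
    for (k in seq_len(nrow(a))) {
      j <- which.min(abs(b$x - a$x[k]))
      ra <- a$re_complex[k]; rb <- b$re_complex[j]
      if (is.finite(ra) && is.finite(rb) && ra * rb < 0) {
        ref <- refine_hopf(V_grid[i], V_grid[i + 1L],
                           (a$x[k] + b$x[j]) / 2, device, circuit,
                           tol = hopf_tol)
        hopf[[length(hopf) + 1L]] <-
          data.frame(V_ext = ref$V, x = (a$x[k] + b$x[j]) / 2,
                     re = ref$re)
      }
    }
  }
  hopf <- if (length(hopf)) do.call(rbind, hopf) else
    data.frame(V_ext = numeric(0), x = numeric(0), re = numeric(0))
  cycles <- NULL
  if (find_cycles) {
    cyc <- lapply(V_grid, function(V) {
      res <- find_limit_cycle(V, device, circuit, t_max = cycle_t_max,
                              floor_amp = floor_amp)
      data.frame(V_ext = V, x_min = res$x_min, x_max = res$x_max,
                 spiking = res$spiking)
    })
    cycles <- do.call(rbind, cyc)
  } else {
    cycles <- data.frame(V_ext = numeric(0), x_min = numeric(0),
                         x_max = numeric(0), spiking = logical(0))
  }
  coex <- data.frame(V_lo = numeric(0), V_hi = numeric(0))
  if (nrow(cycles)) {
    has_stable_fp <- vapply(seq_along(V_grid), function(i) {
      nrow(fps[[i]]) > 0 && any(fps[[i]]$stable)
    }, logical(1))
    both <- has_stable_fp & cycles$spiking
    if (any(both)) {
      r <- rle(both)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      ii <- which(r$values)
      coex <- data.frame(V_lo = V_grid[starts[ii]],
                         V_hi = V_grid[ends[ii]])
    }
  }
  structure(list(fixed_points = fp_all, hopf = hopf, cycles = cycles,
                 coexistence = coex, V_grid = V_grid),
            class = "tn_bifurcation")
}

#' @export
print.tn_bifurcation <- function(x, ...) {
  cat("<tn_bifurcation>", length(x$V_grid), "voltages;",
      nrow(x$hopf), "Hopf point(s)")
  if (nrow(x$hopf)) {
    cat(" at V =", paste(format(x$hopf$V_ext, digits = 5),
                         collapse = ", "))
  }
  cat("\n  spiking at", sum(x$cycles$spiking), "grid voltages;",
      nrow(x$coexistence), "coexistence window(s)\n")
  invisible(x)
}

#' Export a bifurcation diagram as tidy CSV
#'
#' One row per diagram feature with a `kind` column
#' (`fp_stable`, `fp_unstable`, `lc_min`, `lc_max`, `hopf`).
#'
#' @param diagram a `tn_bifurcation`.
#' @param path CSV path.
#' @export
export_diagram <- function(diagram, path) {
  fp <- diagram$fixed_points
  rows <- list()
  if (!is.null(fp) && nrow(fp)) {
    rows$fp <- data.frame(V_ext = fp$V_ext, x = fp$x,
                          kind = ifelse(fp$stable, "fp_stable",
                                        "fp_unstable"),
                          eigen_real = fp$re_max,
                          eigen_imag = fp$im_complex)
  }
  cy <- diagram$cycles[diagram$cycles$spiking, , drop = FALSE]
  if (nrow(cy)) {
    rows$lc <- data.frame(
      V_ext = rep(cy$V_ext, 2), x = c(cy$x_min, cy$x_max),
      kind = rep(c("lc_min", "lc_max"), each = nrow(cy)),
      eigen_real = NA_real_, eigen_imag = NA_real_)
  }
  if (nrow(diagram$hopf)) {
    rows$hopf <- data.frame(V_ext = diagram$hopf$V_ext,
                            x = diagram$hopf$x, kind = "hopf",
                            eigen_real = diagram$hopf$re,
                            eigen_imag = NA_real_)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Quasi-static hysteresis sweep
#'
#' Integrates the deterministic model while `V_ext(t)` ramps slowly up and
#' then back down, and reports where the ascending and descending
#' `(V_ext, x)` paths disagree — the signature of dynamical multistability.
#' Paths are compared through per-voltage-bin envelopes of `x`.
#'
#' @param device,circuit model objects.
#' @param V_min,V_max sweep range.
#' @param sweep_time duration of each leg (up and down); make it much
#'   longer than every relaxation time for an adiabatic sweep.
#' @param n_bins voltage bins for path comparison.
#' @param tol disagreement tolerance on the binned envelopes (default
#'   `0.02 * L`).
#' @return list with `up`, `down` (data frames `t`, `V_ext`, `x`),
#'   `window` (`c(V_lo, V_hi)` of the disagreement region, or `NULL`), and
#'   `binned` (per-bin envelope comparison).
#' @export
hysteresis_sweep <- function(device, circuit, V_min, V_max, sweep_time,
                             n_bins = 60L, tol = NULL) {
  tol <- tol %||% (0.02 * device$L)
  x0 <- device$potential$well_position
  st <- frozen_x_steady(x0, device, circuit, V_min)
  times <- seq(0, sweep_time, length.out = 4000L)
  v_up <- function(t) V_min + (V_max - V_min) * t / sweep_time
  up <- det_integrate(c(x0, st$Tp, st$V, st$Vp), times, device, circuit,
                      v_up, rtol = 1e-8, atol = 1e-10)
  end_state <- up[nrow(up), c("x", "T_prime", "V", "V_prime")]
  v_dn <- function(t) V_max - (V_max - V_min) * t / sweep_time
  dn <- det_integrate(as.numeric(end_state), times, device, circuit,
                      v_dn, rtol = 1e-8, atol = 1e-10)
  up_df <- data.frame(t = up[, "time"], V_ext = v_up(up[, "time"]),
                      x = up[, "x"])
  dn_df <- data.frame(t = dn[, "time"], V_ext = v_dn(dn[, "time"]),
                      x = dn[, "x"])
  edges <- seq(V_min, V_max, length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  env <- function(df) {
    idx <- findInterval(df$V_ext, edges, rightmost.closed = TRUE)
    lo <- hi <- rep(NA_real_, n_bins)
    for (b in seq_len(n_bins)) {
      xs <- df$x[idx == b]
      if (length(xs)) { lo[b] <- min(xs); hi[b] <- max(xs) }
    }
    list(lo = lo, hi = hi)
  }
  e_up <- env(up_df); e_dn <- env(dn_df)
  disagree <- abs(e_up$lo - e_dn$lo) > tol | abs(e_up$hi - e_dn$hi) > tol
  disagree[is.na(disagree)] <- FALSE
  window <- if (any(disagree)) range(mids[disagree]) else NULL
  list(up = up_df, down = dn_df, window = window,
       binned = data.frame(V_ext = mids, up_lo = e_up$lo, up_hi = e_up$hi,
                           down_lo = e_dn$lo, down_hi = e_dn$hi,
                           disagree = disagree))
}

#' Basin-of-attraction boundary at fixed voltage
#'
#' Classifies initial cluster positions as leading to spiking (sustained
#' oscillation of `x`) or non-spiking (decay to a fixed point) under the
#' deterministic model, and estimates the boundary position separating the
#' two basins.  The remaining state variables start from their frozen-`x`
#' steady values.
#'
#' @param V_ext applied voltage (inside a coexistence window for a
#'   nontrivial boundary).
#' @param device,circuit model objects.
#' @param x0_grid initial positions to classify.
#' @param t_max integration horizon.
#' @param floor_amp amplitude floor for the spiking criterion.
#' @return data frame `x0`, `outcome` (`"spiking"`, `"non-spiking"`,
#'   `"undecided"`), plus attribute `boundary` (midpoints between
#'   differently classified neighbours).
#' @export
basin_boundary <- function(V_ext, device, circuit, x0_grid,
                           t_max = 300, floor_amp = NULL) {
  floor_amp <- floor_amp %||% (1e-3 * device$L)
  outcome <- character(length(x0_grid))
  for (i in seq_along(x0_grid)) {
    st <- frozen_x_steady(x0_grid[i], device, circuit, V_ext)
    out <- det_integrate(c(x0_grid[i], st$Tp, st$V, st$Vp),
                         seq(0, t_max, length.out = 1500L),
                         device, circuit, V_ext)
    res <- cycle_from_run(out, floor_amp)
    mid <- cycle_from_run(out[seq_len(nrow(out) %/% 2), , drop = FALSE],
                          floor_amp)
    outcome[i] <- if (res$spiking) {
      "spiking"
    } else if (!res$spiking && !mid$spiking) {
      "non-spiking"
    } else if (!res$spiking && mid$spiking) {
      "non-spiking" # decaying envelope
    } else {
      "undecided"
    }
  }
  boundary <- numeric(0)
  for (i in seq_len(length(x0_grid) - 1L)) {
    if (outcome[i] != outcome[i + 1L]) {
      boundary <- c(boundary, (x0_grid[i] + x0_grid[i + 1L]) / 2)
    }
  }
  structure(data.frame(x0 = x0_grid, outcome = outcome),
            boundary = boundary)
}
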