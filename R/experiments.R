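#' Spiking-regime sweep
#'
#' Simulates the reference neuron at a set of DC voltage levels, detects
#' spikes on the conductance (log mode), and labels each condition
#' `quiescent`, `regular`, `sparse` or `bursting` by majority vote over
#' seeds.  The default levels and the two-particle reference device are
#' calibrated so increasing voltage traverses the canonical sequence:
#' quiescence, regular self-sustained spiking, sparse irregular
#' noise-induced spiking, and intermittent bursting, then quiescence again.
#'
#' Labelling rules (per seed, config-exposed): a condition with rate below
#' `rate_floor` is `quiescent`; else CV1 at or below `cv1_regular` is
#' `regular`; else CV1 at or above `cv1_bursting` together with at least
#' `min_bursts` bursts of mean size `burst_size` or more is `bursting`
#' (extreme global irregularity arises from dense spike clusters separated
#' by long quiet inter-train intervals); anything else is `sparse`.
#'
#' @param V_levels DC voltages to probe (increasing).
#' @param seeds integer vector of seeds (>= 1).
#' @param device,circuit,T0 model objects; default: two-particle
#'   [reference_params()].
#' @param t_max,dt simulation length and step per condition.
#' @param rate_floor,cv1_regular,cv1_bursting,min_bursts,burst_size
#'   labelling thresholds.
#' @param burst_isi_factor burst segmentation threshold as a multiple of
#'   the median ISI (default 5).
#' @param out_dir optional directory: traces (CSV + JSON sidecar), spike
#'   trains and the summary table are persisted there.
#' @return list with `summary` (per condition x seed: rate, cv1, cv2,
#'   n_bursts, mean_burst, label), `labels` (majority label per V level),
#'   `trains` (list of spike trains, `[[condition]][[seed]]`).
#' @export
run_regimes <- function(V_levels = c(0.6, 0.95, 2.9, 3.3),
                        seeds = 1:5, device = NULL, circuit = NULL,
                        T0 = NULL, t_max = 600, dt = 5e-4,
                        rate_floor = 0.05, cv1_regular = 0.6,
                        cv1_bursting = 1.75, min_bursts = 3,
                        burst_size = 3,
                        burst_isi_factor = 5, out_dir = NULL) {
  if (is.null(device)) {
    ref <- reference_params(2L)
    device <- ref$device; circuit <- circuit %||% ref$circuit
    T0 <- T0 %||% ref$T0
  }
  T0 <- T0 %||% 0.05
  if (length(V_levels) < 3L) {
    stop_tn("need at least three voltage levels", class = "tn_config_error")
  }
  rows <- list(); trains <- list()
  for (vi in seq_along(V_levels)) {
    V <- V_levels[vi]
    trains[[vi]] <- list()
    for (si in seq_along(seeds)) {
      pr <- drive_protocol(voltage = list(kind = "dc", V = V),
                           temperature = list(kind = "const", T0 = T0))
      trace <- simulate_neuron(device, circuit, pr,
                        sim_config(t_max = t_max, dt = dt,
                                   seed = seeds[si], record_stride = 8L))
      st <- detect_spikes(trace, signal = "G_norm", mode = "log")
      n <- length(st$timestamps)
      rate <- n / st$duration
      c1 <- if (n >= 4L) cv1(st) else NA_real_
      c2 <- if (n >= 4L) cv2(st) else NA_real_
      nb <- mb <- NA_real_
      if (n >= 6L) {
        b <- segment_bursts(st, burst_isi_factor * median(isi(st)))
        nb <- nrow(b$bursts); mb <- mean(b$bursts$n_spikes)
      }
      label <- if (rate < rate_floor || n < 10L) {
        "quiescent"
      } else if (is.finite(c1) && c1 <= cv1_regular) {
        "regular"
      } else if (is.finite(c1) && c1 >= cv1_bursting &&
                 is.finite(nb) && nb >= min_bursts && mb >= burst_size) {
        "bursting"
      } else {
        "sparse"
      }
      rows[[length(rows) + 1L]] <-
        data.frame(V_ext = V, seed = seeds[si], n_spikes = n, rate = rate,
                   cv1 = c1, cv2 = c2, n_bursts = nb, mean_burst = mb,
                   label = label)
      trains[[vi]][[si]] <- st
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_spike_train(st, file.path(out_dir,
          sprintf("train_V%.3g_seed%d.csv", V, seeds[si])))
      }
    }
  }
  summary <- do.call(rbind, rows)
  majority <- vapply(V_levels, function(V) {
    labs <- summary$label[summary$V_ext == V]
    names(which.max(table(labs)))
  }, character(1))
  labels <- data.frame(V_ext = V_levels, label = majority)
  if (!all(c("regular", "sparse", "bursting") %in% majority) &&
      all(majority == "quiescent")) {
    stop_tn("no spiking at any voltage level: calibration range mismatch",
            class = "tn_diagnostic_error")
  }
  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "regimes_summary.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, list(experiment = "regimes",
                                 V_levels = V_levels, seeds = seeds,
                                 t_max = t_max, dt = dt, T0 = T0))
  }
  list(summary = summary, labels = labels, trains = trains)
}

#' CV1/CV2 cloud over an operating-point sweep
#'
#' Simulates the one-particle reference neuron on a grid of conditions
#' (applied voltage, load resistance, capacitance, optionally bath
#' temperature) and records one (CV1, CV2) point per condition and seed —
#' the artificial-neuron counterpart of a biological spiking-statistics
#' scatter.  Conditions with fewer than 4 detected spikes contribute no
#' point.
#'
#' @param conditions data frame with columns `V_ext`, `R_ext`, `C` and
#'   optionally `T0`; default: a calibrated grid spanning the regular and
#'   irregular corners of the reference device.
#' @param seeds seeds per condition.
#' @param device base device (default one-particle reference).
#' @param t_max,dt simulation length and step.
#' @param reference optional data frame with columns `cv1`, `cv2` (e.g. a
#'   biological CV table read from CSV); when given, the convex-hull
#'   coverage of it by the simulated cloud is reported.
#' @param out_dir optional directory: tidy result tables and a JSON
#'   manifest (parameters, seeds, versions) are persisted there.
#' @return list with `points` (tidy CVPoint table: cv1, cv2, n_isi, V_ext,
#'   R_ext, C, T0, seed) and `coverage` (fraction, or NA without a
#'   reference).
#' @export
run_cv_cloud <- function(conditions = NULL, seeds = 1:3, device = NULL,
                         t_max = 400, dt = 5e-4, reference = NULL,
                         out_dir = NULL) {
  ref <- reference_params(1L)
  device <- device %||% ref$device
  if (is.null(conditions)) {
    conditions <- expand.grid(V_ext = c(0.85, 0.95, 1.1, 2.9, 3.3),
                              R_ext = c(0.9, 1, 1.15), C = 1)
  }
  if (!all(c("V_ext", "R_ext", "C") %in% names(conditions))) {
    stop_tn("conditions need V_ext, R_ext and C columns",
            class = "tn_format_error")
  }
  if (!is.null(reference) &&
      !all(c("cv1", "cv2") %in% names(reference))) {
    stop_tn("reference table lacks cv1/cv2 columns",
            class = "tn_format_error")
  }
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    circuit <- circuit_params(R_ext = cond$R_ext, C = cond$C)
    T0 <- if ("T0" %in% names(cond)) cond$T0 else ref$T0
    # bursting corner needs the two-particle variant to spike; use the
    # paired device when the voltage lies beyond the one-particle windows
    dev <- if (cond$V_ext > 2) reference_params(2L)$device else device
    for (s in seeds) {
      pr <- drive_protocol(voltage = list(kind = "dc", V = cond$V_ext),
                           temperature = list(kind = "const", T0 = T0))
      trace <- simulate_neuron(dev, circuit, pr,
                        sim_config(t_max = t_max, dt = dt, seed = s,
                                   record_stride = 8L))
      st <- detect_spikes(trace, signal = "G_norm", mode = "log")
      if (length(st$timestamps) < 4L) next
      rows[[length(rows) + 1L]] <-
        data.frame(cv1 = cv1(st), cv2 = cv2(st),
                   n_isi = length(st$timestamps) - 1L,
                   V_ext = cond$V_ext, R_ext = cond$R_ext, C = cond$C,
                   T0 = T0, seed = s)
    }
  }
  points <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cv1 = numeric(0), cv2 = numeric(0), n_isi = integer(0),
               V_ext = numeric(0), R_ext = numeric(0), C = numeric(0),
               T0 = numeric(0), seed = integer(0))
  coverage <- NA_real_
  if (!is.null(reference) && nrow(points) >= 3L) {
    coverage <- hull_coverage(reference[, c("cv1", "cv2")],
                              points[, c("cv1", "cv2")])
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(points, file.path(out_dir, "cv_points.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, list(experiment = "cv_cloud",
                                 conditions = conditions, seeds = seeds,
                                 t_max = t_max, dt = dt))
  }
  list(points = points, coverage = coverage)
}

#' Frequency-selectivity experiment under AC drive
#'
#' Drives the one-particle reference neuron with
#' `V_ext(t) = V_DC (1 + a_AC cos(2 pi t / t_p))` over a grid of stimulus
#' periods `t_p` and AC amplitudes, collects spike trains, and assembles
#' the two-dimensional ISI histogram (temporal receptive field), the rate
#' curves `r(t_p)`, and the preferred period `t_p*` per amplitude.
#'
#' @param t_p_grid stimulus periods; default spans the neuron's natural
#'   ISI.
#' @param a_AC AC amplitudes as fractions of `V_DC` (>= 1 value).
#' @param V_DC DC operating voltage (inside the regular-spiking window).
#' @param seeds seeds whose spike trains are pooled per condition.
#' @param device,circuit,T0 model objects (default one-particle reference).
#' @param t_max,dt simulation length and step per condition.
#' @param out_dir optional directory: tidy result tables and a JSON
#'   manifest (parameters, seeds, versions) are persisted there.
#' @return list with `trains` (pooled per (a_AC, t_p)), `isi_map` (from
#'   [isi_histogram_2d()], computed for the first amplitude), `rates`
#'   (tidy rate table), `preferred` (t_p* per amplitude), `natural_isi`.
#' @export
run_selectivity <- function(t_p_grid = seq(0.3, 1.5, by = 0.1),
                            a_AC = c(0.2, 0.4, 0.6), V_DC = 0.95,
                            seeds = 1:4, device = NULL, circuit = NULL,
                            T0 = NULL, t_max = 400, dt = 5e-4,
                            out_dir = NULL) {
  ref <- reference_params(1L)
  device <- device %||% ref$device
  circuit <- circuit %||% ref$circuit
  T0 <- T0 %||% ref$T0
  # natural period at V_DC (no AC component)
  pr0 <- drive_protocol(voltage = list(kind = "dc", V = V_DC),
                        temperature = list(kind = "const", T0 = T0))
  tr0 <- simulate_neuron(device, circuit, pr0,
                  sim_config(t_max = t_max, dt = dt, seed = max(seeds) + 1L,
                             record_stride = 8L))
  st0 <- detect_spikes(tr0, signal = "G_norm", mode = "log")
  if (length(st0$timestamps) < 10L) {
    stop_tn("quiescent at V_DC = %g: no natural period; raise V_DC",
            V_DC, class = "tn_diagnostic_error")
  }
  natural_isi <- median(isi(st0))
  trains <- list(); rows <- list()
  for (a in a_AC) {
    key_a <- sprintf("a%.3g", a)
    trains[[key_a]] <- list()
    for (tp in t_p_grid) {
      merged <- list()
      for (s in seeds) {
        pr <- drive_protocol(
          voltage = list(kind = "ac", V_DC = V_DC, V_AC = a * V_DC,
                         period = tp, fun = "cos"),
          temperature = list(kind = "const", T0 = T0))
        trace <- simulate_neuron(device, circuit, pr,
                          sim_config(t_max = t_max, dt = dt, seed = s,
                                     record_stride = 8L))
        merged[[as.character(s)]] <-
          detect_spikes(trace, signal = "G_norm", mode = "log")
      }
      all_isi <- unlist(lapply(merged, isi))
      n_spk <- sum(vapply(merged, function(m) length(m$timestamps), 1L))
      pooled <- spike_train(
        sort(unlist(lapply(seq_along(merged), function(k) {
          merged[[k]]$timestamps + (k - 1L) * t_max
        }))), duration = length(merged) * t_max,
        meta = sprintf("a_AC=%g t_p=%g pooled", a, tp))
      trains[[key_a]][[sprintf("tp%.3g", tp)]] <- pooled
      rows[[length(rows) + 1L]] <-
        data.frame(V_AC = a, t_p = tp,
                   rate = n_spk / (length(merged) * t_max))
    }
  }
  rates <- do.call(rbind, rows)
  rvp <- rate_vs_period(rates = data.frame(t_p = rates$t_p,
                                           rate = rates$rate,
                                           group = rates$V_AC))
  first_a <- trains[[1L]]
  isi_map <- isi_histogram_2d(first_a, t_p_grid)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rates, file.path(out_dir, "selectivity_rates.csv"),
                     row.names = FALSE)
    utils::write.csv(rvp$preferred,
                     file.path(out_dir, "preferred_period.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, list(experiment = "selectivity",
                                 t_p_grid = t_p_grid, a_AC = a_AC,
                                 V_DC = V_DC, seeds = seeds,
                                 t_max = t_max, dt = dt, T0 = T0))
  }
  list(trains = trains, isi_map = isi_map, rates = rates,
       preferred = rvp$preferred, natural_isi = natural_isi)
}

#' Two-signal phase comparator
#'
#' Drives the one-particle reference neuron with a slow sinusoidal voltage
#' `V_ext = V_DC + V_AC sin(omega t)` and a bath-temperature oscillation
#' `T0(t) = T_star (1 + a_T sin(omega t + phi))` of the same frequency, and
#' measures the mean spiking rate as a function of the relative phase
#' `phi`.  With `V_DC - V_AC` reaching into the multistability window of
#' the device, antiphase signals (`phi = pi`) promote noise-induced entry
#' into the spiking state while in-phase signals suppress it, so the rate
#' encodes the phase difference.
#'
#' @param phi_grid relative phases in `[0, 2 pi)`.
#' @param V_DC,V_AC voltage signal; defaults calibrated so the low half
#'   of the cycle dips into the coexistence window.
#' @param T_star,a_T temperature signal (mean and relative amplitude).
#' @param period common signal period; default 20 times the natural ISI
#'   of the regular regime (slow drive).
#' @param seeds seeds averaged per phase (>= 20 for headline statistics).
#' @param device,circuit model objects (default one-particle reference).
#' @param t_max,dt simulation length and step per run.
#' @param out_dir optional directory: tidy result tables and a JSON
#'   manifest (parameters, seeds, versions) are persisted there.
#' @return list with `rates` (per phi x seed), `curve` (mean and sd of the
#'   rate per phi), `phi_min`, `phi_max`.
#' @export
run_phase_detector <- function(phi_grid = c(0, pi / 2, pi, 3 * pi / 2),
                               V_DC = 1.35, V_AC = 0.12,
                               T_star = 0.2, a_T = 0.85, period = 20,
                               seeds = 1:20, device = NULL,
                               circuit = NULL, t_max = 120, dt = 5e-4,
                               out_dir = NULL) {
  ref <- reference_params(1L)
  device <- device %||% ref$device
  circuit <- circuit %||% ref$circuit
  if (abs(a_T) >= 1) {
    stop_tn("|a_T| must be < 1", class = "tn_config_error")
  }
  rows <- list()
  for (phi in phi_grid) {
    for (s in seeds) {
      pr <- drive_protocol(
        voltage = list(kind = "ac", V_DC = V_DC, V_AC = V_AC,
                       period = period, fun = "sin"),
        temperature = list(kind = "ac", T_star = T_star, a_T = a_T,
                           period = period, phase = phi))
      trace <- simulate_neuron(device, circuit, pr,
                        sim_config(t_max = t_max, dt = dt, seed = s,
                                   record_stride = 8L))
      # the limit cycle near the top of the spiking window is smaller than
      # the low-voltage relaxation loop, so accept ~e-fold conductance
      # swings here (chatter at this noise level stays well below that)
      st <- detect_spikes(trace, signal = "G_norm", mode = "log",
                          min_swing = 1.0)
      rows[[length(rows) + 1L]] <-
        data.frame(phi = phi, seed = s,
                   rate = length(st$timestamps) / st$duration)
    }
  }
  rates <- do.call(rbind, rows)
  curve <- do.call(rbind, lapply(split(rates, rates$phi), function(df) {
    data.frame(phi = df$phi[1], mean_rate = mean(df$rate),
               sd_rate = sd(df$rate), n = nrow(df))
  }))
  rownames(curve) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(curve, file.path(out_dir, "phase_rate_curve.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, list(experiment = "phase_detector",
                                 phi_grid = phi_grid, V_DC = V_DC,
                                 V_AC = V_AC, T_star = T_star, a_T = a_T,
                                 period = period, seeds = seeds,
                                 t_max = t_max, dt = dt))
  }
  list(rates = rates, curve = curve,
       phi_min = curve$phi[which.min(curve$mean_rate)],
       phi_max = curve$phi[which.max(curve$mean_rate)])
}

#' Energy and power estimate for thermal signalling
#'
#' Closed-form estimate of the heat needed to modulate the temperature of
#' the Ag clusters in the filament bottleneck by `dT` once per signal
#' cycle: `E = C_Ag * rho_Ag * N * (4/3) pi r_Ag^3 * dT`, and the average
#' power at cycle frequency `f`, `P = E * f`.
#'
#' @param C_Ag specific heat of silver (J g^-1 K^-1).
#' @param rho_Ag density of silver (g cm^-3).
#' @param N number of clusters heated.
#' @param r_Ag cluster radius; unit given by `r_unit` (`"nm"`, `"cm"` or
#'   `"m"`).
#' @param dT temperature modulation (K or degC, identical increments).
#' @param f signal cycle frequency (Hz).
#' @param r_unit unit of `r_Ag`.
#' @return list with `energy_J` (energy per cycle, J) and `power_W`
#'   (average power, W).
#' @export
estimate_energy_power <- function(C_Ag = 0.236, rho_Ag = 10.49, N = 10,
                                  r_Ag = 10, dT = 100, f = 1e8,
                                  r_unit = c("nm", "cm", "m")) {
  r_unit <- match.arg(r_unit)
  for (v in c(C_Ag, rho_Ag, N, r_Ag, dT, f)) check_nonnegative(v, "input")
  r_cm <- switch(r_unit, nm = r_Ag * 1e-7, cm = r_Ag, m = r_Ag * 100)
  volume_cm3 <- 4 / 3 * pi * r_cm^3
  energy <- C_Ag * rho_Ag * N * volume_cm3 * dT
  list(energy_J = energy, power_W = energy * f)
}

write_manifest <- function(out_dir, fields) {
  fields$package_version <-
    as.character(utils::packageVersion("transneuron"))
  fields$r_version <- R.version.string
  jsonlite::write_json(fields, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
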