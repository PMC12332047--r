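#' Spike train container
#'
#' @param timestamps strictly increasing spike times within
#'   `[0, duration]`.
#' @param duration observation window length.
#' @param meta optional free-form source description.
#' @return an object of class `tn_spike_train`.
#' @export
spike_train <- function(timestamps, duration, meta = NULL) {
  timestamps <- as.numeric(timestamps)
  if (any(!is.finite(timestamps))) {
    stop_tn("spike timestamps must be finite", class = "tn_input_error")
  }
  if (is.unsorted(timestamps, strictly = TRUE)) {
    stop_tn("spike timestamps must be strictly increasing",
            class = "tn_input_error")
  }
  check_positive(duration, "duration")
  if (length(timestamps) && (timestamps[1] < 0 ||
                             timestamps[length(timestamps)] > duration)) {
    stop_tn("spike timestamps must lie within [0, duration]",
            class = "tn_input_error")
  }
  structure(list(timestamps = timestamps, duration = duration,
                 meta = meta), class = "tn_spike_train")
}

#' @export
print.tn_spike_train <- function(x, ...) {
  cat("<tn_spike_train>", length(x$timestamps), "spikes over",
      x$duration, "time units; rate",
      format(length(x$timestamps) / x$duration, digits = 4), "\n")
  invisible(x)
}

#' Inter-spike intervals of a train
#'
#' @param train a [spike_train()].
#' @return numeric vector `diff(timestamps)`.
#' @export
isi <- function(train) {
  stopifnot(inherits(train, "tn_spike_train"))
  diff(train$timestamps)
}

require_isis <- function(train, n_min = 3L, what = "CV") {
  k <- length(train$timestamps) - 1L
  if (k < n_min) {
    stop_tn("%s needs at least %d inter-spike intervals (got %d)",
            what, n_min, max(k, 0L), class = "tn_insufficient_data")
  }
  invisible(k)
}

#' Global irregularity index CV1
#'
#' The ratio of the standard deviation of the inter-spike intervals to the
#' mean interval.  A perfectly periodic train gives 0 and a Poisson process
#' gives 1.  The population standard deviation (divisor `n`) is used by
#' default; set `type = "sample"` for the `n - 1` convention.
#'
#' @param train a [spike_train()] with at least 3 ISIs.
#' @param type `"population"` (default) or `"sample"` standard deviation.
#' @return dimensionless CV1 >= 0.
#' @export
cv1 <- function(train, type = c("population", "sample")) {
  type <- match.arg(type)
  require_isis(train, 3L, "CV1")
  d <- isi(train)
  s <- if (type == "population") {
    sqrt(mean((d - mean(d))^2))
  } else {
    sd(d)
  }
  s / mean(d)
}

#' Local variability index CV2
#'
#' For each pair of consecutive intervals the statistic
#' `2 |dt[n+1] - dt[n]| / (dt[n+1] + dt[n])` is computed and the values are
#' averaged over the trial.  By construction `0 <= CV2 < 2`; a periodic
#' train gives 0, a Poisson process gives 1, and only pathologically
#' alternating interval sequences approach (without reaching) 2.
#'
#' @param train a [spike_train()] with at least 3 ISIs.
#' @param pairwise return the per-pair values instead of their mean.
#' @return dimensionless CV2 in `[0, 2)` (or the per-pair vector).
#' @export
cv2 <- function(train, pairwise = FALSE) {
  require_isis(train, 3L, "CV2")
  d <- isi(train)
  n <- length(d)
  v <- 2 * abs(d[-1] - d[-n]) / (d[-1] + d[-n])
  if (pairwise) v else mean(v)
}

#' Detect spikes in a current trace
#'
#' Spike times are the local maxima of the signal inside each
#' suprathreshold excursion.  The threshold is scale-free:
#' `baseline + threshold_frac * (robust peak - baseline)` with the baseline
#' a low quantile of the samples and the robust peak the 99.5th percentile.
#' Traces whose robust amplitude does not exceed `noise_floor`
#' first-difference deviations are declared spike-free (so pure-noise input
#' yields an empty train rather than threshold chatter).  Detections closer
#' than `min_separation` are merged, keeping the taller peak.
#'
#' Two modes are available.  `"linear"` (default for current input)
#' thresholds the raw signal and suits additive-noise traces with pulses on
#' a flat baseline.  `"log"` thresholds the logarithm of the signal —
#' appropriate for the memristor conductance, which swings multiplicatively
#' over decades when the device opens; a spike must then change the
#' conductance by at least `exp(min_swing)`-fold, which rejects the
#' small-amplitude chatter of a quiescent operating point regardless of its
#' linear amplitude.
#'
#' @param trace a `tn_trace`, or any data frame with columns `t` and `I`.
#' @param threshold_frac fraction of the robust amplitude; default 0.5.
#' @param min_separation merge window; defaults to twice the trace sample
#'   interval.
#' @param signal column to detect on (default `"I"`).
#' @param noise_floor amplitude floor, in units of the high-frequency noise
#'   scale (robust standard deviation of the first difference), below which
#'   the trace is treated as spike-free; default 8.
#' @param abs_frac linear mode only: for traces produced by [simulate_neuron()]
#'   (which carry their device and circuit parameters), the robust
#'   amplitude must additionally reach `abs_frac` times the device's
#'   full-on current scale `max(V_ext) / (R_min + R_ext)`.  Ignored for
#'   plain data-frame input.  Default 0.15.
#' @param mode `"linear"` or `"log"` (see Details).  Default `"linear"`.
#' @param min_swing log mode only: minimum robust amplitude of the log
#'   signal (in e-folds) for the trace to count as spiking; default 1.5
#'   (about a 4.5-fold conductance swing).
#' @param baseline_q quantile used for the baseline; default 0.5 (median)
#'   in linear mode and 0.25 in log mode (robust against traces that spend
#'   a large fraction of the time in the open state).
#' @return a [spike_train()] over the trace's time span.
#' @export
detect_spikes <- function(trace, threshold_frac = 0.5,
                          min_separation = NULL, signal = "I",
                          noise_floor = 8, abs_frac = 0.15,
                          mode = c("linear", "log"), min_swing = 1.5,
                          baseline_q = NULL) {
  mode <- match.arg(mode)
  tt <- trace$t
  y <- trace[[signal]]
  if (is.null(tt) || is.null(y) || !length(y)) {
    stop_tn("trace must provide nonempty 't' and '%s' columns", signal,
            class = "tn_input_error")
  }
  if (any(!is.finite(y))) {
    stop_tn("trace contains non-finite samples", class = "tn_input_error")
  }
  dt_sample <- if (length(tt) > 1L) tt[2] - tt[1] else 1
  min_separation <- min_separation %||% (2 * dt_sample)
  duration <- max(tt[length(tt)], dt_sample)
  baseline_q <- baseline_q %||% (if (mode == "log") 0.25 else 0.5)
  if (mode == "log") {
    if (any(y <= 0)) {
      stop_tn("log-mode detection needs a strictly positive signal",
              class = "tn_input_error")
    }
    y <- log(y)
  }
  baseline <- quantile(y, baseline_q, names = FALSE)
  peak <- quantile(y, 0.995, names = FALSE)
  amp <- peak - baseline
  # high-frequency noise scale: for white noise sd(diff) = sqrt(2) * sd,
  # while smooth oscillations contribute little to the first difference
  scale <- max(mad(diff(y), constant = 1.4826) / sqrt(2),
               .Machine$double.eps)
  amp_floor <- 0
  if (mode == "log") {
    amp_floor <- min_swing
  } else {
    device <- attr(trace, "device")
    circuit <- attr(trace, "circuit")
    if (identical(signal, "I") && !is.null(device) && !is.null(circuit)) {
      v_peak <- if (!is.null(trace$V_ext)) max(abs(trace$V_ext)) else
        max(abs(y)) * (r_min_of(device) + circuit$R_ext)
      amp_floor <- abs_frac * v_peak / (r_min_of(device) + circuit$R_ext)
    }
  }
  if (amp <= 0 || amp < noise_floor * scale || amp < amp_floor) {
    return(spike_train(numeric(0), duration, meta = "no spikes detected"))
  }
  thr <- baseline + threshold_frac * amp
  above <- y > thr
  if (!any(above)) {
    return(spike_train(numeric(0), duration, meta = "no spikes detected"))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  times <- heights <- numeric(0)
  for (k in which(keep)) {
    seg <- starts[k]:ends[k]
    j <- seg[which.max(y[seg])]
    times <- c(times, tt[j]); heights <- c(heights, y[j])
  }
  # merge detections closer than min_separation, keeping the taller peak
  if (length(times) > 1L) {
    merged_t <- times[1]; merged_h <- heights[1]
    for (k in 2:length(times)) {
      last <- length(merged_t)
      if (times[k] - merged_t[last] < min_separation) {
        if (heights[k] > merged_h[last]) {
          merged_t[last] <- times[k]; merged_h[last] <- heights[k]
        }
      } else {
        merged_t <- c(merged_t, times[k])
        merged_h <- c(merged_h, heights[k])
      }
    }
    times <- merged_t
  }
  spike_train(times, duration, meta = sprintf("threshold %.4g", thr))
}

#' @importFrom stats mad
NULL

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-tapered, mean-removed segments with 50%
#' overlap.  The one-sided density is normalised so that
#' `sum(power) * df` approximates the trace variance (Parseval).
#'
#' @param trace a `tn_trace` or data frame with column `t` and the signal
#'   column, or a plain numeric vector (then `fs` must be given).
#' @param segment_length samples per segment (default: the largest power of
#'   two not exceeding an eighth of the trace, at least 64).
#' @param signal column to analyse when `trace` is a data frame.
#' @param fs sampling frequency, required for plain numeric input.
#' @return data frame with columns `frequency` and `power`.
#' @export
psd <- function(trace, segment_length = NULL, signal = "I", fs = NULL) {
  if (is.numeric(trace)) {
    y <- trace
    if (is.null(fs)) {
      stop_tn("'fs' is required for numeric input", class = "tn_config_error")
    }
  } else {
    y <- trace[[signal]]
    tt <- trace$t
    fs <- 1 / (tt[2] - tt[1])
  }
  n <- length(y)
  if (is.null(segment_length)) {
    segment_length <- max(64L, 2^floor(log2(n / 8)))
  }
  segment_length <- as.integer(segment_length)
  if (segment_length > n) {
    stop_tn("segment_length (%d) exceeds trace length (%d)",
            segment_length, n, class = "tn_config_error")
  }
  step <- max(1L, segment_length %/% 2L)
  starts <- seq(1L, n - segment_length + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(segment_length) / (segment_length + 1)))
  scale <- 1 / (fs * sum(w^2))
  nfreq <- segment_length %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- y[s:(s + segment_length - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2 * scale
    acc <- acc + sp[seq_len(nfreq)]
  }
  p <- acc / length(starts)
  # fold to a one-sided density
  if (segment_length %% 2L == 0L) {
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
  } else {
    p[2:nfreq] <- 2 * p[2:nfreq]
  }
  data.frame(frequency = (seq_len(nfreq) - 1L) * fs / segment_length,
             power = p)
}

#' Two-dimensional ISI histogram across stimulus periods
#'
#' For each stimulus period `t_p`, the distribution of inter-spike intervals
#' is histogrammed on a common (logarithmic) ISI grid and column-normalised
#' to unit mass; the per-period mode (most probable ISI) summarises the
#' neuron's temporal receptive field.  Perfect frequency selectivity puts
#' the mode on the identity line `ISI = t_p`.
#'
#' @param trains named or unnamed list of [spike_train()]s, one per period.
#' @param t_p numeric vector of stimulus periods, parallel to `trains`.
#' @param n_bins number of logarithmic ISI bins (default 48).
#' @param isi_range optional `c(min, max)` ISI range; defaults to the pooled
#'   ISI range.
#' @return list with `map` (matrix `n_bins x length(t_p)` of column
#'   densities), `isi_mid` (bin mid-points), `t_p`, and `mode` (data frame
#'   `t_p`, `isi_mode`; `NA` where a column is empty).
#' @export
isi_histogram_2d <- function(trains, t_p, n_bins = 48L, isi_range = NULL) {
  stopifnot(length(trains) == length(t_p), length(t_p) >= 2L)
  isis <- lapply(trains, function(tr) isi(tr))
  pooled <- unlist(isis)
  if (!length(pooled)) {
    stop_tn("no inter-spike intervals in any train", class = "tn_input_error")
  }
  if (is.null(isi_range)) {
    isi_range <- range(pooled[pooled > 0])
  }
  edges <- exp(seq(log(isi_range[1] * 0.999), log(isi_range[2] * 1.001),
                   length.out = n_bins + 1L))
  mids <- sqrt(edges[-1] * edges[-length(edges)])
  map <- matrix(0, nrow = n_bins, ncol = length(t_p))
  mode_isi <- rep(NA_real_, length(t_p))
  for (j in seq_along(t_p)) {
    d <- isis[[j]]
    d <- d[d >= edges[1] & d <= edges[n_bins + 1L]]
    if (!length(d)) next
    counts <- tabulate(findInterval(d, edges, rightmost.closed = TRUE),
                       nbins = n_bins)
    map[, j] <- counts / sum(counts)
    mode_isi[j] <- mids[which.max(counts)]
  }
  list(map = map, isi_mid = mids, t_p = t_p,
       mode = data.frame(t_p = t_p, isi_mode = mode_isi))
}

#' Firing rate versus stimulus period and the preferred period
#'
#' Computes the firing rate (spike count / duration) for each condition of
#' a selectivity experiment and locates the preferred period `t_p*` — the
#' period of maximal rate — by quadratic interpolation through the discrete
#' argmax and its neighbours.
#'
#' @param rates data frame with columns `t_p`, `rate`, and optionally a
#'   grouping column (e.g. `V_AC`); or build it from `trains` + `t_p`.
#' @param trains optional list of [spike_train()]s used with `t_p` (and
#'   `group`) to build the rate table.
#' @param t_p,group condition descriptors parallel to `trains`.
#' @return list with `rates` (the tidy rate table) and `preferred` (data
#'   frame of `group`, `t_p_star`, `rate_max`).
#' @export
rate_vs_period <- function(rates = NULL, trains = NULL, t_p = NULL,
                           group = NULL) {
  if (is.null(rates)) {
    stopifnot(!is.null(trains), !is.null(t_p))
    rates <- data.frame(
      t_p = t_p,
      rate = vapply(trains, function(tr) {
        length(tr$timestamps) / tr$duration
      }, numeric(1)))
    if (!is.null(group)) rates$group <- group
  }
  if (!"group" %in% names(rates)) {
    gcol <- setdiff(names(rates), c("t_p", "rate"))
    rates$group <- if (length(gcol)) rates[[gcol[1]]] else "all"
  }
  pref <- do.call(rbind, lapply(split(rates, rates$group), function(df) {
    df <- df[order(df$t_p), ]
    if (all(df$rate <= 0)) {
      return(data.frame(group = df$group[1], t_p_star = NA_real_,
                        rate_max = 0, flagged = TRUE))
    }
    data.frame(group = df$group[1],
               t_p_star = preferred_period(df$t_p, df$rate),
               rate_max = max(df$rate), flagged = FALSE)
  }))
  rownames(pref) <- NULL
  list(rates = rates, preferred = pref)
}

#' @rdname rate_vs_period
#' @export
preferred_period <- function(t_p, rate) {
  stopifnot(length(t_p) == length(rate), length(t_p) >= 1L)
  o <- order(t_p)
  t_p <- t_p[o]; rate <- rate[o]
  i <- which.max(rate)
  if (i == 1L || i == length(rate)) return(t_p[i])
  # three-point parabola through the argmax
  x <- t_p[(i - 1L):(i + 1L)]
  y <- rate[(i - 1L):(i + 1L)]
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
        x[1] * (y[3] - y[2])) / denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
        x[1]^2 * (y[2] - y[3])) / denom
  if (a >= 0) return(t_p[i])
  xs <- -b / (2 * a)
  min(max(xs, x[1]), x[3])
}

#' CV1/CV2 colour map over a parameter sweep
#'
#' Pivots a tidy CV table (one row per condition, as produced by
#' [run_cv_cloud()]) into matrices over the `(R_ext, V_ext)` grid; cells
#' with fewer than `n_min` ISIs are masked (`NA`).
#'
#' @param cv_table data frame with columns `V_ext`, `R_ext`, `cv1`, `cv2`,
#'   `n_isi`.
#' @param n_min minimum ISI count per cell; default 3.
#' @return list with `V_ext`, `R_ext`, and matrices `cv1`, `cv2`, `n_isi`
#'   (rows = `R_ext`, columns = `V_ext`).
#' @export
cv_map <- function(cv_table, n_min = 3L) {
  need <- setdiff(c("V_ext", "R_ext", "cv1", "cv2", "n_isi"),
                  names(cv_table))
  if (length(need)) {
    stop_tn("cv_table lacks column(s): %s", paste(need, collapse = ", "),
            class = "tn_format_error")
  }
  vg <- sort(unique(cv_table$V_ext))
  rg <- sort(unique(cv_table$R_ext))
  m <- function(field) {
    out <- matrix(NA_real_, nrow = length(rg), ncol = length(vg),
                  dimnames = list(format(rg), format(vg)))
    for (k in seq_len(nrow(cv_table))) {
      i <- match(cv_table$R_ext[k], rg)
      j <- match(cv_table$V_ext[k], vg)
      v <- cv_table[[field]][k]
      out[i, j] <- if (is.na(out[i, j])) v else mean(c(out[i, j], v))
    }
    out
  }
  cv1m <- m("cv1"); cv2m <- m("cv2"); nm <- m("n_isi")
  mask <- !is.na(nm) & nm < n_min
  cv1m[mask] <- NA; cv2m[mask] <- NA
  list(V_ext = vg, R_ext = rg, cv1 = cv1m, cv2 = cv2m, n_isi = nm)
}

#' Convex-hull coverage of a reference point cloud
#'
#' Fraction of `reference` points lying inside (or on) the convex hull of
#' `cloud`.  Used to quantify how much of a biological (CV1, CV2) cloud the
#' artificial neuron's operating points span.
#'
#' @param reference two-column matrix or data frame of points to test.
#' @param cloud two-column matrix or data frame (>= 3 non-collinear points)
#'   whose convex hull is taken.
#' @return fraction in `[0, 1]`.
#' @export
hull_coverage <- function(reference, cloud) {
  reference <- as.matrix(reference)[, 1:2, drop = FALSE]
  cloud <- as.matrix(cloud)[, 1:2, drop = FALSE]
  if (nrow(cloud) < 3L) {
    stop_tn("cloud needs at least 3 points", class = "tn_degenerate_hull")
  }
  hull_idx <- grDevices::chull(cloud)
  if (length(hull_idx) < 3L) {
    stop_tn("cloud points are collinear; convex hull is degenerate",
            class = "tn_degenerate_hull")
  }
  hull <- cloud[hull_idx, , drop = FALSE]
  # expand the hull infinitesimally about its centroid so points exactly on
  # the boundary count as covered
  centre <- colMeans(hull)
  hull_eps <- sweep(sweep(hull, 2, centre, "-") * (1 + 1e-9), 2, centre, "+")
  inside <- mgcv::in.out(rbind(hull_eps, hull_eps[1, ]), reference)
  mean(inside)
}

#' Burst segmentation of a spike train
#'
#' Maximal runs of inter-spike intervals below `isi_threshold` form bursts;
#' the intervals at or above the threshold are the quiet inter-train
#' intervals separating them.  Isolated spikes count as bursts of one.
#'
#' @param train a [spike_train()] with at least 2 spikes.
#' @param isi_threshold interval separating within-burst from between-burst
#'   gaps (same time units as the train).
#' @return list with `bursts` (data frame `start`, `end`, `n_spikes`) and
#'   `inter_train_intervals` (numeric vector of quiet gaps).
#' @export
segment_bursts <- function(train, isi_threshold) {
  stopifnot(inherits(train, "tn_spike_train"))
  ts <- train$timestamps
  if (length(ts) < 2L) {
    stop_tn("burst segmentation needs at least 2 spikes",
            class = "tn_insufficient_data")
  }
  check_positive(isi_threshold, "isi_threshold")
  gaps <- diff(ts)
  breaks <- which(gaps >= isi_threshold)
  start_idx <- c(1L, breaks + 1L)
  end_idx <- c(breaks, length(ts))
  bursts <- data.frame(start = ts[start_idx], end = ts[end_idx],
                       n_spikes = end_idx - start_idx + 1L)
  list(bursts = bursts, inter_train_intervals = gaps[breaks])
}

#' Read and write spike-train CSV files
#'
#' One spike per row under a single `timestamp` header (times in the
#' package's time units, or seconds for externally recorded trains).  The
#' reader validates strict monotonicity.
#'
#' @param train a [spike_train()].
#' @param path CSV path.
#' @param duration observation window for `read_spike_train()`; defaults to
#'   the last timestamp.
#' @return `read_spike_train()` returns a [spike_train()].
#' @export
write_spike_train <- function(train, path) {
  utils::write.csv(data.frame(timestamp = train$timestamps), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path, duration = NULL) {
  df <- utils::read.csv(path)
  if (!"timestamp" %in% names(df)) {
    stop_tn("spike CSV must have a 'timestamp' column",
            class = "tn_format_error")
  }
  ts <- df$timestamp
  if (is.unsorted(ts, strictly = TRUE)) {
    stop_tn("timestamps in '%s' are not strictly increasing", path,
            class = "tn_format_error")
  }
  spike_train(ts, duration %||% max(ts), meta = path)
}
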