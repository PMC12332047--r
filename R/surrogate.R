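#' Surrogate spike-train generators
#'
#' Seeded generators for spike-train classes with known statistics, used to
#' validate the analysis stack without any recorded data: `periodic`
#' (CV1 = CV2 = 0), `poisson` (CV1 = CV2 = 1), `gamma_renewal`
#' (CV1 = 1/sqrt(shape)), `jittered_periodic` (period plus Gaussian
#' timestamp jitter), `two_state_bursting` (a two-state Markov-modulated
#' Poisson process alternating high-rate bursts with silent epochs), and
#' `alternating_isi` (deterministically alternating interval pair — the
#' adversarial case that pushes CV2 toward its supremum of 2).
#'
#' @param kind surrogate class (see above).
#' @param duration observation window (> 0); the train is truncated to it.
#' @param seed RNG seed; generators are pure functions of (spec, seed).
#' @param rate mean firing rate (poisson, gamma_renewal, and the in-burst
#'   rate of `two_state_bursting`).
#' @param period spike period (periodic, jittered_periodic).
#' @param shape gamma shape parameter (gamma_renewal).
#' @param jitter_sd timestamp jitter standard deviation
#'   (jittered_periodic).
#' @param burst_mean,quiet_mean mean dwell times of the bursting and silent
#'   states (two_state_bursting; exponential dwells).
#' @param isi_pair the two alternating intervals (alternating_isi).
#' @return a [spike_train()].
#' @export
generate_train <- function(kind = c("periodic", "poisson", "gamma_renewal",
                                    "jittered_periodic",
                                    "two_state_bursting",
                                    "alternating_isi"),
                           duration, seed = 1L, rate = 1, period = 1,
                           shape = 1, jitter_sd = 0.05, burst_mean = 5,
                           quiet_mean = 20, isi_pair = c(1, 3)) {
  kind <- match.arg(kind)
  check_positive(duration, "duration")
  set.seed(seed)
  ts <- switch(kind,
    periodic = seq(period, duration, by = period),
    poisson = {
      n <- max(10L, ceiling(duration * rate * 1.5) + 50L)
      cumsum(rexp(n, rate))
    },
    gamma_renewal = {
      check_positive(shape, "shape")
      n <- max(10L, ceiling(duration * rate * 1.5) + 50L)
      cumsum(rgamma(n, shape = shape, rate = shape * rate))
    },
    jittered_periodic = {
      base <- seq(period, duration, by = period)
      sort(base + rnorm(length(base), sd = jitter_sd))
    },
    two_state_bursting = {
      check_positive(burst_mean, "burst_mean")
      check_positive(quiet_mean, "quiet_mean")
      t0 <- 0; out <- numeric(0); bursting <- TRUE
      while (t0 < duration) {
        dwell <- rexp(1, 1 / (if (bursting) burst_mean else quiet_mean))
        if (bursting && dwell > 0) {
          n <- rpois(1, rate * dwell)
          if (n > 0) out <- c(out, t0 + sort(runif(n, 0, dwell)))
        }
        t0 <- t0 + dwell
        bursting <- !bursting
      }
      out
    },
    alternating_isi = {
      check_positive(isi_pair[1], "isi_pair[1]")
      check_positive(isi_pair[2], "isi_pair[2]")
      n <- ceiling(2 * duration / sum(isi_pair)) * 2L + 2L
      cumsum(rep(isi_pair, length.out = n))
    })
  ts <- ts[ts > 0 & ts <= duration]
  ts <- ts[!duplicated(ts)]
  if (length(ts) < 3L) {
    warning("surrogate parameters yield fewer than 3 expected spikes; ",
            "returning best-effort train")
  }
  spike_train(ts, duration, meta = paste0("surrogate:", kind))
}

#' Synthetic current trace with known spike times
#'
#' Builds a baseline current trace carrying stereotyped Gaussian-shaped
#' pulses at prescribed times plus additive white noise; returns both the
#' trace and the ground-truth train so spike detectors can be validated for
#' recall and precision.
#'
#' @param spike_times sorted spike times; successive times must be more
#'   than `3 * pulse_width` apart so the fixture is unambiguous.
#' @param duration trace length.
#' @param dt sample interval.
#' @param amplitude pulse height above baseline.
#' @param pulse_width Gaussian pulse standard deviation.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param baseline constant offset.
#' @param seed RNG seed for the noise.
#' @return list with `trace` (data frame `t`, `I`) and `truth` (a
#'   [spike_train()]).
#' @export
generate_trace_with_spikes <- function(spike_times, duration, dt = 0.01,
                                       amplitude = 1, pulse_width = 0.05,
                                       noise_sd = 0, baseline = 0,
                                       seed = 1L) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = TRUE) &&
      length(spike_times) > 1L) {
    stop_tn("spike_times must be sorted strictly increasing",
            class = "tn_input_error")
  }
  if (length(spike_times) > 1L &&
      any(diff(spike_times) <= 3 * pulse_width)) {
    stop_tn("spike pulses overlap (separation <= 3 * pulse_width)",
            class = "tn_input_error")
  }
  tt <- seq(0, duration, by = dt)
  y <- rep(baseline, length(tt))
  for (s in spike_times) {
    y <- y + amplitude * exp(-(tt - s)^2 / (2 * pulse_width^2))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(tt), sd = noise_sd)
  }
  list(trace = data.frame(t = tt, I = y),
       truth = spike_train(spike_times, duration, meta = "ground truth"))
}

#' Synthetic (CV1, CV2) cloud around requested centroids
#'
#' Emulates a biological CV scatter by mixing surrogate classes whose
#' realised statistics land near the requested centroids: periodic trains
#' near the origin, gamma-renewal trains for sub-Poisson targets
#' (shape = 1/CV1^2), Poisson near (1, 1), and bursting trains for
#' super-Poisson CV1.  Realised CV1/CV2 are recomputed from the generated
#' trains, never copied from the request.
#'
#' @param centroids data frame with columns `cv1`, `cv2`; each centroid must
#'   satisfy `cv1 >= 0`, `0 <= cv2 < 2`.
#' @param n points per centroid.
#' @param dispersion relative parameter jitter between points (default
#'   0.15).
#' @param n_spikes target spike count per train (default 400).
#' @param seed base RNG seed.
#' @return data frame with columns `cv1`, `cv2`, `n_isi`, `condition`
#'   (centroid index), `kind`.
#' @export
generate_cv_cloud <- function(centroids, n = 20L, dispersion = 0.15,
                              n_spikes = 400L, seed = 1L) {
  centroids <- as.data.frame(centroids)
  if (!all(c("cv1", "cv2") %in% names(centroids))) {
    stop_tn("centroids need 'cv1' and 'cv2' columns",
            class = "tn_spec_error")
  }
  if (any(centroids$cv1 < 0) || any(centroids$cv2 < 0) ||
      any(centroids$cv2 >= 2)) {
    stop_tn("centroids must satisfy cv1 >= 0 and 0 <= cv2 < 2",
            class = "tn_spec_error")
  }
  rows <- list()
  idx <- 0L
  for (ci in seq_len(nrow(centroids))) {
    c1 <- centroids$cv1[ci]
    for (j in seq_len(n)) {
      idx <- idx + 1L
      sj <- seed + 1000L * ci + j
      set.seed(sj)
      wobble <- exp(rnorm(1, sd = dispersion))
      duration <- n_spikes # rate-1 trains
      tr <- if (c1 < 0.05) {
        generate_train("periodic", duration = duration, seed = sj,
                       period = 1)
      } else if (c1 < 0.95) {
        generate_train("gamma_renewal", duration = duration, seed = sj,
                       rate = 1, shape = max(1, 1 / (c1 * wobble)^2))
      } else if (c1 <= 1.05) {
        generate_train("poisson", duration = duration, seed = sj, rate = 1)
      } else {
        generate_train("two_state_bursting", duration = duration * 2,
                       seed = sj, rate = 4 * c1 * wobble,
                       burst_mean = 2, quiet_mean = 2 * c1 * wobble)
      }
      if (length(tr$timestamps) < 4L) next
      rows[[idx]] <- data.frame(cv1 = cv1(tr), cv2 = cv2(tr),
                                n_isi = length(tr$timestamps) - 1L,
                                condition = ci, kind = tr$meta)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @importFrom stats rpois
NULL
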