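#' Burst detection by the cumulative moving average of the ISI histogram
#'
#' Detects bursts in a single spike train with the CMA-family procedure:
#' \enumerate{
#'   \item build the interspike-interval (ISI) histogram,
#'   \item compute the cumulative moving average (CMA) of the histogram
#'     counts and locate its maximum,
#'   \item pick the burst ISI threshold as the first histogram bin beyond the
#'     maximum where the CMA has fallen to `alpha1 * max(CMA)`, with `alpha1`
#'     selected from the skewness of the CMA curve via a lookup table,
#'   \item group runs of consecutive spikes whose ISIs do not exceed the
#'     threshold; runs with at least `min_spikes` spikes are bursts.
#' }
#'
#' The default skewness-to-`alpha1` lookup (`< 1` gives 1, `1-4` gives 0.7,
#' `4-9` gives 0.5, `>= 9` gives 0.3) and the histogram bin width are
#' configurable, since variants of the procedure differ in these choices.
#'
#' @param spike_times sorted numeric spike times (s).
#' @param bin_width ISI histogram bin width (s); defaults to the 5 ms
#'   simulation bin.
#' @param skew_breaks increasing skewness break points of the lookup.
#' @param alpha1_values `alpha1` values, one more than `length(skew_breaks)`.
#' @param min_spikes minimum spikes per burst.
#' @return data.frame with one row per burst: `start`, `end` (s),
#'   `n_spikes`, `duration` (s). Zero rows when fewer than `min_spikes`
#'   spikes exist.
#' @export
#' @examples
#' train <- c(seq(0, 0.09, by = 0.01), 5 + seq(0, 0.09, by = 0.01))
#' detect_bursts_cma(train)
detect_bursts_cma <- function(spike_times, bin_width = 0.005,
                              skew_breaks = c(1, 4, 9),
                              alpha1_values = c(1, 0.7, 0.5, 0.3),
                              min_spikes = 3) {
  stopifnot(length(alpha1_values) == length(skew_breaks) + 1,
            !is.unsorted(skew_breaks), bin_width > 0, min_spikes >= 2)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), duration = numeric(0))
  if (length(spike_times) < min_spikes) return(empty)
  spike_times <- sort(spike_times)
  isi <- diff(spike_times)
  if (all(isi == 0)) return(empty)
  breaks <- seq(0, max(isi) + bin_width, by = bin_width)
  h <- graphics::hist(isi, breaks = breaks, plot = FALSE)$counts
  cma <- cumsum(h) / seq_along(h)
  m <- which.max(cma)
  skew <- e1071::skewness(cma, type = 2)
  if (!is.finite(skew)) skew <- 0
  alpha1 <- alpha1_values[findInterval(skew, skew_breaks) + 1L]
  beyond <- which(cma <= alpha1 * cma[m])
  beyond <- beyond[beyond >= m]
  cut_bin <- if (length(beyond)) beyond[1L] else length(cma)
  threshold <- breaks[cut_bin + 1L]   # right edge of the cut bin
  in_burst <- isi <= threshold
  runs <- rle(in_burst)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= (min_spikes - 1L)
  if (!any(keep)) return(empty)
  burst_start <- spike_times[starts[keep]]
  burst_end <- spike_times[ends[keep] + 1L]
  data.frame(start = burst_start, end = burst_end,
             n_spikes = as.integer(runs$lengths[keep] + 1L),
             duration = burst_end - burst_start)
}

#' Spike and burst features of a recording
#'
#' Applies [detect_bursts_cma()] to every neuron's spike train and summarizes
#' the recording: the mean spike rate (spikes/min per neuron), mean burst
#' rate (bursts/min per neuron), mean spikes per burst and mean burst
#' duration in milliseconds (both over all detected bursts; 0 when no bursts
#' were found).
#'
#' @param trains list of spike-time vectors, one per neuron (see
#'   [spike_trains()]).
#' @param T_total recording duration (s).
#' @param ... passed to [detect_bursts_cma()].
#' @return Object of class `burst_features`: named list with `spike_rate`,
#'   `burst_rate`, `spikes_per_burst`, `burst_duration_ms`, `n_bursts`.
#' @export
burst_features <- function(trains, T_total, ...) {
  stopifnot(T_total > 0)
  bursts <- lapply(trains, detect_bursts_cma, ...)
  n_bursts <- sum(vapply(bursts, nrow, integer(1)))
  all_counts <- unlist(lapply(bursts, `[[`, "n_spikes"))
  all_dur <- unlist(lapply(bursts, `[[`, "duration"))
  structure(list(
    spike_rate = 60 * mean(lengths(trains)) / T_total,
    burst_rate = 60 * mean(vapply(bursts, nrow, integer(1))) / T_total,
    spikes_per_burst = if (n_bursts) mean(all_counts) else 0,
    burst_duration_ms = if (n_bursts) 1000 * mean(all_dur) else 0,
    n_bursts = n_bursts), class = "burst_features")
}

#' @export
print.burst_features <- function(x, ...) {
  cat(sprintf(paste0("spike rate %.2f /min, burst rate %.2f /min, ",
                     "%.2f spikes/burst, duration %.1f ms (%d bursts)\n"),
              x$spike_rate, x$burst_rate, x$spikes_per_burst,
              x$burst_duration_ms, x$n_bursts))
  invisible(x)
}

# Border-corrected Gaussian (Nadaraya-Watson) smoothing on a regular grid:
# the convolution of the data with the kernel is divided by the convolution
# of the observation-window indicator, so a constant input is reproduced
# exactly up to the borders.
gaussian_smooth <- function(values, grid_step, sigma, radius_sd = 4) {
  n <- length(values)
  half <- min(n - 1L, ceiling(radius_sd * sigma / grid_step))
  kern <- exp(-((-half:half) * grid_step)^2 / (2 * sigma^2))
  num <- stats::convolve(values, rev(kern), type = "open")
  den <- stats::convolve(rep(1, n), rev(kern), type = "open")
  idx <- half + seq_len(n)
  num[idx] / den[idx]
}

#' Smooth a pooled activity series with a border-corrected Gaussian kernel
#'
#' Gaussian smoothing of a regularly sampled activity series, normalized by
#' the smoothed observation-window indicator so that borders are corrected: a
#' constant series is returned unchanged, including at the edges. The
#' operation is linear and positivity-preserving.
#'
#' @param series numeric series on the simulation time grid.
#' @param dt grid step (s).
#' @param rho Gaussian kernel width (s).
#' @return Smoothed series of the same length.
#' @export
smooth_activity <- function(series, dt = 0.005, rho = 3) {
  stopifnot(dt > 0, rho > 0)
  gaussian_smooth(series, dt, rho)
}

#' Averaged, smoothed spectrum of pooled network activity
#'
#' For each run, the pooled per-bin spike count is centred by subtracting its
#' mean and transformed with a discrete Fourier transform; the moduli of the
#' positive-frequency coefficients are averaged across runs and smoothed with
#' a border-corrected Gaussian kernel on the frequency axis. Band averages
#' over 0.01-0.1 Hz and 1-10 Hz summarize the slow and fast activity
#' components.
#'
#' @param pooled_runs a numeric vector (one run) or list of vectors (runs) of
#'   pooled per-bin spike counts.
#' @param dt bin width (s).
#' @param sigma Gaussian smoothing width on the frequency axis (Hz).
#' @param band_low,band_high numeric length-2 frequency bands (Hz).
#' @return Object of class `spectrum_result`: `freq` (Hz), `raw` (run-mean
#'   DFT moduli), `smoothed`, `band_low_avg`, `band_high_avg`, `band_ratio`.
#' @export
pooled_spectrum <- function(pooled_runs, dt = 0.005, sigma = 0.025,
                            band_low = c(0.01, 0.1),
                            band_high = c(1, 10)) {
  if (!is.list(pooled_runs)) pooled_runs <- list(pooled_runs)
  stopifnot(length(pooled_runs) >= 1, dt > 0, sigma > 0)
  n <- length(pooled_runs[[1L]])
  stopifnot(all(lengths(pooled_runs) == n), n >= 4)
  n_pos <- floor(n / 2)
  freq <- (seq_len(n_pos)) / (n * dt)
  moduli <- vapply(pooled_runs, function(x) {
    Mod(fft(x - mean(x)))[1L + seq_len(n_pos)]
  }, numeric(n_pos))
  raw <- rowMeans(moduli)
  smoothed <- gaussian_smooth(raw, grid_step = freq[2L] - freq[1L],
                              sigma = sigma)
  in_band <- function(band) freq >= band[1L] & freq <= band[2L]
  if (!any(in_band(band_low)) || !any(in_band(band_high)))
    stop("a frequency band lies outside the resolved spectrum")
  low_avg <- mean(smoothed[in_band(band_low)])
  high_avg <- mean(smoothed[in_band(band_high)])
  structure(list(freq = freq, raw = raw, smoothed = smoothed,
                 band_low = band_low, band_high = band_high,
                 band_low_avg = low_avg, band_high_avg = high_avg,
                 band_ratio = high_avg / low_avg),
            class = "spectrum_result")
}

#' Ratio of fast-band to slow-band spectral averages
#'
#' @param spectrum a `spectrum_result` from [pooled_spectrum()].
#' @return The 1-10 Hz band average divided by the 0.01-0.1 Hz band average.
#' @export
band_ratio <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum_result"))
  spectrum$band_ratio
}

#' Normalized cross-correlation between two activity series
#'
#' Sample cross-correlation between a (typically smoothed) pooled neuronal
#' series and astrocytic series over a symmetric lag window. Positive lags
#' mean the second series follows the first: `r(k)` is the correlation of
#' `y` at time `t + k` with `x` at time `t`.
#'
#' @param x,y equal-length numeric series on the time grid.
#' @param dt grid step (s).
#' @param max_lag maximum absolute lag (s).
#' @return data.frame with `lag` (s) and `r` in \[-1, 1\].
#' @export
#' @examples
#' t <- seq(0, 20, by = 0.01)
#' x <- sin(t)
#' cross_correlation(x, x, dt = 0.01, max_lag = 2)[201, ]  # lag 0, r = 1
cross_correlation <- function(x, y, dt = 0.005, max_lag = 30) {
  stopifnot(length(x) == length(y), dt > 0, max_lag > 0)
  lag_bins <- min(length(x) - 1L, round(max_lag / dt))
  cc <- stats::ccf(y, x, lag.max = lag_bins, plot = FALSE, demean = TRUE)
  data.frame(lag = as.vector(cc$lag) * dt, r = as.vector(cc$acf))
}

#' Run-averaged neuron-astrocyte cross-correlation
#'
#' Smooths the pooled neuronal spike-count series and the active-astrocyte
#' count series of each run with the border-corrected Gaussian kernel
#' ([smooth_activity()]), computes their normalized cross-correlation and
#' averages the correlation curves across runs. Positive lags mean the
#' astrocytic activity follows the neuronal activity.
#'
#' @param experiment an `inexa_experiment` (or list of `inexa_result`).
#' @param rho smoothing kernel width (s).
#' @param max_lag maximum absolute lag (s).
#' @return data.frame with `lag` (s) and run-averaged `r`.
#' @export
xcorr_neuron_astro <- function(experiment, rho = 3, max_lag = 30) {
  results <- if (inherits(experiment, "inexa_experiment"))
    experiment$results else experiment
  stopifnot(length(results) >= 1)
  curves <- lapply(results, function(res) {
    stopifnot(inherits(res, "inexa_result"))
    if (res$n_astrocytes == 0)
      stop("cross-correlation requires an astrocytic scenario")
    ns <- smooth_activity(res$pooled, res$dt, rho)
    as <- smooth_activity(res$astro_active, res$dt, rho)
    cross_correlation(ns, as, dt = res$dt, max_lag = max_lag)
  })
  out <- curves[[1L]]
  out$r <- rowMeans(vapply(curves, `[[`, numeric(nrow(out)), "r"))
  out
}

#' Astrocyte activation ratio
#'
#' The time-averaged fraction of active astrocytes, normalized by the highest
#' fraction that continuous U -> A -> R cycling can sustain. With activation
#' gated at `dt / tau_A`, deactivation at `dt / tau_R` and recovery at
#' `dt / tau_U`, the mean dwell times of the three states are `tau_A` (wait
#' in U), `tau_R` (active) and `tau_U` (refractory), so continuous cycling
#' spends the fraction `tau_R / (tau_A + tau_R + tau_U)` of the time active:
#' `AR = (mean(B) / n_A) * (tau_A + tau_R + tau_U) / tau_R`, equal to 1 at
#' the cycling limit.
#'
#' @param active_count per-bin active-astrocyte count series.
#' @param n_A total number of astrocytes (> 0).
#' @param tau_A,tau_R,tau_U state time constants (s).
#' @return Activation ratio in \[0, 1\].
#' @export
activation_ratio <- function(active_count, n_A, tau_A = 1.5, tau_R = 7.0,
                             tau_U = 5.0) {
  if (n_A <= 0) stop("n_A must be positive")
  stopifnot(all(active_count >= 0), all(active_count <= n_A))
  (mean(active_count) / n_A) * (tau_A + tau_R + tau_U) / tau_R
}

#' Full analysis report for an experiment
#'
#' Convenience wrapper computing burst features (averaged across runs), the
#' run-averaged smoothed spectrum with band averages, and, for astrocytic
#' scenarios, the run-averaged neuron-astrocyte cross-correlation and the
#' mean activation ratio.
#'
#' @param experiment an `inexa_experiment`.
#' @param rho,max_lag cross-correlation settings, see
#'   [xcorr_neuron_astro()].
#' @param ... passed to [detect_bursts_cma()].
#' @return Named list with `bursts`, `spectrum`, and (when astrocytes are
#'   present) `xcorr` and `activation_ratio`.
#' @export
analyze_experiment <- function(experiment, rho = 3, max_lag = 30, ...) {
  stopifnot(inherits(experiment, "inexa_experiment"))
  results <- experiment$results
  feats <- lapply(results, function(res)
    burst_features(spike_trains(res), res$T_total, ...))
  bursts <- structure(list(
    spike_rate = mean(vapply(feats, `[[`, numeric(1), "spike_rate")),
    burst_rate = mean(vapply(feats, `[[`, numeric(1), "burst_rate")),
    spikes_per_burst = mean(vapply(feats, `[[`, numeric(1),
                                   "spikes_per_burst")),
    burst_duration_ms = mean(vapply(feats, `[[`, numeric(1),
                                    "burst_duration_ms")),
    n_bursts = sum(vapply(feats, `[[`, integer(1), "n_bursts"))),
    class = "burst_features")
  out <- list(
    bursts = bursts,
    spectrum = pooled_spectrum(lapply(results, `[[`, "pooled"),
                               dt = results[[1L]]$dt))
  if (experiment$config$n_astrocytes > 0) {
    out$xcorr <- xcorr_neuron_astro(experiment, rho = rho,
                                    max_lag = max_lag)
    uar <- experiment$config$params$uar
    out$activation_ratio <- mean(vapply(results, function(res)
      activation_ratio(res$astro_active, res$n_astrocytes,
                       uar$tau_A, uar$tau_R, uar$tau_U), numeric(1)))
  }
  out
}
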