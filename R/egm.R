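# deflection template: w(tau) = -A tau exp(-tau^2 / (2 sigma^2)), scaled to
# the requested peak-to-peak amplitude; its steepest negative slope is at
# tau = 0, which is where the local activation time is marked
deflection_waveform <- function(tau_ms, pp_mv = 1, sigma_ms = 2) {
  A <- pp_mv / (2 * sigma_ms * exp(-0.5))
  -A * tau_ms * exp(-tau_ms^2 / (2 * sigma_ms^2))
}

# synthetic QRST far-field shape on tau in [-100, +500] ms around the
# ventricular fiducial: biphasic QRS (derivative-of-Gaussian, sigma 12 ms)
# plus a positive T wave (Gaussian, sigma 35 ms, centered +300 ms); unit
# peak-to-peak QRS
qrst_waveform <- function(tau_ms, qrs_sigma_ms = 12, t_center_ms = 300,
                          t_sigma_ms = 35, t_amp = 0.3) {
  qrs <- deflection_waveform(tau_ms, pp_mv = 1, sigma_ms = qrs_sigma_ms)
  tw <- t_amp * exp(-(tau_ms - t_center_ms)^2 / (2 * t_sigma_ms^2))
  qrs + tw
}

# first-order acquisition filters of the mapping hardware: 0.56 Hz high-pass
# followed by 408 Hz low-pass (bilinear-transform butterworth order 1)
apply_acquisition_filters <- function(x, fs_hz, hp_hz = 0.56, lp_hz = 408) {
  hp <- signal::butter(1, hp_hz / (fs_hz / 2), type = "high")
  lp <- signal::butter(1, min(lp_hz / (fs_hz / 2), 0.999), type = "low")
  as.numeric(signal::filter(lp, signal::filter(hp, x)))
}

#' Synthesize unipolar electrograms from an activation series
#'
#' Renders each activation as a biphasic deflection
#' (derivative-of-Gaussian, default 1 mV peak-to-peak, sigma 2 ms) centered
#' at its activation time, adds an identical ventricular far-field QRST
#' waveform to all channels at regular beat times, emits a clean ventricular
#' reference channel as the last row, optionally applies the first-order
#' 0.56 Hz high-pass / 408 Hz low-pass acquisition filters, and adds
#' seeded Gaussian noise. Deflections overlapping closer than the template
#' support are summed and flagged in the truth attribute.
#'
#' @param series An `activation_series`.
#' @param grid The `electrode_grid`.
#' @param fs_hz Sampling rate (default 1039 Hz).
#' @param deflection List `pp_mv, sigma_ms` of the atrial deflection.
#' @param farfield List `rr_ms` (ventricular beat interval, default 1200 ms
#'   — an anesthetized-horse rate), `amplitude_mv` (far-field size on the
#'   atrial channels), `first_beat_ms`. Set `amplitude_mv = 0` for
#'   far-field-free signals.
#' @param noise_sd_mv Additive Gaussian noise SD, mV.
#' @param filters Apply the acquisition filters (`TRUE`/`FALSE`).
#' @param seed Seed for the noise generator.
#' @param duration_ms Recording length; default the series window end plus
#'   50 ms.
#' @param ref_amplitude_mv QRST amplitude on the reference channel.
#' @return An `egm_recording` whose last channel is the ventricular
#'   reference; `attr(, "truth")` holds the beat times, the event table with
#'   an `overlapped` flag, and the synthesis parameters.
#' @export
synthesize_egms <- function(series, grid, fs_hz = 1039,
                            deflection = list(pp_mv = 1, sigma_ms = 2),
                            farfield = list(rr_ms = 1200, amplitude_mv = 0.5,
                                            first_beat_ms = 400),
                            noise_sd_mv = 0, filters = FALSE, seed = NULL,
                            duration_ms = NULL, ref_amplitude_mv = 1) {
  stopifnot(fs_hz > 0)
  sigma <- deflection$sigma_ms
  if (fs_hz < 2 * 1000 / sigma)
    stop("sampling rate too low for the deflection bandwidth")
  if (is.null(duration_ms)) duration_ms <- series$window_ms[2] + 50
  n_samp <- ceiling(duration_ms * fs_hz / 1000)
  t_ms <- (seq_len(n_samp) - 1) / fs_hz * 1000
  n_el <- grid$n_electrodes
  sig <- matrix(0, n_el + 1L, n_samp)

  ev <- series$events
  half <- 5 * sigma
  for (r in seq_len(nrow(ev))) {
    at <- ev$at_ms[r]
    i0 <- max(1L, floor((at - half) * fs_hz / 1000) + 1L)
    i1 <- min(n_samp, ceiling((at + half) * fs_hz / 1000) + 1L)
    if (i1 < i0) next
    ix <- i0:i1
    sig[ev$electrode[r], ix] <- sig[ev$electrode[r], ix] +
      deflection_waveform(t_ms[ix] - at, deflection$pp_mv, sigma)
  }

  beat_times <- numeric(0)
  if (!is.null(farfield) && !is.null(farfield$rr_ms)) {
    fb <- if (is.null(farfield$first_beat_ms)) 400 else farfield$first_beat_ms
    beat_times <- seq(fb, duration_ms, by = farfield$rr_ms)
    ff <- numeric(n_samp)
    for (bt in beat_times) {
      i0 <- max(1L, floor((bt - 100) * fs_hz / 1000) + 1L)
      i1 <- min(n_samp, ceiling((bt + 500) * fs_hz / 1000) + 1L)
      if (i1 < i0) next
      ix <- i0:i1
      ff[ix] <- ff[ix] + qrst_waveform(t_ms[ix] - bt)
    }
    amp <- if (is.null(farfield$amplitude_mv)) 0.5 else farfield$amplitude_mv
    if (amp != 0)
      sig[seq_len(n_el), ] <- sig[seq_len(n_el), ] +
        matrix(amp * ff, n_el, n_samp, byrow = TRUE)
    sig[n_el + 1L, ] <- ref_amplitude_mv * ff
  }

  if (filters)
    for (ch in seq_len(nrow(sig)))
      sig[ch, ] <- apply_acquisition_filters(sig[ch, ], fs_hz)

  if (noise_sd_mv > 0) {
    if (!is.null(seed)) set.seed(seed)
    sig[seq_len(n_el), ] <- sig[seq_len(n_el), ] +
      rnorm(n_el * n_samp, 0, noise_sd_mv)
  }

  overlapped <- rep(FALSE, nrow(ev))
  if (nrow(ev) > 1) {
    support <- 8 * sigma
    sp <- split(seq_len(nrow(ev)), ev$electrode)
    for (ix in sp) {
      tt <- ev$at_ms[ix]
      if (length(tt) < 2) next
      close_prev <- c(FALSE, diff(tt) < support)
      close_next <- c(diff(tt) < support, FALSE)
      overlapped[ix] <- close_prev | close_next
    }
  }

  rec <- egm_recording(sig, fs_hz,
                       channel_map = c(grid$electrodes$electrode, NA),
                       reference_channel = n_el + 1L)
  attr(rec, "truth") <- list(
    beat_times_ms = beat_times,
    events = cbind(ev, overlapped = overlapped),
    params = list(fs_hz = fs_hz, deflection = deflection,
                  farfield = farfield, noise_sd_mv = noise_sd_mv,
                  filters = filters, seed = seed))
  rec
}
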