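#' Detect ventricular beats on a reference channel
#'
#' Marks one fiducial per ventricular beat at the dominant absolute
#' deflection of the reference electrogram, with a 300 ms refractory
#' (shorter inter-beat intervals are physiologically impossible).
#'
#' @param recording An `egm_recording` with a reference channel.
#' @param ref_channel Reference channel row; default the recording's
#'   `reference_channel`.
#' @param threshold_frac Detection threshold as a fraction of the channel's
#'   peak absolute amplitude.
#' @param refractory_ms Minimum inter-beat interval.
#' @return Object of class `beat_list`: list `fiducials_ms` (strictly
#'   increasing), `channel`.
#' @export
detect_ventricular_beats <- function(recording,
                                     ref_channel = recording$reference_channel,
                                     threshold_frac = 0.65,
                                     refractory_ms = 300) {
  if (is.null(ref_channel)) stop("no reference channel")
  x <- recording$signal[ref_channel, ]
  fs <- recording$sampling_rate_hz
  a <- abs(x)
  if (max(a) < 1e-9) stop("no beats: flat reference channel")
  thr <- threshold_frac * max(a)
  cand <- which(a >= thr &
                a >= c(-Inf, a[-length(a)]) & a >= c(a[-1], -Inf))
  if (!length(cand)) stop("no beats detected on reference channel")
  # greedy refractory suppression by amplitude
  cand <- cand[order(-a[cand])]
  keep <- logical(0); kept <- integer(0)
  refr_samp <- refractory_ms * fs / 1000
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= refr_samp)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  # refine each fiducial to the steepest negative slope of the QRS complex
  # (the intrinsic deflection), within +/- 25 ms of the amplitude peak
  half <- round(0.025 * fs)
  d <- diff(x)
  kept <- vapply(kept, function(i) {
    lo <- max(1L, i - half); hi <- min(length(d), i + half)
    as.integer(lo + which.min(d[lo:hi]) - 1L)
  }, integer(1))
  fid <- (kept - 1 + 0.5) / fs * 1000
  if (length(fid) < 2)
    stop("fewer than 2 beats detected; template cancellation needs >= 2")
  structure(list(fiducials_ms = fid, channel = ref_channel),
            class = "beat_list")
}

#' @export
print.beat_list <- function(x, ...) {
  cat(sprintf("<beat_list> %d beats, mean RR %.0f ms\n",
              length(x$fiducials_ms),
              if (length(x$fiducials_ms) > 1) mean(diff(x$fiducials_ms))
              else NA))
  invisible(x)
}

#' Averaged-beat QRST template cancellation
#'
#' Removes the ventricular far-field from atrial unipolar electrograms: per
#' channel, the beat-aligned average over all (fully-windowed) beats forms
#' the QRST template, which is subtracted at every beat fiducial, optionally
#' with a per-beat least-squares amplitude scale. Samples outside the beat
#' windows are left untouched (sample-exact). When the far-field waveform is
#' identical across beats (as in the synthetic generator's noise-free case)
#' the cancellation is exact up to the atrial deflections leaking into the
#' template average.
#'
#' @param recording An `egm_recording`.
#' @param beats A `beat_list`.
#' @param window_ms Template window around each fiducial, default
#'   `c(-100, 500)` (sized for the equine QT of roughly 500 ms).
#' @param per_beat_scaling Fit a least-squares amplitude factor per beat.
#' @param channels Channels to clean; default all except the reference.
#' @return A cleaned `egm_recording`. Overlapping beat windows trigger a
#'   warning; the earlier beat takes precedence on the overlap.
#' @export
cancel_qrst <- function(recording, beats, window_ms = c(-100, 500),
                        per_beat_scaling = FALSE, channels = NULL) {
  fs <- recording$sampling_rate_hz
  fid <- beats$fiducials_ms
  if (length(fid) == 0) return(recording)
  if (length(fid) < 2) stop("template cancellation needs >= 2 beats")
  if (any(diff(fid) < diff(window_ms)))
    warning("overlapping beat windows; earlier beat takes precedence")
  if (is.null(channels)) {
    channels <- seq_len(nrow(recording$signal))
    if (!is.null(recording$reference_channel))
      channels <- setdiff(channels, recording$reference_channel)
  }
  n_samp <- ncol(recording$signal)
  off <- round(window_ms[1] * fs / 1000):round(window_ms[2] * fs / 1000)
  fid_samp <- round(fid * fs / 1000) + 1L
  full <- fid_samp + off[1] >= 1L & fid_samp + off[length(off)] <= n_samp
  if (sum(full) < 2) stop("fewer than 2 fully-windowed beats")

  sig <- recording$signal
  claimed <- rep(FALSE, n_samp)   # earlier beats take precedence
  templates <- matrix(0, length(channels), length(off))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    segs <- vapply(fid_samp[full], function(s) sig[ch, s + off],
                   numeric(length(off)))
    templates[ci, ] <- rowMeans(segs)
  }
  for (b in seq_along(fid_samp)) {
    ix <- fid_samp[b] + off
    ok <- ix >= 1L & ix <= n_samp
    ok[ok] <- !claimed[ix[ok]]
    if (!any(ok)) next
    claimed[ix[ok]] <- TRUE
    for (ci in seq_along(channels)) {
      ch <- channels[ci]
      tpl <- templates[ci, ]
      scale <- 1
      if (per_beat_scaling && full[b]) {
        denom <- sum(tpl^2)
        if (denom > 1e-12)
          scale <- sum(sig[ch, fid_samp[b] + off] * tpl) / denom
      }
      sig[ch, ix[ok]] <- sig[ch, ix[ok]] - scale * tpl[ok]
    }
  }
  out <- recording
  out$signal <- sig
  out
}

#' Detect local activation times on unipolar electrograms
#'
#' Candidate activation times are the local minima of the first difference
#' (steepest negative slope of the unipolar deflection) falling below
#' `-k * MAD` of the channel's derivative (with a floor of 20% of the
#' channel's steepest descent, so that noise-free channels with zero MAD
#' remain detectable); non-maximum suppression within
#' the refractory period keeps the steeper candidate. With
#' `cycle_prior = TRUE`, an iterative refinement estimates the channel's
#' cycle length and re-scores candidates by slope magnitude times a
#' periodicity likelihood, dropping low-scoring candidates until a fixed
#' point (at most 10 iterations).
#'
#' @param recording An `egm_recording`, cleaned of ventricular far-field
#'   (or far-field-free).
#' @param grid The `electrode_grid` the channels map to.
#' @param deriv_threshold_k MAD multiplier for the slope threshold.
#' @param refractory_ms Suppression window (default 40 ms).
#' @param cycle_prior Enable the periodicity refinement.
#' @param score_threshold Relative score below which a candidate is dropped
#'   during refinement.
#' @return An `activation_series`. All-constant channels yield no events
#'   (not an error).
#' @export
detect_activation_times <- function(recording, grid,
                                    deriv_threshold_k = 4,
                                    refractory_ms = 40,
                                    cycle_prior = FALSE,
                                    score_threshold = 0.2) {
  fs <- recording$sampling_rate_hz
  chans <- which(!is.na(recording$channel_map))
  out <- list()
  for (ch in chans) {
    x <- recording$signal[ch, ]
    d <- diff(x)
    steepest <- max(-d)
    if (!length(d) || steepest < 1e-9) next   # flat / no descending slope
    s <- stats::mad(d, center = 0)
    # the MAD term sets the threshold on noisy channels; the slope-relative
    # floor keeps noise-free channels (zero MAD) detectable
    thr <- -max(deriv_threshold_k * s, 0.2 * steepest)
    cand <- which(d < thr &
                  d <= c(Inf, d[-length(d)]) & d <= c(d[-1], Inf))
    if (!length(cand)) next
    # suppression: steeper candidate wins within the refractory window
    ord <- cand[order(d[cand])]
    kept <- integer(0)
    refr_samp <- refractory_ms * fs / 1000
    for (i in ord)
      if (!length(kept) || all(abs(kept - i) >= refr_samp))
        kept <- c(kept, i)
    kept <- sort(kept)
    at <- (kept - 1 + 0.5) / fs * 1000   # first difference sits mid-sample
    slope <- -d[kept]
    if (cycle_prior && length(at) >= 3) {
      for (iter in 1:10) {
        if (length(at) < 3) break
        cl <- stats::median(diff(at))
        dev <- vapply(seq_along(at), function(i) {
          gaps <- abs(at[i] - at[-i])
          min(abs(gaps - cl))
        }, numeric(1))
        lik <- exp(-(dev / (0.35 * cl))^2)
        score <- (slope / max(slope)) * lik
        drop <- score < score_threshold
        if (!any(drop)) break
        at <- at[!drop]; slope <- slope[!drop]
      }
    }
    if (length(at))
      out[[length(out) + 1L]] <- data.frame(
        electrode = recording$channel_map[ch], at_ms = at)
  }
  events <- if (length(out)) do.call(rbind, out) else
    data.frame(electrode = integer(0), at_ms = numeric(0))
  activation_series(events, grid,
                    window_ms = c(0, (ncol(recording$signal) - 1) / fs * 1000),
                    refractory_floor_ms = min(refractory_ms, 40))
}
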