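#' ECG interval measurement over consecutive beats
#'
#' Measures RR, QRS and QT over `n_beats` consecutive beats of a surface or
#' reference ECG channel. Per beat: the fiducial is the dominant QRS
#' deflection; QRS onset/offset are where the rectified signal leaves/returns
#' to baseline (a small fraction of the QRS peak) around the fiducial; the
#' T-wave end is found by the tangent method (steepest down-slope after the
#' T peak extrapolated to baseline). Beats with an undetectable T wave are
#' excluded and counted. Heart rate is `60000 / RR`.
#'
#' @param ecg Numeric vector (mV) or an `egm_recording` (its reference
#'   channel is used).
#' @param fs_hz Sampling rate; taken from the recording when one is given.
#' @param n_beats Number of consecutive beats to measure (default 10).
#' @param qtc_model Optional piecewise-linear correction model passed to
#'   [qtc_piecewise()]; without it `qtc_ms` is `NA`.
#' @param onset_frac Baseline threshold as a fraction of the QRS peak.
#' @return Object of class `ecg_intervals`: medians over the measured beats
#'   (`rr_ms, qrs_ms, qt_ms, qtc_ms, hr_bpm`), `n_beats`, `n_excluded`, and
#'   the per-beat table in `$beats`.
#' @export
ecg_intervals <- function(ecg, fs_hz = NULL, n_beats = 10,
                          qtc_model = NULL, onset_frac = 0.05) {
  if (inherits(ecg, "egm_recording")) {
    fs_hz <- ecg$sampling_rate_hz
    ecg <- ecg$signal[ecg$reference_channel, ]
  }
  stopifnot(!is.null(fs_hz), fs_hz > 0)
  rec <- egm_recording(matrix(ecg, nrow = 1), fs_hz, channel_map = NA_integer_,
                       reference_channel = 1L)
  beats <- detect_ventricular_beats(rec, 1L)
  fid <- beats$fiducials_ms
  if (length(fid) < n_beats + 1)
    stop("need at least ", n_beats + 1, " detectable beats, got ",
         length(fid))
  fid <- fid[seq_len(n_beats + 1)]
  rr <- diff(fid)
  t_ms <- (seq_along(ecg) - 1) / fs_hz * 1000
  a <- abs(ecg)

  per_beat <- vector("list", n_beats)
  for (b in seq_len(n_beats)) {
    f <- fid[b]
    fi <- round(f * fs_hz / 1000) + 1L
    # the fiducial sits at the steepest slope (zero crossing), so the QRS
    # peak is taken over a window around it
    pk_win <- max(1L, fi - round(0.08 * fs_hz)):min(length(a),
                                                    fi + round(0.08 * fs_hz))
    peak <- max(a[pk_win])
    thr <- onset_frac * peak
    run_min <- max(3L, round(0.008 * fs_hz))   # sustained-baseline run, 8 ms
    # QRS onset: end of the last sustained below-threshold run before the
    # fiducial (the brief zero crossing at the fiducial itself is not
    # baseline)
    lo <- max(1L, fi - round(0.12 * fs_hz))
    q_on <- t_ms[lo]
    r <- rle(a[lo:fi] < thr)
    ends <- cumsum(r$lengths)
    ok <- which(r$values & r$lengths >= run_min)
    if (length(ok)) q_on <- t_ms[lo + ends[max(ok)] - 1L]
    # QRS offset: start of the first sustained below-threshold run after it
    hi <- min(length(a), fi + round(0.12 * fs_hz))
    s_off <- t_ms[hi]
    r <- rle(a[fi:hi] < thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= run_min)
    if (length(ok)) s_off <- t_ms[fi + starts[min(ok)] - 1L]
    # T wave in (fiducial + 150, fiducial + min(500, 0.8 RR))
    t_hi_ms <- f + min(500, 0.8 * rr[b])
    wi <- which(t_ms > f + 150 & t_ms < t_hi_ms)
    t_end <- NA_real_
    if (length(wi) > 5) {
      tp <- wi[which.max(abs(ecg[wi]))]
      t_amp <- ecg[tp]
      if (abs(t_amp) > 3 * onset_frac * peak) {
        after <- tp:max(wi)
        if (length(after) > 2) {
          dd <- diff(ecg[after]) * fs_hz / 1000   # mV/ms
          # steepest slope back toward baseline
          k <- if (t_amp > 0) which.min(dd) else which.max(dd)
          slope <- dd[k]
          xs <- ecg[after[k]]
          ts <- t_ms[after[k]]
          if (abs(slope) > 1e-9) t_end <- ts - xs / slope
        }
      }
    }
    per_beat[[b]] <- data.frame(
      beat = b, rr_ms = rr[b], q_onset_ms = q_on, s_offset_ms = s_off,
      qrs_ms = s_off - q_on, t_end_ms = t_end,
      qt_ms = if (is.na(t_end)) NA_real_ else t_end - q_on)
  }
  tab <- do.call(rbind, per_beat)
  n_excl <- sum(is.na(tab$qt_ms))
  med <- function(v) stats::median(v, na.rm = TRUE)
  rr_med <- med(tab$rr_ms); qt_med <- med(tab$qt_ms)
  hr <- 60000 / rr_med
  qtc <- if (!is.null(qtc_model) && is.finite(qt_med))
    qtc_piecewise(qt_med, hr, qtc_model) else NA_real_
  structure(list(rr_ms = rr_med, qrs_ms = med(tab$qrs_ms), qt_ms = qt_med,
                 qtc_ms = qtc, hr_bpm = hr, n_beats = n_beats,
                 n_excluded = n_excl, beats = tab),
            class = "ecg_intervals")
}

#' @export
print.ecg_intervals <- function(x, ...) {
  cat(sprintf(
    "<ecg_intervals> over %d beats: RR %.0f ms (HR %.1f bpm), QRS %.0f ms, QT %.0f ms, QTc %s ms (%d beat(s) excluded)\n",
    x$n_beats, x$rr_ms, x$hr_bpm, x$qrs_ms, x$qt_ms,
    if (is.na(x$qtc_ms)) "NA" else sprintf("%.0f", x$qtc_ms), x$n_excluded))
  invisible(x)
}

#' Piecewise-linear heart-rate correction of the QT interval
#'
#' `QTc = QT - g(HR)` with `g` a continuous piecewise-linear function of
#' heart rate supplied as a model configuration
#' `list(breakpoints, slopes, intercepts)`: segment i covers
#' `(breakpoints[i-1], breakpoints[i]]` and evaluates
#' `slopes[i] * HR + intercepts[i]`. Continuity across breakpoints is
#' checked at load time and a discontinuous model is rejected. The shipped
#' default (`qtc_identity_model()`) is a labeled placeholder with zero
#' correction; species-specific coefficients must be supplied via the model
#' configuration.
#'
#' @param qt_ms QT interval, ms.
#' @param hr_bpm Heart rate, bpm.
#' @param model Model list as above (`breakpoints` are the interior segment
#'   boundaries, length `length(slopes) - 1`).
#' @return Corrected QTc, ms.
#' @export
qtc_piecewise <- function(qt_ms, hr_bpm, model = qtc_identity_model()) {
  k <- length(model$slopes)
  stopifnot(length(model$intercepts) == k,
            length(model$breakpoints) == k - 1)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      h <- model$breakpoints[i]
      left <- model$slopes[i] * h + model$intercepts[i]
      right <- model$slopes[i + 1] * h + model$intercepts[i + 1]
      if (abs(left - right) > 1e-6)
        stop("discontinuous QTc model at breakpoint HR = ", h)
    }
  }
  seg <- findInterval(hr_bpm, model$breakpoints) + 1
  qt_ms - (model$slopes[seg] * hr_bpm + model$intercepts[seg])
}

#' @rdname qtc_piecewise
#' @export
qtc_identity_model <- function() {
  list(breakpoints = numeric(0), slopes = 0, intercepts = 0)
}

#' Free (unbound) plasma concentration
#'
#' `free = total * (100 - binding) / 100`, reported to two significant
#' figures. At the measured 90.5% equine plasma protein binding, a total
#' concentration of 27.4 uM corresponds to a 2.6 uM free fraction.
#'
#' @param total_conc_uM Total plasma concentration (uM).
#' @param protein_binding_pct Plasma protein binding, percent in [0, 100].
#' @return Free concentration (uM), 2 significant figures.
#' @examples
#' pk_free_concentration(27.4, 90.5)  # 2.6
#' @export
pk_free_concentration <- function(total_conc_uM, protein_binding_pct) {
  if (any(protein_binding_pct < 0 | protein_binding_pct > 100))
    stop("protein binding must be between 0 and 100 percent")
  signif(total_conc_uM * (100 - protein_binding_pct) / 100, 2)
}

#' Median/IQR summary per region and timepoint
#'
#' Summarizes per-electrode metric tables as median and interquartile range
#' (linear-interpolation, type-7 quantiles) per region x timepoint group.
#' Groups with fewer than 4 observations are flagged and not summarized;
#' missing metric values propagate as missing.
#'
#' @param data Data frame with grouping columns and numeric metric columns.
#' @param metrics Character vector of metric column names.
#' @param by Grouping columns (default `c("region", "timepoint")`).
#' @param min_n Minimum observations per group (default 4).
#' @return Long data frame `region, timepoint, metric, n, median, q1, q3,
#'   iqr, included`.
#' @export
summarize_regions <- function(data, metrics,
                              by = c("region", "timepoint"), min_n = 4L) {
  stopifnot(all(by %in% names(data)), all(metrics %in% names(data)))
  key <- interaction(data[by], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(data)), key)
  if (!length(groups)) stop("no groups to summarize")
  rows <- list()
  for (gname in names(groups)) {
    ix <- groups[[gname]]
    labels <- data[ix[1], by, drop = FALSE]
    for (m in metrics) {
      v <- data[[m]][ix]
      v <- v[!is.na(v)]
      n <- length(v)
      if (n >= min_n) {
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        rows[[length(rows) + 1L]] <- cbind(
          labels, data.frame(metric = m, n = n, median = q[2], q1 = q[1],
                             q3 = q[3], iqr = q[3] - q[1], included = TRUE))
      } else {
        rows[[length(rows) + 1L]] <- cbind(
          labels, data.frame(metric = m, n = n, median = NA_real_,
                             q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
                             included = FALSE))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
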