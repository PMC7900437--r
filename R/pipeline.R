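#' Run the full AF mapping analysis
#'
#' Convenience pipeline from an activation series (or a raw electrogram
#' recording) to the mapping metrics of one analysis window: neighbor-link
#' classification, local conduction velocity, anisotropy, electrical
#' dissociation, AF cycle length, fibrillation waves with origin
#' classification and cycle-normalized counts, and re-entry detection.
#'
#' @param x An `activation_series`, or an `egm_recording` (then ventricular
#'   beats are detected, the QRST far-field cancelled, and activation times
#'   detected first).
#' @param grid The `electrode_grid`.
#' @param v_block_cm_s Conduction-block velocity threshold (cm/s).
#' @param min_electrodes Small-wave exclusion threshold.
#' @param detector Parameters forwarded to [detect_activation_times()] when
#'   `x` is a recording.
#' @return Object of class `af_analysis` with elements `series`, `links`,
#'   `cv` (per-event estimates), `cv_summary`, `anisotropy`, `dissociation_pct`,
#'   `afcl`, `waves`, `counts`, `reentry`, `limits`, `grid`.
#' @export
af_analyze <- function(x, grid, v_block_cm_s = 20, min_electrodes = 3L,
                       detector = list()) {
  if (inherits(x, "egm_recording")) {
    rec <- x
    if (!is.null(rec$reference_channel)) {
      beats <- detect_ventricular_beats(rec)
      rec <- cancel_qrst(rec, beats)
    }
    args <- c(list(recording = rec, grid = grid), detector)
    x <- do.call(detect_activation_times, args)
  }
  stopifnot(inherits(x, "activation_series"))
  limits <- block_limits(grid, v_block_cm_s)
  cl <- afcl(x)
  links <- classify_links(
    pair_neighbor_activations(x, grid, pairing_window_ms = cl$regional_ms / 2),
    limits)
  cv <- fit_cv_map(x, grid, limits)
  valid_cv <- cv$speed_cm_s[cv$valid]
  ani <- anisotropy_index(cv)
  waves <- filter_waves(classify_origin(reconstruct_waves(x, grid, limits)),
                        min_electrodes)
  window_ms <- diff(x$window_ms)
  counts <- normalize_counts(waves, window_ms, cl$regional_ms)
  reentry <- detect_reentries(waves, cl$regional_ms, window_ms)
  structure(list(
    series = x, links = links, cv = cv,
    cv_summary = c(median = stats::median(valid_cv),
                   q1 = unname(stats::quantile(valid_cv, 0.25, names = FALSE)),
                   q3 = unname(stats::quantile(valid_cv, 0.75, names = FALSE))),
    anisotropy = ani,
    dissociation_pct = dissociation_index(links),
    afcl = cl, waves = waves, counts = counts, reentry = reentry,
    limits = limits, grid = grid),
    class = "af_analysis")
}

#' @export
print.af_analysis <- function(x, ...) {
  cat("<af_analysis>\n")
  cat(sprintf("  window          : %.0f ms, %d events\n",
              diff(x$series$window_ms), nrow(x$series$events)))
  cat(sprintf("  AFCL            : %.1f ms (regional median)\n",
              x$afcl$regional_ms))
  cat(sprintf("  CV              : %.1f cm/s median [Q1 %.1f, Q3 %.1f]\n",
              x$cv_summary["median"], x$cv_summary["q1"], x$cv_summary["q3"]))
  cat(sprintf("  dissociation    : %.1f %% of paired links blocked\n",
              x$dissociation_pct))
  cat(sprintf("  anisotropy      : %.2f (median mean-resultant length)\n",
              stats::median(x$anisotropy$anisotropy, na.rm = TRUE)))
  cat(sprintf("  waves           : %d (%.2f per cycle), %d breakthroughs (%.2f per cycle)\n",
              x$counts$n_waves, x$counts$waves_per_cycle,
              x$counts$n_breakthroughs, x$counts$breakthroughs_per_cycle))
  cat(sprintf("  re-entry        : %d event(s), present %.1f%% of window\n",
              nrow(x$reentry$reentries), x$reentry$percent_time_present))
  invisible(x)
}

#' @export
summary.af_analysis <- function(object, ...) {
  data.frame(
    metric = c("afcl_ms", "cv_median_cm_s", "dissociation_pct",
               "anisotropy_median", "waves_per_cycle",
               "breakthroughs_per_cycle", "breakthrough_fraction",
               "reentry_percent_time", "reentry_mean_max_revolutions"),
    value = c(object$afcl$regional_ms, object$cv_summary[["median"]],
              object$dissociation_pct,
              stats::median(object$anisotropy$anisotropy, na.rm = TRUE),
              object$counts$waves_per_cycle,
              object$counts$breakthroughs_per_cycle,
              object$counts$breakthrough_fraction,
              object$reentry$percent_time_present,
              object$reentry$mean_max_revolutions))
}

#' Isochronal activation map
#'
#' Plots the first activation time per electrode within a time window as a
#' color-coded lattice map (an isochronal map), with wave boundaries
#' implicit in the color discontinuities.
#'
#' @param x An `af_analysis` (or an `activation_series` via
#'   [plot_isochrones()]).
#' @param window_ms Length-2 window to map; default the first AF cycle.
#' @param ... Passed to [graphics::image()].
#' @export
plot.af_analysis <- function(x, window_ms = NULL, ...) {
  if (is.null(window_ms)) {
    t0 <- x$series$window_ms[1]
    window_ms <- c(t0, t0 + x$afcl$regional_ms)
  }
  plot_isochrones(x$series, x$grid, window_ms, ...)
}

#' @rdname plot.af_analysis
#' @param series An `activation_series`.
#' @param grid The `electrode_grid`.
#' @export
plot_isochrones <- function(series, grid, window_ms = series$window_ms, ...) {
  ev <- series$events
  ev <- ev[ev$at_ms >= window_ms[1] & ev$at_ms <= window_ms[2], , drop = FALSE]
  z <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  if (nrow(ev)) {
    first <- vapply(split(ev$at_ms, ev$electrode), min, numeric(1))
    m <- match(as.integer(names(first)), grid$electrodes$electrode)
    z[cbind(grid$electrodes$row[m], grid$electrodes$col[m])] <- first
  }
  graphics::image(
    x = seq_len(grid$n_cols), y = seq_len(grid$n_rows),
    z = t(z[grid$n_rows:1, , drop = FALSE]),
    col = grDevices::hcl.colors(64, "viridis"),
    xlab = "column", ylab = "row", asp = 1,
    main = sprintf("Isochronal map [%.0f, %.0f] ms",
                   window_ms[1], window_ms[2]), ...)
  invisible(z)
}
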