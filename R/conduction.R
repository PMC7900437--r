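#' Maximal activation-time difference compatible with conduction
#'
#' Neighboring electrodes whose activation-time difference implies an
#' apparent conduction velocity below the block threshold are classified as
#' conduction block. This returns the largest whole-millisecond delay whose
#' implied velocity (inter-electrode distance / delay) is still at or above
#' the threshold, i.e. `floor(distance_mm / v_block)` with the velocity in
#' mm/ms. At the 2.5 mm array spacing and the 20 cm/s block threshold this
#' gives the classical 12 ms (orthogonal) and 17 ms (oblique) limits.
#'
#' @param spacing_mm Inter-electrode distance, mm (> 0).
#' @param v_block_cm_s Block velocity threshold, cm/s (> 0); default 20.
#' @param relation `"orthogonal"` (distance `spacing_mm`) or `"oblique"`
#'   (distance `spacing_mm * sqrt(2)`).
#' @return Integer limit in ms.
#' @examples
#' max_at_difference(2.5, 20, "orthogonal")  # 12
#' max_at_difference(2.5, 20, "oblique")     # 17
#' @export
max_at_difference <- function(spacing_mm, v_block_cm_s = 20,
                              relation = c("orthogonal", "oblique")) {
  relation <- match.arg(relation)
  stopifnot(spacing_mm > 0, v_block_cm_s > 0)
  d <- if (relation == "oblique") spacing_mm * sqrt(2) else spacing_mm
  as.integer(floor(d / (v_block_cm_s / 100) + 1e-9))
}

#' Block limits for a grid
#'
#' Convenience wrapper returning the named pair of orthogonal/oblique
#' activation-time limits for a grid's spacing.
#'
#' @param grid An `electrode_grid`.
#' @param v_block_cm_s Block velocity threshold, cm/s.
#' @return Named numeric `c(orthogonal=, oblique=)` in ms.
#' @export
block_limits <- function(grid, v_block_cm_s = 20) {
  c(orthogonal = max_at_difference(grid$spacing_mm, v_block_cm_s, "orthogonal"),
    oblique = max_at_difference(grid$spacing_mm, v_block_cm_s, "oblique"))
}

#' Pair activations across neighbor links
#'
#' For every activation event and every neighboring electrode, finds the
#' neighbor's nearest-in-time activation within `pairing_window_ms` and
#' records the signed delay. Each (event, neighbor) pairs with at most one
#' neighbor event; links with no neighbor activation in the window are
#' flagged `"unpaired"`.
#'
#' @param series An `activation_series`.
#' @param grid The `electrode_grid`.
#' @param pairing_window_ms Pairing half-window, ms. Default: half the
#'   series' median AF cycle length (falls back to 100 ms when the cycle
#'   length is not estimable), which avoids cross-cycle pairing.
#' @return Data frame of link samples: `from, to, relation, t_from, t_to,
#'   delta_t_ms, status` (`"unpaired"` here; see [classify_links()]).
#' @export
pair_neighbor_activations <- function(series, grid, pairing_window_ms = NULL) {
  ev <- series$events
  if (!nrow(ev)) stop("series is empty")
  if (is.null(pairing_window_ms)) {
    cl <- try(afcl(series), silent = TRUE)
    pairing_window_ms <- if (!inherits(cl, "try-error") &&
                             is.finite(cl$regional_ms))
      cl$regional_ms / 2 else 100
  }
  times <- split(ev$at_ms, ev$electrode)
  nb <- grid$neighbors
  # directed neighbor list (both orientations)
  dnb <- rbind(nb[, c("from", "to", "relation")],
               stats::setNames(nb[, c("to", "from", "relation")],
                               c("from", "to", "relation")))
  out <- vector("list", nrow(dnb))
  for (r in seq_len(nrow(dnb))) {
    ta <- times[[as.character(dnb$from[r])]]
    if (is.null(ta)) next
    tb <- times[[as.character(dnb$to[r])]]
    if (is.null(tb)) {
      out[[r]] <- data.frame(from = dnb$from[r], to = dnb$to[r],
                             relation = dnb$relation[r], t_from = ta,
                             t_to = NA_real_, delta_t_ms = NA_real_,
                             status = "unpaired")
      next
    }
    # nearest tb for each ta
    pos <- findInterval(ta, tb)
    lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(tb))
    d_lo <- abs(ta - tb[lo]); d_hi <- abs(ta - tb[hi])
    pick <- ifelse(d_hi < d_lo, hi, lo)
    t_to <- tb[pick]
    delta <- t_to - ta
    paired <- abs(delta) <= pairing_window_ms
    out[[r]] <- data.frame(from = dnb$from[r], to = dnb$to[r],
                           relation = dnb$relation[r], t_from = ta,
                           t_to = ifelse(paired, t_to, NA_real_),
                           delta_t_ms = ifelse(paired, delta, NA_real_),
                           status = ifelse(paired, NA_character_, "unpaired"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify neighbor links as conducted or blocked
#'
#' A paired link is conducted iff its absolute delay does not exceed the
#' relation's limit (12 ms orthogonal / 17 ms oblique at the default 2.5 mm,
#' 20 cm/s settings); otherwise it is blocked. Unpaired links stay unpaired.
#'
#' @param links Link table from [pair_neighbor_activations()].
#' @param limits Named limits from [block_limits()].
#' @return The link table with `status` filled in.
#' @export
classify_links <- function(links, limits) {
  lim <- unname(limits[links$relation])
  paired <- !is.na(links$delta_t_ms)
  links$status[paired] <- ifelse(abs(links$delta_t_ms[paired]) <= lim[paired],
                                 "conducted", "blocked")
  links$status[!paired] <- "unpaired"
  links
}

#' Local conduction velocity by activation plane fitting
#'
#' Fits a least-squares plane `T(x, y) = a x + b y + c` through an
#' activation event and the conducted-paired activations of its direct
#' neighbors (within the 12/17 ms limits). The local speed is
#' `100 / sqrt(a^2 + b^2)` cm/s (gradient in ms/mm) and the propagation
#' direction is `atan2(b, a)` (the direction along which activation gets
#' later, i.e. where the wavefront is heading). The estimate is invalid with
#' fewer than 3 conducted neighbors, degenerate (collinear) neighbor
#' geometry, or a vanishing gradient (simultaneous activation).
#'
#' @param series An `activation_series`.
#' @param grid The `electrode_grid`.
#' @param electrode Electrode id of the event.
#' @param at_ms Activation time of the event (must be in the series).
#' @param limits Block limits, see [block_limits()].
#' @return One-row data frame: `electrode, at_ms, speed_cm_s, direction_rad,
#'   n_neighbors_used, rms_residual_ms, valid`.
#' @export
fit_local_cv <- function(series, grid, electrode, at_ms,
                         limits = block_limits(grid)) {
  ev <- series$events
  if (!any(ev$electrode == electrode & abs(ev$at_ms - at_ms) < 1e-9))
    stop("event not found in series")
  nb <- grid$neighbors
  sel <- nb$from == electrode | nb$to == electrode
  nbr <- ifelse(nb$from[sel] == electrode, nb$to[sel], nb$from[sel])
  rel <- nb$relation[sel]
  times <- split(ev$at_ms, ev$electrode)
  el <- grid$electrodes
  pts <- list(data.frame(x = el$x_mm[match(electrode, el$electrode)],
                         y = el$y_mm[match(electrode, el$electrode)],
                         t = at_ms))
  n_used <- 0L
  for (q in seq_along(nbr)) {
    tb <- times[[as.character(nbr[q])]]
    if (is.null(tb)) next
    d <- tb - at_ms
    j <- which.min(abs(d))
    if (abs(d[j]) <= limits[[rel[q]]]) {
      m <- match(nbr[q], el$electrode)
      pts[[length(pts) + 1L]] <- data.frame(x = el$x_mm[m], y = el$y_mm[m],
                                            t = tb[j])
      n_used <- n_used + 1L
    }
  }
  invalid <- function(reason) data.frame(
    electrode = electrode, at_ms = at_ms, speed_cm_s = NA_real_,
    direction_rad = NA_real_, n_neighbors_used = n_used,
    rms_residual_ms = NA_real_, valid = FALSE)
  if (n_used < 3L) return(invalid("too few conducted neighbors"))
  P <- do.call(rbind, pts)
  X <- cbind(P$x, P$y, 1)
  fit <- qr(X)
  if (fit$rank < 3L) return(invalid("degenerate neighbor geometry"))
  coefs <- qr.coef(fit, P$t)
  a <- coefs[1]; b <- coefs[2]
  gmag <- sqrt(a^2 + b^2)             # ms/mm
  if (!is.finite(gmag) || gmag < 1e-6) return(invalid("zero gradient"))
  resid <- P$t - X %*% coefs
  data.frame(electrode = electrode, at_ms = at_ms,
             speed_cm_s = 100 / gmag,
             direction_rad = atan2(b, a),
             n_neighbors_used = n_used,
             rms_residual_ms = sqrt(mean(resid^2)),
             valid = TRUE)
}

#' Conduction-velocity map over all events
#'
#' Applies [fit_local_cv()] to every activation event of a series.
#'
#' @inheritParams fit_local_cv
#' @return Data frame of CV estimates, one row per event.
#' @export
fit_cv_map <- function(series, grid, limits = block_limits(grid)) {
  ev <- series$events
  out <- vector("list", nrow(ev))
  for (r in seq_len(nrow(ev)))
    out[[r]] <- fit_local_cv(series, grid, ev$electrode[r], ev$at_ms[r],
                             limits)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Anisotropy index from conduction directions
#'
#' Per electrode, the mean resultant length of its unit conduction-direction
#' vectors, `R = |mean(exp(i * theta))|`; circular variance is `1 - R`. An
#' index of 1 means a fixed preferential direction, 0 a fully isotropic
#' (symmetric) direction distribution. Electrodes with fewer than 3 valid
#' estimates are excluded (`NA`).
#'
#' @param cv_estimates Data frame from [fit_cv_map()].
#' @param min_estimates Minimum valid estimates per electrode (default 3).
#' @return Data frame `electrode, n, anisotropy`.
#' @export
anisotropy_index <- function(cv_estimates, min_estimates = 3L) {
  ok <- cv_estimates[cv_estimates$valid, , drop = FALSE]
  sp <- split(ok$direction_rad, ok$electrode)
  data.frame(
    electrode = as.integer(names(sp)),
    n = lengths(sp),
    anisotropy = vapply(sp, function(th) {
      if (length(th) < min_estimates) return(NA_real_)
      sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    }, numeric(1)),
    row.names = NULL)
}

#' Electrical dissociation index
#'
#' Percentage of paired neighbor links classified as blocked:
#' `100 * blocked / (conducted + blocked)` over the analysis window. A
#' marker of dyssynchrony of activation between neighboring electrodes.
#'
#' @param links Classified link table from [classify_links()].
#' @return Percent (0-100).
#' @export
dissociation_index <- function(links) {
  n_paired <- sum(links$status %in% c("conducted", "blocked"))
  if (n_paired == 0) stop("dissociation undefined: no paired links")
  100 * sum(links$status == "blocked") / n_paired
}

#' AF cycle length
#'
#' Per contributing electrode (>= 3 activations), the median of successive
#' inter-activation intervals; the regional value is the median over
#' electrode values.
#'
#' @param series An `activation_series`.
#' @param electrodes Optional subset of electrode ids.
#' @param aggregation Summary across intervals and electrodes (default
#'   [stats::median]).
#' @return List with `per_electrode` (data frame `electrode, n_intervals,
#'   afcl_ms`) and `regional_ms`.
#' @export
afcl <- function(series, electrodes = NULL, aggregation = stats::median) {
  ev <- series$events
  if (!is.null(electrodes)) ev <- ev[ev$electrode %in% electrodes, , drop = FALSE]
  sp <- split(ev$at_ms, ev$electrode)
  sp <- sp[lengths(sp) >= 3L]
  if (!length(sp))
    stop("AFCL undefined: no electrode has >= 3 activations")
  per <- data.frame(
    electrode = as.integer(names(sp)),
    n_intervals = lengths(sp) - 1L,
    afcl_ms = vapply(sp, function(tt) aggregation(diff(sort(tt))), numeric(1)),
    row.names = NULL)
  list(per_electrode = per, regional_ms = aggregation(per$afcl_ms))
}

#' Wavelength of re-entry
#'
#' `WL = ERP x CV`: the minimal path length able to sustain re-entry, in mm
#' (ms times cm/s divided by 100).
#'
#' @param erp_ms Effective refractory period, ms (> 0).
#' @param cv_cm_s Conduction velocity, cm/s (> 0).
#' @return Wavelength in mm.
#' @examples
#' wavelength(200, 50)  # 100 mm
#' @export
wavelength <- function(erp_ms, cv_cm_s) {
  stopifnot(all(erp_ms > 0), all(cv_cm_s > 0))
  erp_ms * cv_cm_s / 100
}
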