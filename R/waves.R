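#' Reconstruct fibrillation waves from activation times
#'
#' Builds the spatiotemporal event graph — vertices are activation events,
#' with an undirected edge between events at neighboring electrodes whenever
#' their activation-time difference is within the relation's block limit
#' (12/17 ms by default) — and takes its connected components as fibrillation
#' waves. Wave boundaries therefore arise implicitly at the array edge and
#' along lines of conduction block.
#'
#' @param series An `activation_series`.
#' @param grid The `electrode_grid`.
#' @param limits Block limits from [block_limits()].
#' @return Object of class `af_waves`: list with `events` (the event table
#'   plus `wave_id`), `waves` (one row per wave: `wave_id, n_events,
#'   n_electrodes, earliest_electrode, earliest_at_ms, latest_at_ms,
#'   origin`), `grid`, `limits`. Origins are `NA` until [classify_origin()].
#' @export
reconstruct_waves <- function(series, grid, limits = block_limits(grid)) {
  ev <- series$events[, c("electrode", "at_ms")]
  if (!nrow(ev)) {
    return(structure(list(
      events = cbind(ev, wave_id = integer(0)),
      waves = data.frame(wave_id = integer(0), n_events = integer(0),
                         n_electrodes = integer(0),
                         earliest_electrode = integer(0),
                         earliest_at_ms = numeric(0),
                         latest_at_ms = numeric(0), origin = character(0)),
      grid = grid, limits = limits, window_ms = series$window_ms),
      class = "af_waves"))
  }
  n <- nrow(ev)
  edges <- event_graph_edges(ev, grid, limits)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  comp <- igraph::components(g)$membership
  # number waves by earliest event time
  first_t <- vapply(split(ev$at_ms, comp), min, numeric(1))
  relabel <- match(comp, as.integer(names(sort(first_t))))
  ev$wave_id <- relabel
  waves <- do.call(rbind, lapply(split(seq_len(n), ev$wave_id), function(ix) {
    first <- ix[which.min(ev$at_ms[ix])]
    data.frame(wave_id = ev$wave_id[first],
               n_events = length(ix),
               n_electrodes = length(unique(ev$electrode[ix])),
               earliest_electrode = ev$electrode[first],
               earliest_at_ms = ev$at_ms[first],
               latest_at_ms = max(ev$at_ms[ix]),
               origin = NA_character_)
  }))
  rownames(waves) <- NULL
  structure(list(events = ev, waves = waves, grid = grid, limits = limits,
                 window_ms = series$window_ms),
            class = "af_waves")
}

# event-graph edge list (indices into the event table)
event_graph_edges <- function(ev, grid, limits) {
  ord <- order(ev$electrode, ev$at_ms)
  by_el <- split(ord, ev$electrode[ord])
  nb <- grid$neighbors
  ii <- integer(0); jj <- integer(0)
  for (r in seq_len(nrow(nb))) {
    a <- by_el[[as.character(nb$from[r])]]
    b <- by_el[[as.character(nb$to[r])]]
    if (is.null(a) || is.null(b)) next
    lim <- limits[[nb$relation[r]]]
    tb <- ev$at_ms[b]
    for (i in a) {
      lo <- findInterval(ev$at_ms[i] - lim, tb) + 1L
      hi <- findInterval(ev$at_ms[i] + lim + 1e-12, tb)
      if (hi >= lo) { ii <- c(ii, rep(i, hi - lo + 1L)); jj <- c(jj, b[lo:hi]) }
    }
  }
  data.frame(i = ii, j = jj)
}

#' @export
print.af_waves <- function(x, ...) {
  cat(sprintf("<af_waves> %d waves over %d events; origins: %s\n",
              nrow(x$waves), nrow(x$events),
              if (all(is.na(x$waves$origin))) "unclassified"
              else paste(names(table(x$waves$origin)),
                         table(x$waves$origin), collapse = ", ")))
  invisible(x)
}

#' Classify wave origin: peripheral vs breakthrough
#'
#' A wave is `"peripheral"` if its earliest activation lies on the periphery
#' of the array (the wavefront entered the mapped area from outside) and a
#' `"breakthrough"` if it first appears strictly inside the mapped area,
#' where it cannot be explained by epicardial conduction. Ties in the
#' earliest time are broken toward peripheral if any tied electrode is on
#' the periphery.
#'
#' @param waves An `af_waves` object.
#' @param grid The `electrode_grid` (default: the one stored in `waves`).
#' @return `waves` with the `origin` column filled in.
#' @export
classify_origin <- function(waves, grid = waves$grid) {
  ev <- waves$events
  for (w in seq_len(nrow(waves$waves))) {
    wid <- waves$waves$wave_id[w]
    ix <- which(ev$wave_id == wid)
    t0 <- min(ev$at_ms[ix])
    tied <- ev$electrode[ix][ev$at_ms[ix] <= t0 + 1e-9]
    peri <- is_periphery(grid, tied)
    waves$waves$origin[w] <- if (any(peri)) "peripheral" else "breakthrough"
    if (any(peri) && !is_periphery(grid, waves$waves$earliest_electrode[w]))
      waves$waves$earliest_electrode[w] <- tied[peri][1]
  }
  waves
}

#' Filter out small waves
#'
#' Waves spanning fewer than `min_electrodes` distinct electrodes are prone
#' to noise or occasional mis-assignment of an activation time and are
#' removed from the analysis.
#'
#' @param waves An `af_waves` object.
#' @param min_electrodes Minimum distinct electrodes per wave (default 3).
#' @return Filtered `af_waves`; the number removed is recorded in
#'   `attr(, "n_removed")` and reported via `message()`.
#' @export
filter_waves <- function(waves, min_electrodes = 3L) {
  keep_ids <- waves$waves$wave_id[waves$waves$n_electrodes >= min_electrodes]
  n_removed <- nrow(waves$waves) - length(keep_ids)
  if (n_removed > 0)
    message(n_removed, " wave(s) with < ", min_electrodes,
            " electrodes removed")
  waves$waves <- waves$waves[waves$waves$wave_id %in% keep_ids, , drop = FALSE]
  waves$events <- waves$events[waves$events$wave_id %in% keep_ids, , drop = FALSE]
  rownames(waves$waves) <- rownames(waves$events) <- NULL
  attr(waves, "n_removed") <- n_removed
  waves
}

#' Cycle-normalized wave counts
#'
#' Waves and breakthroughs per AF cycle, and the breakthrough fraction:
#' `waves_per_cycle = n_waves * mean_afcl / window`,
#' `breakthrough_fraction = n_breakthrough / n_waves`.
#'
#' @param waves A classified `af_waves` object (after [classify_origin()]).
#' @param window_ms Analysis window length, ms (> 0).
#' @param mean_afcl_ms Mean AF cycle length, ms (> 0).
#' @return List `n_waves, n_breakthroughs, waves_per_cycle,
#'   breakthroughs_per_cycle, breakthrough_fraction` (fraction is `NA` when
#'   there are no waves).
#' @export
normalize_counts <- function(waves, window_ms, mean_afcl_ms) {
  if (window_ms <= 0 || mean_afcl_ms <= 0)
    stop("window_ms and mean_afcl_ms must be positive")
  n_waves <- nrow(waves$waves)
  n_bt <- sum(waves$waves$origin == "breakthrough", na.rm = TRUE)
  list(n_waves = n_waves, n_breakthroughs = n_bt,
       waves_per_cycle = n_waves * mean_afcl_ms / window_ms,
       breakthroughs_per_cycle = n_bt * mean_afcl_ms / window_ms,
       breakthrough_fraction = if (n_waves > 0) n_bt / n_waves else NA_real_)
}

#' Conduction path of a wave
#'
#' The shortest continuous trajectory between the starting point (earliest
#' event) and end point (latest event) of a wave, presuming every step
#' conducts (per-step apparent CV at or above the block threshold): on the
#' wave's events, a directed edge runs from the earlier to the later event
#' of a neighboring-electrode pair whenever `0 <= dt <= limit`; simultaneous
#' activations (`dt = 0`) are oriented from the lower to the higher
#' electrode id. The trajectory is the path of minimum total spatial length.
#'
#' @param waves An `af_waves` object.
#' @param wave_id Id of the wave to trace.
#' @return Data frame `electrode, at_ms` of the trajectory (in path order),
#'   or `NULL` with a warning if no feasible path exists (an integrity
#'   error: within one component this should be impossible).
#' @export
conduction_path <- function(waves, wave_id) {
  ev <- waves$events[waves$events$wave_id == wave_id, , drop = FALSE]
  if (nrow(ev) < 2) return(ev[, c("electrode", "at_ms")])
  rownames(ev) <- NULL
  grid <- waves$grid; limits <- waves$limits
  edges <- event_graph_edges(ev, grid, limits)
  if (!nrow(edges)) { warning("wave has no internal links"); return(NULL) }
  # orient: earlier -> later; dt == 0 by electrode id
  ti <- ev$at_ms[edges$i]; tj <- ev$at_ms[edges$j]
  flip <- tj < ti | (tj == ti & ev$electrode[edges$j] < ev$electrode[edges$i])
  from <- ifelse(flip, edges$j, edges$i)
  to <- ifelse(flip, edges$i, edges$j)
  # drop duplicate directed pairs (event_graph_edges lists both directions
  # when both events see each other)
  key <- paste(from, to)
  keep <- !duplicated(key) & from != to
  from <- from[keep]; to <- to[keep]
  el <- grid$electrodes
  xi <- match(ev$electrode[from], el$electrode)
  xj <- match(ev$electrode[to], el$electrode)
  w <- sqrt((el$x_mm[xi] - el$x_mm[xj])^2 + (el$y_mm[xi] - el$y_mm[xj])^2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = TRUE,
    vertices = data.frame(name = seq_len(nrow(ev))))
  start <- which.min(ev$at_ms + ev$electrode * 1e-12)
  end <- which.max(ev$at_ms)
  sp <- suppressWarnings(igraph::shortest_paths(
    g, from = as.character(start), to = as.character(end),
    mode = "out", output = "vpath"))
  vp <- sp$vpath[[1]]
  if (length(vp) == 0) {
    warning("integrity error: no feasible conduction path within wave ",
            wave_id)
    return(NULL)
  }
  ix <- as.integer(igraph::as_ids(vp))
  out <- ev[ix, c("electrode", "at_ms")]
  rownames(out) <- NULL
  out
}

#' Detect local re-entry from conduction paths
#'
#' A wave's trajectory exhibits re-entry when it re-visits an electrode
#' after at least 75% of the mean AF cycle length has elapsed since the
#' previous visit (the tissue has recovered, so the revisit closes a
#' rotating circuit). The revolution count of a re-entry is the number of
#' qualifying revisits at its most-revisited electrode ("maximal rotation").
#'
#' @param waves A (filtered, classified) `af_waves` object.
#' @param mean_afcl_ms Mean AF cycle length, ms (> 0).
#' @param window_ms Analysis window length for the percent-time summary;
#'   default the series window span stored in `waves`.
#' @return List with `reentries` (data frame `wave_id, electrode,
#'   n_revolutions, start_ms, end_ms`, one row per re-entrant wave; the
#'   electrode is the most-revisited one), `percent_time_present` (share of
#'   the window covered by the union of qualifying trajectories' time spans)
#'   and `mean_max_revolutions` (`NA` when no re-entry).
#' @export
detect_reentries <- function(waves, mean_afcl_ms,
                             window_ms = diff(waves$window_ms)) {
  stopifnot(mean_afcl_ms > 0)
  thr <- 0.75 * mean_afcl_ms
  rows <- list()
  spans <- list()
  for (wid in waves$waves$wave_id) {
    traj <- conduction_path(waves, wid)
    if (is.null(traj) || nrow(traj) < 2) next
    revs_by_el <- vapply(split(traj$at_ms, traj$electrode), function(tt) {
      if (length(tt) < 2) return(0L)
      sum(diff(sort(tt)) >= thr - 1e-9)
    }, integer(1))
    if (!any(revs_by_el >= 1L)) next
    best <- which.max(revs_by_el)
    rows[[length(rows) + 1L]] <- data.frame(
      wave_id = wid,
      electrode = as.integer(names(revs_by_el)[best]),
      n_revolutions = revs_by_el[[best]],
      start_ms = min(traj$at_ms), end_ms = max(traj$at_ms))
    spans[[length(spans) + 1L]] <- c(min(traj$at_ms), max(traj$at_ms))
  }
  reentries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(wave_id = integer(0), electrode = integer(0),
               n_revolutions = integer(0), start_ms = numeric(0),
               end_ms = numeric(0))
  rownames(reentries) <- NULL
  pct <- if (length(spans) && window_ms > 0) {
    m <- do.call(rbind, spans)
    m <- m[order(m[, 1]), , drop = FALSE]
    covered <- 0; cur <- m[1, ]
    if (nrow(m) > 1) for (r in 2:nrow(m)) {
      if (m[r, 1] <= cur[2]) cur[2] <- max(cur[2], m[r, 2])
      else { covered <- covered + diff(cur); cur <- m[r, ] }
    }
    covered <- covered + diff(cur)
    100 * covered / window_ms
  } else 0
  list(reentries = reentries,
       percent_time_present = pct,
       mean_max_revolutions = if (nrow(reentries))
         mean(reentries$n_revolutions) else NA_real_)
}
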