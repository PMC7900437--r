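# edge traversal times (ms) for a speed in cm/s (scalar, or c(x, y) for an
# anisotropic elliptical metric); 100 cm/s == 1 mm/ms
edge_times_ms <- function(grid, speed_cm_s) {
  stopifnot(all(speed_cm_s > 0))
  v <- speed_cm_s / 100   # mm/ms
  nb <- grid$neighbors
  el <- grid$electrodes
  i <- match(nb$from, el$electrode); j <- match(nb$to, el$electrode)
  dx <- abs(el$x_mm[j] - el$x_mm[i]); dy <- abs(el$y_mm[j] - el$y_mm[i])
  if (length(v) == 1L) sqrt(dx^2 + dy^2) / v
  else sqrt((dx / v[1])^2 + (dy / v[2])^2)
}

# canonical from<to form for an edge table
normalize_edges <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0)
    return(data.frame(from = integer(0), to = integer(0)))
  f <- pmin(edges$from, edges$to); t <- pmax(edges$from, edges$to)
  unique(data.frame(from = f, to = t))
}

# igraph lattice with given speed and blocked edges removed
propagation_graph <- function(grid, speed_cm_s, blocked_edges = NULL) {
  nb <- grid$neighbors
  w <- edge_times_ms(grid, speed_cm_s)
  if (!is.null(blocked_edges) && nrow(blocked_edges)) {
    blocked_edges <- normalize_edges(blocked_edges)
    key <- paste(nb$from, nb$to)
    bad <- !(paste(blocked_edges$from, blocked_edges$to) %in% key)
    if (any(bad)) stop("blocked_edges must be a subset of the neighbor relation")
    keep <- !(key %in% paste(blocked_edges$from, blocked_edges$to))
    nb <- nb[keep, , drop = FALSE]; w <- w[keep]
  }
  igraph::graph_from_data_frame(
    data.frame(from = nb$from, to = nb$to, weight = w),
    directed = FALSE,
    vertices = data.frame(name = grid$electrodes$electrode))
}

# min geodesic arrival (ms) from a set of source electrodes
geodesic_arrival <- function(graph, sources, n_electrodes) {
  d <- igraph::distances(graph, v = as.character(sources),
                         to = as.character(seq_len(n_electrodes)))
  if (length(sources) > 1L) apply(d, 2, min) else as.vector(d)
}

# electrodes on one lattice edge
edge_electrodes <- function(grid, side = c("left", "right", "top", "bottom")) {
  side <- match.arg(side)
  el <- grid$electrodes
  sel <- switch(side,
    left = el$col == min(el$col), right = el$col == max(el$col),
    top = el$row == min(el$row), bottom = el$row == max(el$row))
  el$electrode[sel]
}

#' Define a propagation scenario
#'
#' A scenario bundles the grid, one or more activation sources, a conduction
#' speed (scalar, or an `c(x, y)` pair for anisotropic propagation), a set of
#' blocked neighbor edges, a duration and a seed. Sources are lists with a
#' `type` of `"planar"` (field `edge`: `"left"`, `"right"`, `"top"` or
#' `"bottom"`) or `"focal"` (field `site`: an electrode id), plus `onset_ms`
#' and optionally `period_ms` and `n_cycles` for repetitive firing.
#'
#' @param grid An `electrode_grid`.
#' @param sources List of source descriptions (see Details).
#' @param speed_cm_s Conduction speed, cm/s (> 0); length 1 or 2.
#' @param blocked_edges Data frame `from, to` of blocked neighbor pairs
#'   (subset of `grid$neighbors`), or `NULL`.
#' @param duration_ms Scenario duration (events beyond it are discarded).
#' @param seed Integer seed fixing all randomness downstream.
#' @return Object of class `af_scenario`.
#' @export
af_scenario <- function(grid, sources, speed_cm_s = 80,
                        blocked_edges = NULL, duration_ms = 1000,
                        seed = 1L) {
  stopifnot(inherits(grid, "electrode_grid"), length(sources) >= 1,
            all(speed_cm_s > 0), duration_ms > 0)
  for (s in sources) {
    if (!s$type %in% c("planar", "focal"))
      stop("source type must be 'planar' or 'focal'")
    if (s$type == "focal" &&
        !(s$site %in% grid$electrodes$electrode))
      stop("focal site must be an electrode id on the grid")
    if (!is.null(s$period_ms) && s$period_ms <= 0)
      stop("period_ms must be positive")
  }
  blocked_edges <- normalize_edges(blocked_edges)
  if (nrow(blocked_edges)) {
    key <- paste(grid$neighbors$from, grid$neighbors$to)
    if (!all(paste(blocked_edges$from, blocked_edges$to) %in% key))
      stop("blocked_edges must be a subset of the neighbor relation")
  }
  structure(list(grid = grid, sources = sources, speed_cm_s = speed_cm_s,
                 blocked_edges = blocked_edges, duration_ms = duration_ms,
                 seed = as.integer(seed)),
            class = "af_scenario")
}

#' Simulate earliest-arrival activation times
#'
#' Computes activation times as earliest-arrival geodesics on the
#' 8-neighbor electrode graph: each edge is traversed in
#' `edge length / speed` ms, blocked edges are impassable, and with several
#' sources each electrode takes the minimum arrival per cycle (wavefront
#' collision and fusion). A source firing repetitively at `period_ms`
#' produces one event per cycle per electrode.
#'
#' @param scenario An [af_scenario()].
#' @return List with `series` (an `activation_series`) and `truth` (a
#'   `scenario_truth`: event-level data frame with winning `source`, `cycle`,
#'   `wave_id` and origin class, the blocked-edge list, per-electrode true
#'   cycle length, and ids of electrodes unreachable from every source).
#'   Unreachable electrodes are reported via `truth$unreached` and a warning,
#'   never silently dropped.
#' @export
simulate_arrival_times <- function(scenario) {
  grid <- scenario$grid
  g <- propagation_graph(grid, scenario$speed_cm_s, scenario$blocked_edges)
  n <- grid$n_electrodes
  src_names <- vapply(seq_along(scenario$sources), function(i) {
    s <- scenario$sources[[i]]
    if (s$type == "planar") paste0("planar_", i, "_", s$edge)
    else paste0("focal_", i, "_e", s$site)
  }, character(1))

  arr <- matrix(Inf, length(scenario$sources), n)
  for (i in seq_along(scenario$sources)) {
    s <- scenario$sources[[i]]
    verts <- if (s$type == "planar") edge_electrodes(grid, s$edge) else s$site
    arr[i, ] <- geodesic_arrival(g, verts, n)
  }
  unreached <- which(apply(arr, 2, function(x) all(!is.finite(x))))
  if (length(unreached))
    warning(length(unreached),
            " electrode(s) unreachable from every source: ",
            paste(unreached, collapse = ", "))

  max_cycles <- max(vapply(scenario$sources, function(s)
    if (is.null(s$n_cycles)) 1L else as.integer(s$n_cycles), integer(1)))
  ev <- list()
  for (k in seq_len(max_cycles) - 1L) {
    tk <- matrix(Inf, length(scenario$sources), n)
    for (i in seq_along(scenario$sources)) {
      s <- scenario$sources[[i]]
      nc <- if (is.null(s$n_cycles)) 1L else s$n_cycles
      if (k >= nc) next
      per <- if (is.null(s$period_ms)) 0 else s$period_ms
      tk[i, ] <- s$onset_ms + k * per + arr[i, ]
    }
    win <- apply(tk, 2, which.min)
    tmin <- tk[cbind(win, seq_len(n))]
    keep <- is.finite(tmin) & tmin <= scenario$duration_ms
    if (any(keep))
      ev[[length(ev) + 1L]] <- data.frame(
        electrode = which(keep), at_ms = tmin[keep],
        source = src_names[win[keep]], cycle = k)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(electrode = integer(0), at_ms = numeric(0),
               source = character(0), cycle = integer(0))
  events <- enforce_refractory(events, floor_ms = 40)
  finish_truth(events, grid, scenario$blocked_edges,
               window_ms = c(0, scenario$duration_ms),
               unreached = unreached)
}

# drop events violating a per-electrode refractory floor (earlier one wins)
enforce_refractory <- function(events, floor_ms = 40) {
  if (!nrow(events)) return(events)
  events <- events[order(events$electrode, events$at_ms), , drop = FALSE]
  keep <- rep(TRUE, nrow(events))
  last_t <- -Inf; last_e <- -1L
  for (r in seq_len(nrow(events))) {
    if (events$electrode[r] != last_e) { last_e <- events$electrode[r]; last_t <- -Inf }
    if (events$at_ms[r] - last_t < floor_ms) keep[r] <- FALSE
    else last_t <- events$at_ms[r]
  }
  events[keep, , drop = FALSE]
}

# label waves on ground-truth events with a hand-rolled union-find over the
# paper's wave definition (neighbor events within the 12/17 ms limits)
truth_wave_labels <- function(events, grid, limits = block_limits(grid)) {
  n <- nrow(events)
  if (!n) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  ord <- order(events$electrode, events$at_ms)
  by_el <- split(ord, events$electrode[ord])
  nb <- grid$neighbors
  for (r in seq_len(nrow(nb))) {
    a <- by_el[[as.character(nb$from[r])]]
    b <- by_el[[as.character(nb$to[r])]]
    if (is.null(a) || is.null(b)) next
    lim <- limits[[nb$relation[r]]]
    tb <- events$at_ms[b]
    for (i in a) {
      lo <- findInterval(events$at_ms[i] - lim, tb) + 1L
      hi <- findInterval(events$at_ms[i] + lim + 1e-12, tb)
      if (hi >= lo) for (j in b[lo:hi]) union(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots[order(events$at_ms)]))
}

# assemble series + truth from a labeled event table
finish_truth <- function(events, grid, blocked_edges, window_ms,
                         unreached = integer(0), origin_override = NULL,
                         extra = list()) {
  rownames(events) <- NULL
  wave_id <- truth_wave_labels(events, grid)
  events$wave_id <- wave_id
  origin <- character(0)
  if (nrow(events)) {
    origin_by_wave <- vapply(split(seq_len(nrow(events)), wave_id),
      function(ix) {
        first <- ix[which.min(events$at_ms[ix])]
        el <- events$electrode[first]
        if (!is.null(origin_override)) origin_override
        else if (is_periphery(grid, el)) "peripheral" else "breakthrough"
      }, character(1))
    origin <- origin_by_wave[as.character(wave_id)]
  }
  events$origin <- origin
  cl <- vapply(split(events$at_ms, events$electrode), function(tt)
    if (length(tt) >= 2) median(diff(sort(tt))) else NA_real_, numeric(1))
  truth <- structure(c(list(
    events = events,
    blocked_edges = blocked_edges,
    cycle_length_ms = data.frame(electrode = as.integer(names(cl)),
                                 cl_ms = unname(cl)),
    n_waves = length(unique(wave_id)),
    n_breakthroughs = sum(vapply(split(events$origin, wave_id),
                                 function(o) o[1] == "breakthrough",
                                 logical(1))),
    unreached = unreached), extra),
    class = "scenario_truth")
  series <- activation_series(
    events[, c("electrode", "at_ms")], grid, window_ms = window_ms)
  list(series = series, truth = truth)
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat(sprintf("<scenario_truth> %d events, %d waves (%d breakthroughs)\n",
              nrow(x$events), x$n_waves, x$n_breakthroughs))
  invisible(x)
}

#' Simulate a rotor (re-entrant circuit)
#'
#' Activation at electrode e in cycle n is
#' `onset + n * period + period * phi_e / (2*pi)`, where `phi_e` is the polar
#' angle of e about the rotor core (sign set by `chirality`): the wavefront
#' is a spiral arm rotating once per `period_ms`, so every electrode's cycle
#' length is exactly the rotor period. The core electrode itself (phase
#' singularity) emits no events.
#'
#' @param grid An `electrode_grid`.
#' @param core Electrode id of the rotor core; must be strictly interior.
#' @param period_ms Rotation period (ms, > 0).
#' @param n_cycles Number of rotations (>= 1).
#' @param onset_ms Time of the first activation on the reference ray.
#' @param chirality `+1` (counter-clockwise) or `-1` (clockwise).
#' @return List `series`, `truth` as for [simulate_arrival_times()]; truth
#'   origin class is `"rotor"`.
#' @export
simulate_rotor <- function(grid, core, period_ms, n_cycles,
                           onset_ms = 0, chirality = 1) {
  stopifnot(period_ms > 0, n_cycles >= 1, chirality %in% c(-1, 1))
  if (is_periphery(grid, core))
    stop("rotor core must be strictly interior to the array")
  el <- grid$electrodes
  ci <- match(core, el$electrode)
  dx <- el$x_mm - el$x_mm[ci]; dy <- el$y_mm - el$y_mm[ci]
  phi <- (chirality * atan2(dy, dx)) %% (2 * pi)
  others <- el$electrode[el$electrode != core]
  phi <- phi[el$electrode != core]
  ev <- do.call(rbind, lapply(seq_len(n_cycles) - 1L, function(n)
    data.frame(electrode = others,
               at_ms = onset_ms + n * period_ms + period_ms * phi / (2 * pi),
               source = "rotor", cycle = n)))
  finish_truth(ev, grid, normalize_edges(NULL),
               window_ms = c(onset_ms, onset_ms + (n_cycles + 1) * period_ms),
               origin_override = "rotor")
}

# blocked edges crossing a straight cut segment; orientation "v" cuts
# between columns `at` and `at+1` over rows span[1]..span[2], "h" between rows
cut_edges <- function(grid, orientation, at, span) {
  el <- grid$electrodes
  nb <- grid$neighbors
  i <- match(nb$from, el$electrode); j <- match(nb$to, el$electrode)
  if (orientation == "v") {
    cross <- (pmin(el$col[i], el$col[j]) <= at) &
             (pmax(el$col[i], el$col[j]) >= at + 1L) &
             (el$row[i] >= span[1] & el$row[i] <= span[2]) &
             (el$row[j] >= span[1] & el$row[j] <= span[2])
  } else {
    cross <- (pmin(el$row[i], el$row[j]) <= at) &
             (pmax(el$row[i], el$row[j]) >= at + 1L) &
             (el$col[i] >= span[1] & el$col[i] <= span[2]) &
             (el$col[j] >= span[1] & el$col[j] <= span[2])
  }
  nb[cross, c("from", "to")]
}

random_block_line <- function(grid) {
  orientation <- sample(c("v", "h"), 1)
  extent <- if (orientation == "v") grid$n_cols else grid$n_rows
  span_max <- if (orientation == "v") grid$n_rows else grid$n_cols
  at <- sample(seq_len(extent - 1L), 1)
  len <- sample(4:min(10L, span_max), 1)
  start <- sample(seq_len(span_max - len + 1L), 1)
  cut_edges(grid, orientation, at, c(start, start + len - 1L))
}

#' Simulate a compound AF episode with ground truth
#'
#' Emulates a fibrillation recording as a cycle-by-cycle sequence of
#' peripheral planar wavefronts entering from a random array edge, Poisson
#' focal breakthroughs appearing as small late-coupled waves in the wake of
#' the planar wave (tissue activated earlier in the cycle is refractory, so
#' breakthrough events are temporally isolated, as in endo-epicardial
#' breakthrough), and per-cycle random conduction-block line segments which
#' force wavefronts to detour. All randomness derives from `seed`; the first
#' random draw is the Poisson focal-source count.
#'
#' @param grid An `electrode_grid`.
#' @param mean_afcl_ms Mean AF cycle length (ms).
#' @param focal_rate_per_s Mean rate of focal breakthroughs (events/s).
#' @param n_block_lines Number of random block-line segments per cycle.
#' @param speed_cm_s Planar/focal conduction speed, cm/s.
#' @param jitter_sd_ms SD of Gaussian jitter on cycle onsets (ms).
#' @param duration_ms Episode duration (>= 2 * `mean_afcl_ms`).
#' @param seed Integer seed.
#' @param refractory_floor_ms Events closer than this at one electrode are
#'   dropped (earlier event wins).
#' @return List `series`, `truth`; `truth` additionally carries
#'   `n_focal_sources` (the seeded Poisson draw), `n_cycles`, and per-cycle
#'   blocked-edge tables in `block_lines`.
#' @export
simulate_af_episode <- function(grid, mean_afcl_ms = 185,
                                focal_rate_per_s = 1, n_block_lines = 1,
                                speed_cm_s = 80, jitter_sd_ms = 5,
                                duration_ms = 5000, seed = 1L,
                                refractory_floor_ms = 40) {
  stopifnot(mean_afcl_ms > 0, focal_rate_per_s >= 0, n_block_lines >= 0,
            all(speed_cm_s > 0), jitter_sd_ms >= 0)
  if (duration_ms < 2 * mean_afcl_ms)
    stop("duration_ms must be at least twice mean_afcl_ms")
  set.seed(seed)
  n_focal <- rpois(1, focal_rate_per_s * duration_ms / 1000)

  n_cycles <- floor(duration_ms / mean_afcl_ms)
  onsets <- pmax(0, (seq_len(n_cycles) - 1L) * mean_afcl_ms +
                   rnorm(n_cycles, 0, jitter_sd_ms))
  sides <- sample(c("left", "right", "top", "bottom"), n_cycles,
                  replace = TRUE)
  block_lines <- lapply(seq_len(n_cycles), function(k) {
    if (n_block_lines == 0) return(normalize_edges(NULL))
    normalize_edges(do.call(rbind, lapply(seq_len(n_block_lines),
                                          function(i) random_block_line(grid))))
  })

  ev <- vector("list", n_cycles)
  arr_by_cycle <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    g <- propagation_graph(grid, speed_cm_s, block_lines[[k]])
    a <- geodesic_arrival(g, edge_electrodes(grid, sides[k]),
                          grid$n_electrodes)
    arr_by_cycle[[k]] <- a
    tt <- onsets[k] + a
    keep <- is.finite(tt) & tt <= duration_ms
    ev[[k]] <- data.frame(electrode = which(keep), at_ms = tt[keep],
                          source = sprintf("planar_%d", k), cycle = k - 1L)
  }
  events <- do.call(rbind, ev)

  # focal breakthroughs: small waves coupled 0.35-0.55 cycle after the local
  # planar activation, geodesic radius 1-2 electrodes around an interior site
  if (n_focal > 0) {
    el <- grid$electrodes
    interior_ok <- el$electrode[el$row >= 3 & el$row <= grid$n_rows - 2 &
                                el$col >= 3 & el$col <= grid$n_cols - 2]
    g0 <- propagation_graph(grid, speed_cm_s)
    for (f in seq_len(n_focal)) {
      site <- sample(interior_ok, 1)
      k <- sample(seq_len(max(1L, n_cycles - 1L)), 1)
      delay <- runif(1, 0.35, 0.55) * mean_afcl_ms
      radius <- sample(1:2, 1)
      onset <- onsets[k] + arr_by_cycle[[k]][site] + delay
      d <- geodesic_arrival(g0, site, grid$n_electrodes)
      si <- match(site, el$electrode)
      cheb <- pmax(abs(el$row - el$row[si]), abs(el$col - el$col[si]))
      patch <- which(cheb <= radius & is.finite(d))
      tt <- onset + d[patch]
      keep <- tt <= duration_ms
      if (any(keep))
        events <- rbind(events, data.frame(
          electrode = patch[keep], at_ms = tt[keep],
          source = sprintf("focal_%d", f), cycle = k - 1L))
    }
  }

  events <- enforce_refractory(events, refractory_floor_ms)
  out <- finish_truth(events, grid,
                      normalize_edges(do.call(rbind, block_lines)),
                      window_ms = c(0, duration_ms),
                      extra = list(n_focal_sources = n_focal,
                                   n_cycles = n_cycles,
                                   block_lines = block_lines,
                                   mean_afcl_ms = mean_afcl_ms))
  out
}
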