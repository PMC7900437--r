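# Shared fixtures and independent oracles for the test suite.

# analytic planar wavefront: T(x, y) = onset + (x cos(theta) + y sin(theta)) / v,
# optionally quantized to the acquisition sample grid
planar_series <- function(grid, theta = 0, speed_cm_s = 100, onset_ms = 50,
                          fs_hz = NULL) {
  v <- speed_cm_s / 100
  el <- grid$electrodes
  t <- onset_ms + (el$x_mm * cos(theta) + el$y_mm * sin(theta)) / v
  t <- t - min(t) + onset_ms
  if (!is.null(fs_hz)) t <- round(t * fs_hz / 1000) * 1000 / fs_hz
  activation_series(data.frame(electrode = el$electrode, at_ms = t), grid)
}

# brute-force single-source shortest path by repeated edge relaxation
# (Bellman-Ford), independent of the igraph-based implementation
bf_arrival <- function(grid, sources, speed_cm_s, blocked = NULL) {
  v <- speed_cm_s / 100
  nb <- grid$neighbors
  if (!is.null(blocked) && nrow(blocked)) {
    bk <- paste(pmin(blocked$from, blocked$to), pmax(blocked$from, blocked$to))
    keep <- !(paste(nb$from, nb$to) %in% bk)
    nb <- nb[keep, , drop = FALSE]
  }
  w <- nb$dist_mm / v
  from <- c(nb$from, nb$to); to <- c(nb$to, nb$from); w <- c(w, w)
  d <- rep(Inf, grid$n_electrodes)
  d[sources] <- 0
  repeat {
    relaxed <- pmin(d, unname(tapply(d[from] + w, to, min)[
      as.character(seq_len(grid$n_electrodes))]))
    relaxed[is.na(relaxed)] <- d[is.na(relaxed)]
    if (isTRUE(all.equal(relaxed, d, tolerance = 0))) break
    d <- relaxed
  }
  d
}

# von-Mises sampler (Best & Fisher rejection scheme) for the anisotropy
# oracle; the analytic mean resultant length is besselI(k,1)/besselI(k,0)
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
    }
  }
  out
}

# detection quality against ground truth: |dt| <= tol counts as a match
match_stats <- function(detected, truth_events, tol_ms = 5) {
  tp <- 0
  de <- detected$events
  for (e in unique(truth_events$electrode)) {
    tt <- truth_events$at_ms[truth_events$electrode == e]
    dd <- de$at_ms[de$electrode == e]
    if (!length(dd)) next
    for (x in tt) if (min(abs(dd - x)) <= tol_ms) tp <- tp + 1
  }
  c(sensitivity = tp / nrow(truth_events), precision = tp / nrow(de))
}

# small random block set drawn from a grid's neighbor relation
random_blocked <- function(grid, n_blocked) {
  ix <- sample(nrow(grid$neighbors), n_blocked)
  grid$neighbors[ix, c("from", "to")]
}
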