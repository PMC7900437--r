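test_that("a single planar wave reconstructs as one wave covering the grid", {
  g <- build_grid(10, 10, 2.5)
  s <- planar_series(g, theta = 0.2, speed_cm_s = 80)
  w <- reconstruct_waves(s, g)
  expect_equal(nrow(w$waves), 1)
  expect_equal(w$waves$n_electrodes, g$n_electrodes)
  expect_equal(w$waves$n_events, g$n_electrodes)
  w <- classify_origin(w)
  expect_equal(w$waves$origin, "peripheral")
})

test_that("a full block line bisecting the grid yields two waves", {
  g <- build_grid(8, 8, 2.5)
  # block every edge crossing the cut between columns 4 and 5
  blocked <- fibwave:::cut_edges(g, "v", 4L, c(1L, 8L))
  sc <- af_scenario(g, list(list(type = "planar", edge = "left",
                                 onset_ms = 0)),
                    speed_cm_s = 80, blocked_edges = blocked,
                    duration_ms = 5000)
  sim <- suppressWarnings(simulate_arrival_times(sc))
  # right half unreachable -> only left half activates; add a delayed right
  # source to form the second wave
  sc2 <- af_scenario(g, list(list(type = "planar", edge = "left",
                                  onset_ms = 0),
                             list(type = "planar", edge = "right",
                                  onset_ms = 60)),
                     speed_cm_s = 80, blocked_edges = blocked,
                     duration_ms = 5000)
  sim2 <- simulate_arrival_times(sc2)
  w <- reconstruct_waves(sim2$series, g)
  expect_equal(nrow(w$waves), 2)
  expect_equal(sim2$truth$n_waves, 2)

  # empty series: empty wave list
  es <- activation_series(data.frame(electrode = integer(0),
                                     at_ms = numeric(0)), g,
                          window_ms = c(0, 100))
  expect_equal(nrow(reconstruct_waves(es, g)$waves), 0)
})

test_that("origin classification follows the earliest-site periphery rule", {
  g <- build_grid(10, 10, 2.5)
  # interior focal source: breakthrough
  center <- g$electrodes$electrode[g$electrodes$row == 5 &
                                   g$electrodes$col == 5]
  sc <- af_scenario(g, list(list(type = "focal", site = center,
                                 onset_ms = 0)),
                    speed_cm_s = 80, duration_ms = 1000)
  sim <- simulate_arrival_times(sc)
  w <- classify_origin(reconstruct_waves(sim$series, g))
  expect_equal(w$waves$origin, "breakthrough")
  expect_equal(sim$truth$n_breakthroughs, 1)

  # single-event wave at a corner electrode is peripheral
  corner <- g$electrodes$electrode[g$electrodes$row == 1 &
                                   g$electrodes$col == 1]
  s1 <- activation_series(data.frame(electrode = corner, at_ms = 10), g,
                          window_ms = c(0, 100))
  w1 <- classify_origin(reconstruct_waves(s1, g))
  expect_equal(w1$waves$origin, "peripheral")

  # earliest-time tie between interior and peripheral electrodes breaks
  # toward peripheral
  edge_e <- g$electrodes$electrode[g$electrodes$row == 1 &
                                   g$electrodes$col == 5]
  inner_e <- g$electrodes$electrode[g$electrodes$row == 2 &
                                    g$electrodes$col == 5]
  s2 <- activation_series(data.frame(electrode = c(inner_e, edge_e),
                                     at_ms = c(50, 50)), g,
                          window_ms = c(0, 100))
  w2 <- classify_origin(reconstruct_waves(s2, g))
  expect_equal(w2$waves$origin, "peripheral")
})

test_that("small waves are filtered at the 3-electrode boundary", {
  g <- build_grid(8, 8, 2.5)
  # two separate components: a 2-electrode and a 3-electrode chain
  e <- function(row, col) g$electrodes$electrode[g$electrodes$row == row &
                                                 g$electrodes$col == col]
  s <- activation_series(
    data.frame(electrode = c(e(1, 1), e(1, 2), e(8, 8), e(8, 7), e(8, 6)),
               at_ms = c(10, 12, 500, 503, 506)), g,
    window_ms = c(0, 600))
  w <- classify_origin(reconstruct_waves(s, g))
  expect_equal(nrow(w$waves), 2)
  wf <- suppressMessages(filter_waves(w))
  expect_equal(nrow(wf$waves), 1)
  expect_equal(wf$waves$n_electrodes, 3)
  expect_equal(attr(wf, "n_removed"), 1)
  # empty input stays empty
  es <- activation_series(data.frame(electrode = integer(0),
                                     at_ms = numeric(0)), g,
                          window_ms = c(0, 1))
  expect_equal(nrow(filter_waves(reconstruct_waves(es, g))$waves), 0)
})

test_that("cycle normalization follows the stated arithmetic", {
  g <- build_grid(4, 4, 2.5)
  w <- reconstruct_waves(activation_series(
    data.frame(electrode = integer(0), at_ms = numeric(0)), g,
    window_ms = c(0, 1000)), g)
  # synthetic wave table: 10 waves, 5 breakthroughs
  w$waves <- data.frame(wave_id = 1:10, n_events = 5, n_electrodes = 5,
                        earliest_electrode = 1L, earliest_at_ms = 1:10,
                        latest_at_ms = 2:11,
                        origin = rep(c("peripheral", "breakthrough"), 5))
  nc <- normalize_counts(w, window_ms = 1000, mean_afcl_ms = 200)
  expect_equal(nc$waves_per_cycle, 2.0)
  expect_equal(nc$breakthroughs_per_cycle, 1.0)
  expect_equal(nc$breakthrough_fraction, 0.5)
  # zero waves: counts 0, fraction missing
  w$waves <- w$waves[0, ]
  nc0 <- normalize_counts(w, 1000, 200)
  expect_equal(nc0$waves_per_cycle, 0)
  expect_true(is.na(nc0$breakthrough_fraction))
  expect_error(normalize_counts(w, 0, 200), "positive")
})

test_that("conduction paths are monotone chains on planar waves", {
  g <- build_grid(8, 8, 2.5)
  s <- planar_series(g, theta = 0, speed_cm_s = 80)
  w <- reconstruct_waves(s, g)
  traj <- conduction_path(w, w$waves$wave_id[1])
  expect_true(all(diff(traj$at_ms) >= 0))
  expect_false(any(duplicated(traj$electrode)))
  # path length within the sqrt(2) lattice factor of the straight line
  el <- g$electrodes
  step_len <- sqrt(diff(el$x_mm[match(traj$electrode, el$electrode)])^2 +
                   diff(el$y_mm[match(traj$electrode, el$electrode)])^2)
  straight <- sqrt((el$x_mm[match(traj$electrode[nrow(traj)], el$electrode)] -
                    el$x_mm[match(traj$electrode[1], el$electrode)])^2 +
                   (el$y_mm[match(traj$electrode[nrow(traj)], el$electrode)] -
                    el$y_mm[match(traj$electrode[1], el$electrode)])^2)
  expect_lte(sum(step_len), sqrt(2) * straight + 1e-9)

  # 2-event wave: the trajectory is that single link
  e <- function(row, col) g$electrodes$electrode[g$electrodes$row == row &
                                                 g$electrodes$col == col]
  s2 <- activation_series(data.frame(electrode = c(e(4, 4), e(4, 5)),
                                     at_ms = c(100, 105)), g,
                          window_ms = c(0, 200))
  w2 <- reconstruct_waves(s2, g)
  traj2 <- conduction_path(w2, 1L)
  expect_equal(nrow(traj2), 2)
  expect_equal(traj2$at_ms, c(100, 105))
})

test_that("rotor trajectories revisit electrodes; re-entry is detected", {
  g <- build_grid(12, 12, 2.5)
  core <- g$electrodes$electrode[g$electrodes$row == 6 & g$electrodes$col == 6]
  for (cfg in list(c(150, 3), c(180, 5), c(250, 8))) {
    period <- cfg[1]; cycles <- cfg[2]
    rot <- simulate_rotor(g, core, period, cycles)
    w <- suppressMessages(filter_waves(classify_origin(
      reconstruct_waves(rot$series, g))))
    traj <- conduction_path(w, w$waves$wave_id[1])
    expect_true(any(duplicated(traj$electrode)))   # non-simple path
    re <- detect_reentries(w, mean_afcl_ms = period)
    expect_equal(nrow(re$reentries), 1)
    expect_equal(re$reentries$n_revolutions, cycles - 1)
    expect_gt(re$percent_time_present, 0)
  }
})

test_that("planar and focal waves never trigger re-entry detection", {
  g <- build_grid(10, 10, 2.5)
  s <- planar_series(g, theta = 0.4, speed_cm_s = 70)
  w <- reconstruct_waves(s, g)
  re <- detect_reentries(w, mean_afcl_ms = 180)
  expect_equal(nrow(re$reentries), 0)
  expect_equal(re$percent_time_present, 0)
  expect_true(is.na(re$mean_max_revolutions))

  center <- g$electrodes$electrode[g$electrodes$row == 5 &
                                   g$electrodes$col == 5]
  sc <- af_scenario(g, list(list(type = "focal", site = center,
                                 onset_ms = 0)),
                    speed_cm_s = 80, duration_ms = 1000)
  sim <- simulate_arrival_times(sc)
  wf <- reconstruct_waves(sim$series, g)
  expect_equal(nrow(detect_reentries(wf, 180)$reentries), 0)
})

test_that("revisits earlier than 75% of the cycle length do not qualify", {
  g <- build_grid(12, 12, 2.5)
  core <- g$electrodes$electrode[g$electrodes$row == 6 & g$electrodes$col == 6]
  rot <- simulate_rotor(g, core, period_ms = 150, n_cycles = 4)
  w <- reconstruct_waves(rot$series, g)
  # revisits are separated by exactly the period: demanding a mean AFCL
  # of twice the period makes every revisit fall below the 75% bound
  re <- detect_reentries(w, mean_afcl_ms = 2 * 150)
  expect_equal(nrow(re$reentries), 0)
})

test_that("waves partition retained events and respect edge removal", {
  g <- build_grid(10, 10, 2.5)
  ep <- simulate_af_episode(g, duration_ms = 3000, seed = 6)
  w <- reconstruct_waves(ep$series, g)
  expect_equal(nrow(w$events), nrow(ep$series$events))
  expect_false(any(is.na(w$events$wave_id)))
  # tightening the limits (removing event-graph edges) never merges waves
  w_tight <- reconstruct_waves(ep$series, g,
                               limits = c(orthogonal = 6, oblique = 8))
  expect_gte(nrow(w_tight$waves), nrow(w$waves))
})

test_that("reconstructed counts agree exactly with episode truth", {
  g <- build_grid(10, 10, 2.5)
  for (seed in 1:20) {
    ep <- simulate_af_episode(g, duration_ms = 5000, seed = seed)
    w <- classify_origin(reconstruct_waves(ep$series, g))
    expect_equal(nrow(w$waves), ep$truth$n_waves)
    expect_equal(sum(w$waves$origin == "breakthrough"),
                 ep$truth$n_breakthroughs)
  }
})
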