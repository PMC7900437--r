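test_that("block limits reproduce the printed 12/17 ms values", {
  expect_identical(max_at_difference(2.5, 20, "orthogonal"), 12L)
  expect_identical(max_at_difference(2.5, 20, "oblique"), 17L)
  expect_identical(max_at_difference(2.5, 250, "orthogonal"), 1L)
  g <- build_grid(4, 4, 2.5)
  expect_equal(block_limits(g), c(orthogonal = 12, oblique = 17))
})

test_that("limits are monotone in threshold velocity and spacing", {
  vs <- c(10, 20, 40, 80, 160)
  for (rel in c("orthogonal", "oblique")) {
    lims <- vapply(vs, function(v) max_at_difference(2.5, v, rel), integer(1))
    expect_true(all(diff(lims) <= 0))
    sp <- vapply(c(1, 2, 2.5, 4, 8), function(s)
      max_at_difference(s, 20, rel), integer(1))
    expect_true(all(diff(sp) >= 0))
  }
})

test_that("neighbor pairing is complete on planar waves and symmetric", {
  g <- build_grid(6, 6, 2.5)
  s <- planar_series(g, theta = 0.2, speed_cm_s = 80)
  links <- pair_neighbor_activations(s, g, pairing_window_ms = 50)
  expect_false(any(links$status %in% "unpaired"))
  # |delta| is symmetric between the two orientations of a link
  key <- paste(pmin(links$from, links$to), pmax(links$from, links$to))
  for (k in unique(key)[1:20]) {
    d <- abs(links$delta_t_ms[key == k])
    expect_equal(d[1], d[2])
  }
  # a silent neighbor leaves the link unpaired
  s2 <- activation_series(data.frame(electrode = c(1L, 2L),
                                     at_ms = c(100, 500)), g)
  l2 <- pair_neighbor_activations(s2, g, pairing_window_ms = 50)
  expect_true(all(l2$status == "unpaired"))
})

test_that("link classification applies the exact limit boundaries", {
  g <- build_grid(2, 2, 2.5)
  lim <- block_limits(g)
  mk <- function(delta, relation) data.frame(
    from = 1L, to = 2L, relation = relation, t_from = 0, t_to = delta,
    delta_t_ms = delta, status = NA_character_)
  expect_equal(classify_links(mk(12, "orthogonal"), lim)$status, "conducted")
  expect_equal(classify_links(mk(13, "orthogonal"), lim)$status, "blocked")
  expect_equal(classify_links(mk(17, "oblique"), lim)$status, "conducted")
  expect_equal(classify_links(mk(18, "oblique"), lim)$status, "blocked")
  expect_equal(classify_links(mk(0, "oblique"), lim)$status, "conducted")
})

test_that("plane fitting recovers planar-wave speed and direction", {
  g <- build_grid(10, 10, 2.5)
  interior <- setdiff(g$electrodes$electrode, g$periphery)

  s <- planar_series(g, theta = 0, speed_cm_s = 100)
  cv <- fit_cv_map(s, g)
  cvi <- cv[cv$valid & cv$electrode %in% interior, ]
  expect_equal(nrow(cvi), length(interior))
  expect_true(all(abs(cvi$speed_cm_s - 100) < 1))
  expect_true(all(abs(cvi$direction_rad) < 0.02))
  expect_true(all(cvi$n_neighbors_used == 8))

  s45 <- planar_series(g, theta = pi / 4, speed_cm_s = 100)
  cv45 <- fit_cv_map(s45, g)
  cvi45 <- cv45[cv45$valid & cv45$electrode %in% interior, ]
  expect_true(all(abs(cvi45$speed_cm_s - 100) < 1))
  expect_true(all(abs(cvi45$direction_rad - pi / 4) < 0.02))
})

test_that("degenerate plane fits are flagged invalid", {
  g <- build_grid(5, 5, 2.5)
  # simultaneous activation: zero gradient
  s <- activation_series(data.frame(electrode = g$electrodes$electrode,
                                    at_ms = rep(100, g$n_electrodes)), g)
  e <- setdiff(g$electrodes$electrode, g$periphery)[1]
  fit <- fit_local_cv(s, g, e, 100)
  expect_false(fit$valid)
  # fewer than 3 conducted neighbors
  s2 <- activation_series(data.frame(electrode = c(12L, 13L),
                                     at_ms = c(100, 104)), g)
  fit2 <- fit_local_cv(s2, g, 12L, 100)
  expect_false(fit2$valid)
  expect_lt(fit2$n_neighbors_used, 3)
})

test_that("plane-fit speed is invariant under grid rotation", {
  g <- build_grid(10, 10, 2.5)
  interior <- setdiff(g$electrodes$electrode, g$periphery)
  for (th in c(0.31, 1.1)) {
    s <- planar_series(g, theta = th, speed_cm_s = 75)
    cv <- fit_cv_map(s, g)
    cvi <- cv[cv$valid & cv$electrode %in% interior, ]
    expect_lt(abs(median(cvi$speed_cm_s) - 75) / 75, 0.01)
  }
})

test_that("anisotropy index matches circular-statistics references", {
  mk_cv <- function(dirs) data.frame(
    electrode = 1L, at_ms = seq_along(dirs), speed_cm_s = 50,
    direction_rad = dirs, n_neighbors_used = 8, rms_residual_ms = 0,
    valid = TRUE)
  # identical directions: index 1
  expect_equal(anisotropy_index(mk_cv(rep(0.7, 5)))$anisotropy, 1)
  # four symmetric directions: index 0
  expect_equal(anisotropy_index(mk_cv(c(0, pi / 2, pi, 3 * pi / 2)))$anisotropy,
               0, tolerance = 1e-12)
  # fewer than 3 estimates: undefined
  expect_true(is.na(anisotropy_index(mk_cv(c(0, 1)))$anisotropy))
  # seeded von-Mises draws against the analytic mean resultant length
  set.seed(12)
  kappa <- 4
  draws <- rvonmises(200, mu = 1, kappa = kappa)
  r_analytic <- besselI(kappa, 1) / besselI(kappa, 0)
  expect_equal(anisotropy_index(mk_cv(draws))$anisotropy, r_analytic,
               tolerance = 0.05)
  # invariant under global rotation of all directions
  r0 <- anisotropy_index(mk_cv(draws))$anisotropy
  r1 <- anisotropy_index(mk_cv(draws + 2.2))$anisotropy
  expect_equal(r0, r1, tolerance = 1e-9)
})

test_that("dissociation index counts blocked links among paired links", {
  mk <- function(statuses) data.frame(status = statuses)
  expect_equal(dissociation_index(mk(rep("conducted", 8))), 0)
  expect_equal(dissociation_index(mk(c(rep("conducted", 4),
                                       rep("blocked", 4)))), 50)
  expect_equal(dissociation_index(mk(c("blocked", "unpaired", "conducted"))),
               50)
  expect_error(dissociation_index(mk(rep("unpaired", 3))), "no paired")
  # noise-free planar wave at 100 cm/s: all delays within limits
  g <- build_grid(6, 6, 2.5)
  s <- planar_series(g, theta = 0.2, speed_cm_s = 100)
  links <- classify_links(pair_neighbor_activations(s, g, 50),
                          block_limits(g))
  expect_equal(dissociation_index(links), 0)
})

test_that("AFCL is the median inter-activation interval", {
  g <- build_grid(3, 3, 2.5)
  ev <- data.frame(electrode = rep(1:9, each = 4),
                   at_ms = rep(c(0, 150, 300, 450), 9) + rep(0:8, each = 4))
  s <- activation_series(ev, g)
  cl <- afcl(s)
  expect_true(all(cl$per_electrode$afcl_ms == 150))
  expect_equal(cl$regional_ms, 150)
  # intervals {140, 150, 160} -> median 150
  s2 <- activation_series(data.frame(electrode = 1L,
                                     at_ms = c(0, 140, 290, 450)), g)
  expect_equal(afcl(s2)$regional_ms, 150)
  # fewer than 3 activations everywhere is undefined
  s3 <- activation_series(data.frame(electrode = 1L, at_ms = c(0, 100)), g)
  expect_error(afcl(s3), "undefined")
})

test_that("jittered episodes recover the programmed cycle length", {
  g <- build_grid(10, 10, 2.5)
  for (seed in 1:3) {
    ep <- simulate_af_episode(g, mean_afcl_ms = 185, jitter_sd_ms = 5,
                              duration_ms = 10000, seed = seed)
    expect_lt(abs(afcl(ep$series)$regional_ms - 185), 3)
  }
})

test_that("wavelength is the ERP x CV product in mm", {
  expect_equal(wavelength(200, 50), 100)
  expect_equal(wavelength(0.001, 100), 0.001)
  expect_equal(wavelength(250, 80), 200)
  expect_error(wavelength(-1, 50))
})
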