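# Integrity statistics: per-state Phi tables, surface machinery, and the
# derived summaries.

test_that("phi_per_state covers all collective states", {
  nn <- noise2_tpm()
  tab <- phi_per_state(nn, scope = "full_system")
  expect_equal(nrow(tab), 4)
  expect_equal(tab$phi, rep(0, 4))
  tab2 <- phi_per_state(copy2_tpm(), scope = "full_system")
  expect_equal(tab2$label, c("00", "10", "01", "11"))
  expect_true(all(tab2$phi > 0))
  # determinism: recomputation is bit-identical
  tab3 <- phi_per_state(copy2_tpm(), scope = "full_system")
  expect_identical(tab2$phi, tab3$phi)
})

test_that("mean / variance / fano arithmetic", {
  x <- c(0, 0, 0, 2)
  expect_equal(mean_phi(x), 0.5)
  expect_equal(variance_phi(x), 0.75)  # population variance
  expect_equal(fano_factor(mean_phi(x), variance_phi(x)), 1.5)
  expect_equal(fano_factor(0.5, 0), 0)         # constant phi
  expect_true(is.na(fano_factor(0, 0)))        # undefined at zero mean
})

test_that("phi_surface has the grid-cell contract and equivariances", {
  cfg <- generator_config(n_fish = 2, n_steps = 4000, seed = 17)
  traj <- boids_school(cfg)
  grid <- list(xi_D = c(100, 300), xi_VF = c(pi, 2 * pi), xi_TR = 0)
  surf <- phi_surface(traj, grid, dt_frames = 10, setting = "local",
                      scope = "full_system")
  expect_equal(nrow(surf), 4)
  expect_true(all(surf$mean_phi >= 0 & surf$var_phi >= 0))
  per_state <- attr(surf, "per_state")
  expect_length(per_state, 4)
  expect_true(all(vapply(per_state, nrow, integer(1)) == 4))
  # permuting fish ids leaves every cell mean unchanged
  traj_p <- trajectory(traj$positions[, c(2, 1), ], fps = 120)
  surf_p <- phi_surface(traj_p, grid, dt_frames = 10, setting = "local",
                        scope = "full_system")
  expect_equal(surf_p$mean_phi, surf$mean_phi, tolerance = 1e-10)
})

test_that("extreme thresholds on a cohesive school degenerate the chain", {
  # always-cohesive school, huge xi_D, full field, xi_TR = 0: everyone is
  # always ON, so the chain collapses onto the all-ON state.  Note the
  # unseen rows are filled with 0.5 (maximum entropy), which leaves the
  # *filled* TPM with residual joint structure, so the per-state Phi of
  # the never-visited states need not vanish; the observed dynamics are
  # nevertheless degenerate: a point-mass occupancy and an exact all-ON
  # row.
  cfg <- generator_config(n_fish = 3, n_steps = 4000, seed = 19)
  traj <- boids_school(cfg)
  s <- local_collective_state(traj, local_thresholds(1e6, 2 * pi, 0), 10)
  expect_true(all(s == 1L))
  expect_equal(unname(state_occupancy(s)["111"]), 1)
  est <- estimate_tpm(s)
  expect_equal(unname(unclass(est)[8, ]), c(1, 1, 1))
  tab <- phi_per_state(est, scope = "full_system")
  expect_lt(mean_phi(tab), 0.2)
})

test_that("normalisation and weighted positions behave", {
  surf <- data.frame(xi_D = c(100, 200, 300), xi_VF = pi, xi_TR = 0,
                     mean_phi = c(0.1, 0.4, 0.2), var_phi = 0,
                     fano = 0, n_states = 4)
  class(surf) <- c("phi_surface", "data.frame")
  ns <- normalize_surface(surf)
  expect_equal(max(ns$mean_phi_norm), 1)
  expect_equal(ns$mean_phi_norm, c(0.25, 1, 0.5))
  # region-restricted normalisation
  ns2 <- normalize_surface(surf, region = function(d) d$xi_D < 250)
  expect_equal(attr(ns2, "phi_max"), 0.4)
  zero <- surf; zero$mean_phi <- 0
  expect_error(normalize_surface(zero), "maximum mean Phi")
  # weighted mean position: cells over fraction*max, weighted by mean_phi
  wp <- weighted_mean_position(surf, fraction = 0.4)
  expect_equal(unname(wp["xi_D"]), (200 * 0.4 + 300 * 0.2) / 0.6)
  # single qualifying cell -> its own coordinates
  wp2 <- weighted_mean_position(surf, fraction = 0.9)
  expect_equal(unname(wp2["xi_D"]), 200)
  # two equal cells -> midpoint
  surf$mean_phi <- c(0.4, 0.4, 0)
  expect_equal(unname(weighted_mean_position(surf, 0.5)["xi_D"]), 150)
})

test_that("top-k mean and the local-global difference", {
  x <- c(5, 1, 3, 2, 4)
  expect_equal(top_k_mean(x, 1), 5)
  expect_equal(top_k_mean(x, 3), 4)
  expect_equal(top_k_mean(x, 99), mean(x))   # k >= #cells: global mean
  set.seed(2)
  y <- runif(50)
  expect_equal(top_k_mean(y, 20), mean(sort(y, decreasing = TRUE)[1:20]))
  sl <- data.frame(mean_phi = y)
  sg <- data.frame(mean_phi = y - 0.1)
  expect_equal(local_global_difference(sl, sg, k = 20), 0.1,
               tolerance = 1e-12)
  expect_equal(local_global_difference(sl, sl, k = 20), 0)
})

test_that("phi-fano correlation handles exact, undefined and constant cases", {
  m <- c(0.1, 0.2, 0.3, 0.4)
  f <- 2 * m + 1  # perfectly linear
  expect_equal(phi_fano_correlation(m, f)$r, 1)
  r <- phi_fano_correlation(c(m, 0), c(f, NA))
  expect_equal(r$n_excluded, 1)
  expect_equal(r$n_used, 4)
  expect_true(is.na(phi_fano_correlation(m, rep(2, 4))$r))  # constant fano
  set.seed(3)
  a <- runif(30); b <- runif(30)
  # closed-form Pearson oracle
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(phi_fano_correlation(a, b)$r, oracle, tolerance = 1e-12)
})

test_that("surface CSV export is long-format with metadata", {
  cfg <- generator_config(n_fish = 2, n_steps = 2500, seed = 23)
  traj <- boids_school(cfg)
  surf <- phi_surface(traj, list(xi_D = 200, xi_VF = 2 * pi, xi_TR = 0),
                      dt_frames = 20, scope = "full_system")
  path <- withr::local_tempfile(fileext = ".csv")
  write_surface_csv(surf, path)
  d <- read.csv(path)
  expect_equal(nrow(d), 1)
  expect_true(all(c("xi_D", "mean_phi", "var_phi", "dt_frames", "n",
                    "setting", "scope") %in% names(d)))
})
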