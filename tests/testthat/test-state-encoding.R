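# Trajectory resampling, per-parameter bit functions, and the local /
# global collective-state encoders.

# Straight-line trajectory builder: each fish moves with constant
# velocity; positions (T, N, 2).
line_traj <- function(starts, vels, t_n = 50, fps = 120) {
  n <- nrow(starts)
  pos <- array(NA_real_, c(t_n, n, 2))
  for (t in seq_len(t_n)) {
    pos[t, , ] <- starts + (t - 1) * vels
  }
  trajectory(pos, fps = fps)
}

test_that("resample strides then smooths, with affine invariance", {
  starts <- rbind(c(0, 0), c(100, 0))
  vels <- rbind(c(1, 0), c(1, 0))
  traj <- line_traj(starts, vels, t_n = 241)
  rs <- resample(traj, 20)
  expect_equal(attr(rs, "dt_seconds"), 20 / 120)
  # linear motion is unchanged by the centred 3-point average (ends cut)
  expect_equal(rs$positions[1, 1, 1], 20)  # was sample 2 of the strided grid
  expect_equal(dim(rs$positions)[1], 13 - 2)
  v <- velocities(rs)
  expect_true(all(abs(v[, , 1] - 20) < 1e-9))
  expect_true(all(abs(v[, , 2]) < 1e-9))
  # constant positions unchanged
  still <- line_traj(starts, vels * 0, t_n = 30)
  rs2 <- resample(still, 5)
  expect_true(all(abs(sweep(rs2$positions, c(2, 3), starts)) < 1e-12))
  expect_error(resample(line_traj(starts, vels, t_n = 10), 5), "too few")
})

test_that("velocities on uniform circular motion give chord lengths", {
  theta <- seq(0, 4 * pi, length.out = 200)
  r <- 500
  pos <- array(NA_real_, c(200, 2, 2))
  pos[, 1, 1] <- r * cos(theta); pos[, 1, 2] <- r * sin(theta)
  pos[, 2, 1] <- 1000 + r * cos(theta); pos[, 2, 2] <- r * sin(theta)
  traj <- trajectory(pos, fps = 120)
  v <- velocities(traj)
  step_angle <- diff(theta)[1]
  expect_equal(sqrt(v[1, 1, 1]^2 + v[1, 1, 2]^2), 2 * r * sin(step_angle / 2),
               tolerance = 1e-9)
})

test_that("distance bit uses strict inequality", {
  pos <- rbind(c(0, 0), c(50, 0))
  expect_equal(distance_state(pos, 100), c(1L, 1L))
  expect_equal(distance_state(pos, 50), c(0L, 0L))   # exactly xi_D -> OFF
  pos3 <- rbind(c(0, 0), c(500, 0), c(1000, 0))
  expect_equal(distance_state(pos3, 450), c(0L, 0L, 0L))
})

test_that("visual-field bit implements the half-angle convention", {
  pos <- rbind(c(0, 0), c(100, 0))
  v <- rbind(c(1, 0), c(1, 0))
  # neighbour dead ahead of fish 1: ON for any width
  expect_equal(visual_field_state(pos, v, 0.1)[1], 1L)
  # fish 2 looks away from fish 1: OFF unless the field covers the rear
  expect_equal(visual_field_state(pos, v, pi)[2], 0L)
  # complete field: ON whenever any neighbour exists
  expect_equal(visual_field_state(pos, v, 2 * pi), c(1L, 1L))
  # neighbour at bearing pi/2 with width pi/2: half-angle pi/4 -> OFF
  pos2 <- rbind(c(0, 0), c(0, 100))
  expect_equal(visual_field_state(pos2, v, pi / 2)[1], 0L)
  # but a width just over pi sees it
  expect_equal(visual_field_state(pos2, v, pi + 1e-6)[1], 1L)
  # literal full-angle reading restores angle < xi_VF
  expect_equal(visual_field_state(pos2, v, pi / 2, vf_half_angle = FALSE)[1],
               0L)
  expect_equal(visual_field_state(pos2, v, pi / 2 + 1e-6,
                                  vf_half_angle = FALSE)[1], 1L)
  # zero velocity: heading undefined -> OFF
  v0 <- rbind(c(0, 0), c(1, 0))
  expect_equal(visual_field_state(pos, v0, 2 * pi)[1], 0L)
})

test_that("turning bit uses >= against the threshold", {
  v_now <- rbind(c(1, 0), c(1, 0))
  v_prev <- rbind(c(cos(0.1), -sin(0.1)), c(1, 0))
  expect_equal(turning_state(v_now, v_prev, 0.05), c(1L, 0L))
  expect_equal(turning_state(v_now, v_prev, 0), c(1L, 1L))  # angle >= 0 always
  expect_equal(turning_state(v_now, v_now, 0.001), c(0L, 0L))
})

test_that("local encoder is the conjunction of the three bits", {
  # two fish side by side moving +x: close, ahead-of-neither (bearing 90deg),
  # not turning
  starts <- rbind(c(0, 0), c(0, 50))
  vels <- rbind(c(2, 0), c(2, 0))
  traj <- line_traj(starts, vels, t_n = 40)
  # distance ON, visual field OFF (narrow field), turning OFF -> OFF
  s1 <- local_collective_state(traj, local_thresholds(100, pi / 4, 0.01))
  expect_true(all(s1 == 0L))
  # with xi_TR = 0 and full field the conjunction reduces to the distance bit
  s2 <- local_collective_state(traj, local_thresholds(100, 2 * pi, 0))
  expect_true(all(s2 == 1L))
  s3 <- local_collective_state(traj, local_thresholds(40, 2 * pi, 0))
  expect_true(all(s3 == 0L))  # distance OFF kills the conjunction
})

test_that("global encoder combines alignment and centroid proximity", {
  # fish 2 anti-aligned at the centroid
  starts <- rbind(c(0, 0), c(10, 0))
  vels <- rbind(c(2, 0), c(-2, 0))
  traj <- line_traj(starts, vels, t_n = 30)
  # mean velocity is zero -> both headings undefined relative to it -> OFF
  expect_warning(
    s <- global_collective_state(traj, global_thresholds(Xi_AD = pi / 4,
                                                         Xi_CM = 1000)),
    "undefined headings")
  expect_true(all(s == 0L))
  # identical velocities: all aligned for any threshold; near centroid -> ON
  traj2 <- line_traj(rbind(c(0, 0), c(30, 0)), rbind(c(2, 1), c(2, 1)),
                     t_n = 30)
  s2 <- global_collective_state(traj2, global_thresholds(Xi_AD = 1e-6,
                                                         Xi_CM = 100))
  expect_true(all(s2 == 1L))
  # far from the centroid -> OFF
  traj3 <- line_traj(rbind(c(0, 0), c(800, 0)), rbind(c(2, 0), c(2, 0)),
                     t_n = 30)
  s3 <- global_collective_state(traj3, global_thresholds(Xi_AD = pi,
                                                         Xi_CM = 100))
  expect_true(all(s3 == 0L))
})

test_that("encoding is invariant under rigid motions and relabelling", {
  set.seed(99)
  cfg <- generator_config(n_fish = 3, n_steps = 1500, seed = 5)
  traj <- boids_school(cfg)
  thr <- local_thresholds(200, 1.2 * pi, 0.01)
  s0 <- local_collective_state(traj, thr, dt_frames = 5)
  # rigid rotation + translation
  ang <- 0.7; R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  pos <- traj$positions
  rot <- pos
  for (i in 1:3) rot[, i, ] <- pos[, i, ] %*% t(R)
  rot <- rot + 123.4
  s1 <- local_collective_state(trajectory(rot, fps = 120), thr, dt_frames = 5)
  expect_equal(unclass(s1), unclass(s0), ignore_attr = TRUE)
  # permuting individuals permutes the state bits
  perm <- c(2, 3, 1)
  s2 <- local_collective_state(trajectory(pos[, perm, ], fps = 120), thr,
                               dt_frames = 5)
  expect_equal(unclass(s2), unclass(s0)[, perm], ignore_attr = TRUE)
})

test_that("raising xi_D or xi_VF never turns ON individuals OFF", {
  cfg <- generator_config(n_fish = 3, n_steps = 1200, seed = 8)
  traj <- boids_school(cfg)
  s_small <- local_collective_state(traj, local_thresholds(150, 0.8 * pi, 0),
                                    dt_frames = 5)
  s_big <- local_collective_state(traj, local_thresholds(300, 1.6 * pi, 0),
                                  dt_frames = 5)
  expect_true(all(s_big >= s_small))
  # and the (2*pi, 0) corner equals the pure distance state
  s_corner <- local_collective_state(traj, local_thresholds(150, 2 * pi, 0),
                                     dt_frames = 5)
  rs <- resample(traj, 5)
  idx <- attr(s_corner, "time_index")
  d_only <- t(vapply(idx, function(t) {
    p <- rs$positions[t, , ]; dim(p) <- c(3, 2)
    distance_state(p, 150)
  }, integer(3)))
  expect_equal(unclass(s_corner), d_only, ignore_attr = TRUE)
})

test_that("trajectory CSV round-trips", {
  cfg <- generator_config(n_fish = 2, n_steps = 50, seed = 3)
  traj <- independent_walkers(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$positions, traj$positions, tolerance = 1e-12)
  # corrupt file: missing column
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("frame,id,x\n1,a,0", bad)
  expect_error(read_trajectory_csv(bad), "frame,id,x_mm,y_mm")
})

test_that("state sequences round-trip through CSV + JSON sidecar", {
  cfg <- generator_config(n_fish = 3, n_steps = 800, seed = 21)
  traj <- boids_school(cfg)
  s <- local_collective_state(traj, local_thresholds(300, 2 * pi, 0),
                              dt_frames = 5)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "states.csv")
  write_state_seq(s, path)
  back <- read_state_seq(path)
  expect_equal(unclass(back), unclass(s), ignore_attr = TRUE)
  expect_equal(attr(back, "dt_frames"), attr(s, "dt_frames"))
  expect_equal(attr(back, "setting"), "local")
})
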