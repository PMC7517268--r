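# Leadership metrics: single-OFF detection, positional leader, match
# rates, cohesion.

test_that("single_off_index picks exactly one OFF individual", {
  expect_equal(single_off_index(c(1, 0, 1, 1)), 2L)
  expect_equal(single_off_index(c(1, 1, 1, 1)), 0L)
  expect_equal(single_off_index(c(1, 0, 0, 1)), 0L)
  expect_equal(single_off_index(c(0, 1)), 1L)
})

test_that("positional leader is the front fish along the mean heading", {
  # three fish on a line moving +x: front fish leads
  pos <- rbind(c(0, 0), c(100, 0), c(200, 0))
  vel <- rbind(c(1, 0), c(1, 0), c(1, 0))
  expect_equal(positional_leader(pos, vel), 3L)
  # coincident fish tie -> lowest index
  pos2 <- rbind(c(0, 0), c(0, 0), c(0, 0))
  expect_equal(positional_leader(pos2, vel), 1L)
  # zero mean velocity -> undefined
  vel0 <- rbind(c(1, 0), c(-1, 0), c(0, 0))
  expect_true(is.na(positional_leader(pos, vel0)))
  # randomised configurations against a direct projection oracle
  set.seed(12)
  for (i in 1:20) {
    p <- matrix(runif(8, 0, 1000), 4, 2)
    v <- matrix(rnorm(8), 4, 2)
    u <- colMeans(v); u <- u / sqrt(sum(u^2))
    expect_equal(positional_leader(p, v), which.max(p %*% u))
  }
})

# Builds a trajectory in which all fish swim +x at 1 mm/frame with fish 1
# in front, and a hand-crafted state sequence aligned to it.
make_pl_fixture <- function(states) {
  t_steps <- nrow(states)
  n <- ncol(states)
  # encoder semantics: resampling at stride 1 trims one sample per end,
  # and states start at the third resampled sample
  t_raw <- t_steps + 4
  pos <- array(NA_real_, c(t_raw, n, 2))
  for (t in seq_len(t_raw)) {
    for (i in seq_len(n)) pos[t, i, ] <- c(t - 100 * (i - 1), 10 * i)
  }
  traj <- trajectory(pos, fps = 120)
  seq_ <- schoolphi:::new_state_seq(states, NULL, 1L, 120, "manual",
                                    3:(t_steps + 2), 0L, list())
  list(traj = traj, seq = seq_)
}

test_that("pl_match_rate implements the match-rate formula exactly", {
  # 10 steps, 6 single-OFF events, 3 of them fish 1 (the leader) -> 50%
  states <- rbind(
    c(0, 1, 1),  # single OFF = 1 = leader  (match)
    c(1, 1, 1),
    c(0, 1, 1),  # match
    c(1, 0, 1),  # single OFF = 2           (no match)
    c(0, 0, 1),
    c(1, 1, 0),  # single OFF = 3           (no match)
    c(0, 1, 1),  # match
    c(1, 1, 1),
    c(1, 0, 1),  # no match
    c(0, 0, 0))
  fx <- make_pl_fixture(states)
  r <- pl_match_rate(fx$seq, fx$traj)
  expect_equal(r$n_events, 6L)
  expect_equal(r$n_matches, 3L)
  expect_identical(r$rate, 50)
  # no single-OFF events -> undefined
  fx2 <- make_pl_fixture(matrix(1L, 5, 3))
  expect_true(is.na(pl_match_rate(fx2$seq, fx2$traj)$rate))
  # all-match sequence -> exactly 100
  fx3 <- make_pl_fixture(rbind(c(0, 1, 1), c(0, 1, 1)))
  expect_identical(pl_match_rate(fx3$seq, fx3$traj)$rate, 100)
})

test_that("relabelling individuals leaves pl_match_rate invariant", {
  set.seed(31)
  states <- matrix(rbinom(30 * 3, 1, 0.7), 30, 3)
  fx <- make_pl_fixture(states)
  r1 <- pl_match_rate(fx$seq, fx$traj)
  perm <- c(3, 1, 2)
  fx2 <- make_pl_fixture(states[, perm])
  fx2$traj <- trajectory(fx$traj$positions[, perm, ], fps = 120)
  r2 <- pl_match_rate(fx2$seq, fx2$traj)
  expect_equal(r2$rate, r1$rate)
  expect_equal(r2$n_events, r1$n_events)
})

test_that("mip_cut_match_rate is structurally 100% for N = 2", {
  # any 2-node TPM: the only bipartition separates the two fish
  set.seed(14)
  tpm <- random_markov_tpm(2, seed = 800)
  tab <- phi_per_state(tpm)
  states <- rbind(c(0, 1), c(1, 1), c(1, 0), c(0, 1))
  seq_ <- schoolphi:::new_state_seq(states, NULL, 1L, 120, "manual",
                                    3:6, 0L, list())
  r <- mip_cut_match_rate(tab, seq_)
  expect_equal(r$n_events, 3L)
  expect_identical(r$rate, 100)
})

test_that("mip_cut_match_rate agrees with oracle-known MIP cuts (N = 3)", {
  # copy pair (1,2) + noisy node 3: for any single-OFF state the main
  # complex is {1,2} and its MIP separates 1 from 2.  Single-OFF fish 3
  # is outside the complex, so only states 011 and 101 can match.
  tpm <- copy_pair_plus_noise_tpm()
  tab <- phi_per_state(tpm, scope = "main_complex")
  # verify against the exhaustive oracle that the main complex is {1,2}
  for (s in c(3, 5, 6)) {  # states 110, 101, 011 little-endian
    r <- attr(tab, "results")[[s + 1]]
    expect_equal(r$subsystem, c(1, 2), label = paste("state", s))
  }
  states <- rbind(c(0, 1, 1),   # OFF = 1; cut {1}|{2}: match
                  c(1, 0, 1),   # OFF = 2; match
                  c(1, 1, 0))   # OFF = 3; outside the complex: no match
  seq_ <- schoolphi:::new_state_seq(states, NULL, 1L, 120, "manual",
                                    3:5, 0L, list())
  r <- mip_cut_match_rate(tab, seq_)
  expect_equal(r$n_events, 3L)
  expect_equal(r$n_matches, 2L)
  expect_equal(r$rate, 100 * 2 / 3)
})

test_that("cohesion rate counts timesteps with all pairs within range", {
  # two fish 10 mm apart forever
  pos <- array(0, c(20, 2, 2)); pos[, 2, 1] <- 10
  expect_equal(cohesion_rate(trajectory(pos), 400), 100)
  # one fish permanently 1 m away
  pos[, 2, 1] <- 1000
  expect_equal(cohesion_rate(trajectory(pos), 400), 0)
  # constructed fission: together for 15 steps, apart for 5
  pos[, 2, 1] <- c(rep(10, 15), rep(1000, 5))
  expect_equal(cohesion_rate(trajectory(pos), 400), 75)
  # boundary: exactly at the threshold counts as cohesive (<=)
  pos[, 2, 1] <- 400
  expect_equal(cohesion_rate(trajectory(pos), 400), 100)
})

test_that("match_report populates all fields end-to-end", {
  cfg <- generator_config(n_fish = 2, n_steps = 6000, seed = 33)
  traj <- boids_school(cfg)
  rep_ <- match_report(traj, local_thresholds(300, 2 * pi, 0.001),
                       dt_frames = 10)
  expect_s3_class(rep_, "match_report")
  expect_true(rep_$cohesion_rate >= 0 && rep_$cohesion_rate <= 100)
  expect_length(rep_$phi_by_on_count, 3)  # 0, 1, 2 ON bits
  json <- match_report_json(rep_)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$n, 2)
  expect_equal(parsed$cohesion_rate, rep_$cohesion_rate)
})
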