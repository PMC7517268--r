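# Seeded trajectory and TPM generators.
#
# The generators emulate the experimental regime the analysis was built
# for: a 3 x 3 m shallow arena sampled at 120 fps, cruising speeds in the
# 150-350 mm/s band, and cohesive groups of 2-6 fish.  They are not fits
# to any real dataset; they provide inputs with the statistical structure
# the pipeline assumes (cohesion, alignment, persistent headings,
# optional leader-follower asymmetry), so every stage is testable without
# a download.

#' Generator configuration
#'
#' @param n_fish group size, 2-6.
#' @param n_steps number of frames to generate.
#' @param fps frames per second (120, matching the data regime the
#'   package emulates).
#' @param speed_mm_s target cruising speed in mm/s (default 250, the
#'   middle of the observed 150-350 mm/s band).
#' @param noise_sd heading noise per frame, rad (default 0.08).
#' @param cohesion_w,alignment_w,separation_w interaction weights of the
#'   Boids update.
#' @param leader_bias 0-1; how strongly followers steer toward their
#'   predecessor in [leader_follower_chain()].
#' @param arena_mm side length of the square arena (3000 mm).
#' @param seed integer seed; identical configurations give identical
#'   trajectories.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_fish = 3, n_steps = 20000, fps = 120,
                             speed_mm_s = 250, noise_sd = 0.08,
                             cohesion_w = 0.6, alignment_w = 1.0,
                             separation_w = 1.2, leader_bias = 0.8,
                             arena_mm = 3000, seed = 1) {
  stopifnot(n_fish >= 2, n_fish <= 6, n_steps >= 10, speed_mm_s > 0,
            noise_sd >= 0, leader_bias >= 0, leader_bias <= 1)
  structure(list(n_fish = n_fish, n_steps = n_steps, fps = fps,
                 speed_mm_s = speed_mm_s, noise_sd = noise_sd,
                 cohesion_w = cohesion_w, alignment_w = alignment_w,
                 separation_w = separation_w, leader_bias = leader_bias,
                 arena_mm = arena_mm, seed = seed),
            class = "generator_config")
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0) else v / n
}

# Soft repulsion from the arena walls within `margin` mm.
wall_force <- function(x, arena, margin = 300) {
  f <- c(0, 0)
  for (d in 1:2) {
    if (x[d] < margin) f[d] <- f[d] + (margin - x[d]) / margin
    if (x[d] > arena - margin) f[d] <- f[d] - (x[d] - (arena - margin)) / margin
  }
  f
}

# Shared integrator: `steer(i, t, pos, head)` returns the desired
# direction for fish i; heading relaxes toward it with wrapped-normal
# noise; constant speed.
run_walkers <- function(config, init_pos, init_head, steer, turn_gain = 0.25) {
  n <- config$n_fish
  step_mm <- config$speed_mm_s / config$fps
  pos <- array(NA_real_, c(config$n_steps, n, 2))
  head_ <- init_head
  x <- init_pos
  for (t in seq_len(config$n_steps)) {
    pos[t, , ] <- x
    new_head <- head_
    for (i in seq_len(n)) {
      u <- c(cos(head_[i]), sin(head_[i]))
      des <- steer(i, t, x, head_)
      des <- unit(u * (1 - turn_gain) + unit(des) * turn_gain +
                    2 * wall_force(x[i, ], config$arena_mm))
      new_head[i] <- atan2(des[2], des[1]) + rnorm(1, 0, config$noise_sd)
    }
    head_ <- new_head
    x <- x + step_mm * cbind(cos(head_), sin(head_))
    x <- pmin(pmax(x, 1), config$arena_mm - 1)
  }
  trajectory(pos, fps = config$fps)
}

#' Boids-style cohesive school
#'
#' Standard cohesion / alignment / separation update with per-frame
#' heading noise in a bounded square arena.  With the default weights the
#' group stays cohesive (all pairwise distances typically well within
#' 400 mm) and cruises at the configured speed.
#'
#' @param config a [generator_config()].
#' @return a [trajectory()].
#' @export
boids_school <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_fish
  sep_dist <- 60
  with_seed(config$seed, {
    centre <- config$arena_mm / 2
    init_pos <- cbind(centre + runif(n, -100, 100),
                      centre + runif(n, -100, 100))
    init_head <- rep(runif(1, 0, 2 * pi), n) + rnorm(n, 0, 0.1)
    steer <- function(i, t, x, head_) {
      others <- setdiff(seq_len(n), i)
      align <- colMeans(cbind(cos(head_[others]), sin(head_[others])))
      coh <- unit(colMeans(x[others, , drop = FALSE]) - x[i, ])
      sep <- c(0, 0)
      for (j in others) {
        dv <- x[i, ] - x[j, ]
        dd <- sqrt(sum(dv^2))
        if (dd < sep_dist && dd > 1e-9) sep <- sep + dv / dd * (1 - dd / sep_dist)
      }
      config$alignment_w * unit(align) + config$cohesion_w * coh +
        config$separation_w * sep
    }
    run_walkers(config, init_pos, init_head, steer)
  })
}

#' Leader-follower chain
#'
#' Fish 1 performs a noisy persistent walk; every fish k > 1 steers
#' toward fish k - 1.  Followers start behind the leader and chase it,
#' guaranteeing a persistent positional leader (fish 1) for testing the
#' leadership statistics.
#'
#' @param config a [generator_config()]; `leader_bias` sets how strongly
#'   followers steer toward their predecessor.
#' @return a [trajectory()].
#' @export
leader_follower_chain <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_fish
  if (n < 2) stop("a leader-follower chain needs at least 2 fish")
  with_seed(config$seed, {
    centre <- config$arena_mm / 2
    head0 <- runif(1, 0, 2 * pi)
    u0 <- c(cos(head0), sin(head0))
    # chain strung out behind the leader
    init_pos <- t(vapply(seq_len(n), function(k)
      c(centre, centre) - (k - 1) * 120 * u0, numeric(2)))
    init_head <- rep(head0, n)
    steer <- function(i, t, x, head_) {
      if (i == 1L) {
        c(cos(head_[1]), sin(head_[1]))  # persistent walk (noise added outside)
      } else {
        u <- c(cos(head_[i]), sin(head_[i]))
        (1 - config$leader_bias) * u +
          config$leader_bias * unit(x[i - 1L, ] - x[i, ])
      }
    }
    run_walkers(config, init_pos, init_head, steer)
  })
}

#' Independent correlated random walkers
#'
#' No interactions: each fish performs its own persistent random walk
#' from a dispersed initialisation.  The null model: encoded collective
#' states carry no integration, so estimated TPMs approach
#' node-independence and Phi approaches 0.
#'
#' @param config a [generator_config()].
#' @return a [trajectory()].
#' @export
independent_walkers <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_fish
  with_seed(config$seed, {
    init_pos <- cbind(runif(n, 300, config$arena_mm - 300),
                      runif(n, 300, config$arena_mm - 300))
    init_head <- runif(n, 0, 2 * pi)
    steer <- function(i, t, x, head_) c(cos(head_[i]), sin(head_[i]))
    run_walkers(config, init_pos, init_head, steer)
  })
}

#' Random homogeneous Markov TPM
#'
#' Every conditional ON-probability drawn independently and uniformly on
#' `[0, 1]`: the abstract "randomly generated network" null model against
#' which real-data integrity statistics are contrasted.
#'
#' @param n_nodes number of nodes (2-6).
#' @param seed integer seed.
#' @return a [phi_tpm()].
#' @export
random_markov_tpm <- function(n_nodes, seed) {
  stopifnot(n_nodes >= 2, n_nodes <= 6)
  with_seed(seed, phi_tpm(matrix(runif(2^n_nodes * n_nodes),
                                 nrow = 2^n_nodes, ncol = n_nodes)))
}

#' Mean speed of a trajectory in mm/s
#'
#' @param traj a [trajectory()].
#' @return scalar mean speed over all individuals and steps.
#' @export
mean_speed <- function(traj) {
  v <- velocities(traj)
  mean(sqrt(v[, , 1]^2 + v[, , 2]^2)) * traj$fps
}
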