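# Leadership statistics: single-OFF state detection, positional leader,
# PL match rate, MIP-cut match rate, and the cohesion rate.

#' Index of the unique OFF individual in a collective state
#'
#' @param state 0/1 bit vector (one collective state).
#' @return the (1-based) index of the unique OFF individual, or 0 when
#'   the state is not a single-OFF state.
#' @examples
#' single_off_index(c(1, 0, 1, 1))  # 2
#' single_off_index(c(1, 1, 1, 1))  # 0
#' @export
single_off_index <- function(state) {
  off <- which(state == 0)
  if (length(off) == 1L) off else 0L
}

#' Positional leader at one time sample
#'
#' The individual furthest forward along the group's mean velocity
#' direction: the argmax of the projection of position onto the unit
#' mean-velocity vector.  Ties are broken by the lowest index.
#'
#' @param positions numeric `(N, 2)` matrix.
#' @param velocities_t numeric `(N, 2)` matrix of current velocities.
#' @return individual index, or `NA` when the mean velocity is (near)
#'   zero and the group direction is undefined.
#' @export
positional_leader <- function(positions, velocities_t) {
  v_mean <- colMeans(velocities_t)
  nv <- sqrt(sum(v_mean^2))
  if (nv < 1e-12) return(NA_integer_)
  proj <- as.vector(positions %*% (v_mean / nv))
  which.max(proj)  # which.max takes the first (lowest index) on ties
}

# Aligned positions/velocities for each encoded timestep of `seq`.
# Returns a list of (pos, vel) per step, using the sequence's time_index
# into the resampled trajectory.
seq_kinematics <- function(seq, traj) {
  rs <- resample(traj, attr(seq, "dt_frames"),
                 smooth_first = isTRUE(attr(seq, "flags")$smooth_first))
  v <- velocities(rs)
  n <- n_individuals(rs)
  idx <- attr(seq, "time_index")
  lapply(idx, function(t) {
    pos <- rs$positions[t, , ]; vel <- v[t - 1L, , ]
    dim(pos) <- dim(vel) <- c(n, 2)
    list(pos = pos, vel = vel)
  })
}

#' Positional-leader match rate
#'
#' Percentage of single-OFF timesteps at which the OFF individual is the
#' positional leader:
#' `100 * |{t : OFFsingle(t) = PLeader(t)}| / |{t : OFFsingle(t) > 0}|`.
#' Timesteps with an undefined positional leader (zero mean velocity) are
#' dropped from both numerator and denominator.
#'
#' @param seq a `state_seq` produced from `traj` (its `time_index` and
#'   `dt_frames` attributes align states with trajectory samples).
#' @param traj the [trajectory()] the sequence was encoded from.
#' @return list with `rate` (percent, `NA` when no single-OFF events),
#'   `n_events` and `n_matches`.
#' @export
pl_match_rate <- function(seq, traj) {
  kin <- seq_kinematics(seq, traj)
  off <- apply(unclass(seq), 1, single_off_index)
  n_events <- 0L; n_match <- 0L
  for (t in seq_len(nrow(seq))) {
    if (off[t] == 0L) next
    pl <- positional_leader(kin[[t]]$pos, kin[[t]]$vel)
    if (is.na(pl)) next
    n_events <- n_events + 1L
    if (pl == off[t]) n_match <- n_match + 1L
  }
  list(rate = if (n_events == 0) NA_real_ else 100 * n_match / n_events,
       n_events = n_events, n_matches = n_match)
}

#' MIP-cut match rate
#'
#' Over the single-OFF timesteps, the percentage at which the MIP system
#' cut of the observed collective state separates exactly the OFF
#' individual from the rest (in either direction).  The cut attached to a
#' state is computed once per state (states share cuts, not timesteps).
#'
#' @param phi_results a `phi_state_table` from [phi_per_state()] for the
#'   TPM estimated from `seq`.
#' @param seq the `state_seq`.
#' @return list with `rate` (percent, `NA` when no single-OFF events),
#'   `n_events` and `n_matches`.
#' @export
mip_cut_match_rate <- function(phi_results, seq) {
  results <- attr(phi_results, "results")
  m <- unclass(as.matrix(seq))
  n <- ncol(m)
  states <- as.integer(m %*% 2^(seq_len(n) - 1L))
  off <- apply(m, 1, single_off_index)
  n_events <- sum(off > 0)
  if (n_events == 0) {
    return(list(rate = NA_real_, n_events = 0L, n_matches = 0L))
  }
  # Pre-compute, per collective state, whether its MIP cut isolates the
  # single OFF individual of that state.
  match_by_state <- vapply(seq_along(results), function(si) {
    bits <- state_to_bits(si - 1L, n)
    i <- single_off_index(bits)
    if (i == 0L) return(FALSE)
    r <- results[[si]]
    rest <- setdiff(r$subsystem, i)
    (setequal(r$mip_cut$from, i) && setequal(r$mip_cut$to, rest)) ||
      (setequal(r$mip_cut$to, i) && setequal(r$mip_cut$from, rest))
  }, logical(1))
  n_match <- sum(match_by_state[states[off > 0] + 1L])
  list(rate = 100 * n_match / n_events, n_events = n_events,
       n_matches = as.integer(n_match))
}

#' Cohesion rate of a trajectory
#'
#' Percentage of timesteps at which every pairwise distance is within
#' (`<=`) the threshold.
#'
#' @param traj a [trajectory()].
#' @param threshold_mm distance threshold in mm (400 by default; 700 is
#'   conventionally reported in parentheses alongside).
#' @return percent in `[0, 100]`.
#' @export
cohesion_rate <- function(traj, threshold_mm = 400) {
  pos <- traj$positions
  t_n <- dim(pos)[1]
  coh <- vapply(seq_len(t_n), function(t) {
    p <- pos[t, , ]; dim(p) <- c(dim(pos)[2], 2)
    max(stats::dist(p)) <= threshold_mm
  }, logical(1))
  100 * mean(coh)
}

#' Full leadership / integrity report for one dataset
#'
#' Runs encode -> TPM -> per-state Phi -> match rates for one threshold
#' setting and timescale, the row format used for rate tables.
#'
#' @param traj a [trajectory()].
#' @param thresholds a [local_thresholds()] or [global_thresholds()].
#' @param dt_frames resampling stride.
#' @param scope passed to [phi_per_state()].
#' @param ... encoder convention flags.
#' @return a `match_report`: list with the state sequence summary, the
#'   per-state Phi table, `n_single_off_events`, `pl_match_rate`,
#'   `mip_cut_match_rate`, `cohesion_rate` (400 and 700 mm), mean Phi by
#'   number of ON bits, and the occupancy of the two dominant states.
#' @export
match_report <- function(traj, thresholds, dt_frames = 1,
                         scope = c("main_complex", "full_system"), ...) {
  scope <- match.arg(scope)
  seq_ <- if (inherits(thresholds, "local_thresholds")) {
    local_collective_state(traj, thresholds, dt_frames, ...)
  } else {
    global_collective_state(traj, thresholds, dt_frames, ...)
  }
  tpm <- estimate_tpm(seq_)
  tab <- phi_per_state(tpm, scope = scope)
  pl <- pl_match_rate(seq_, traj)
  mip <- mip_cut_match_rate(tab, seq_)
  n <- n_individuals(traj)
  on_count <- rowSums(all_state_bits(n))
  phi_by_on <- tapply(tab$phi, on_count, mean)
  structure(list(
    n = n, dt_frames = dt_frames,
    thresholds = thresholds,
    scope = scope,
    n_single_off_events = mip$n_events,
    pl_match_rate = pl$rate,
    mip_cut_match_rate = mip$rate,
    cohesion_rate = cohesion_rate(traj, 400),
    cohesion_rate_700 = cohesion_rate(traj, 700),
    phi_by_on_count = phi_by_on,
    occupancy = state_occupancy(seq_),
    phi_table = tab), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  fmt <- function(r) if (is.na(r)) "undefined" else sprintf("%.1f%%", r)
  cat(sprintf("Match report (N = %d, dt = %d frames, scope = %s)\n",
              x$n, x$dt_frames, x$scope))
  cat("  single-OFF events:   ", x$n_single_off_events, "\n")
  cat("  PL match rate:       ", fmt(x$pl_match_rate), "\n")
  cat("  MIP-cut match rate:  ", fmt(x$mip_cut_match_rate), "\n")
  cat(sprintf("  cohesion rate:        %.1f%% (%.1f%% at 700 mm)\n",
              x$cohesion_rate, x$cohesion_rate_700))
  invisible(x)
}

#' JSON serialisation of a match report
#'
#' @param x a `match_report`.
#' @param path optional output file.
#' @return JSON string.
#' @export
match_report_json <- function(x, path = NULL) {
  obj <- x[c("n", "dt_frames", "scope", "n_single_off_events",
             "pl_match_rate", "mip_cut_match_rate", "cohesion_rate",
             "cohesion_rate_700")]
  obj$thresholds <- unclass(x$thresholds)
  obj$phi_by_on_count <- as.list(x$phi_by_on_count)
  out <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}
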