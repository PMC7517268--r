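# Binarization of 2-D trajectories into collective states.
#
# A trajectory holds positions (mm) for N individuals on a uniform time
# base (120 fps by default).  The encoders reproduce the two threshold
# families used for fish schools:
#   local:  ON = (some neighbour closer than xi_D)  AND
#                (some neighbour inside the visual field of width xi_VF) AND
#                (own turning rate >= xi_TR)
#   global: ON = (heading within Xi_AD of the mean direction)  AND
#                (position within Xi_CM of the centre of mass)
# Comparison conventions follow the source definitions exactly:
# distance and visual field use strict `<`, turning uses `>=`, both global
# conditions use `<=`.

#' Construct a trajectory object
#'
#' @param positions numeric array `(time, individual, 2)` of x/y positions
#'   in millimetres, on a uniform time base.
#' @param fps frames per second of the time base (120 for the raw data
#'   this package emulates).
#' @param ids optional individual labels.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(positions, fps = 120, ids = NULL) {
  stopifnot(is.array(positions), length(dim(positions)) == 3,
            dim(positions)[3] == 2)
  n <- dim(positions)[2]
  if (n < 2 || n > 6) stop("trajectories must track 2..6 individuals")
  if (anyNA(positions)) stop("trajectories must have no missing frames")
  structure(list(positions = positions, fps = fps,
                 ids = ids %||% paste0("fish", seq_len(n))),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d individuals, %d frames @ %g fps (%.1f s)\n",
              n_individuals(x), n_frames(x), x$fps, n_frames(x) / x$fps))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a `trajectory`.
#' @export
n_individuals <- function(traj) dim(traj$positions)[2]

#' @rdname trajectory
#' @export
n_frames <- function(traj) dim(traj$positions)[1]

#' Read / write trajectories as CSV
#'
#' Long format with header `frame,id,x_mm,y_mm`; every individual must be
#' present at every frame.
#'
#' @param path file path.
#' @param fps frames per second recorded in the file's time base.
#' @return `read_trajectory_csv()` returns a [trajectory()].
#' @export
read_trajectory_csv <- function(path, fps = 120) {
  d <- read.csv(path)
  need <- c("frame", "id", "x_mm", "y_mm")
  if (!all(need %in% names(d))) {
    stop("trajectory CSV must have columns frame,id,x_mm,y_mm: ", path)
  }
  ids <- sort(unique(d$id))
  frames <- sort(unique(d$frame))
  if (nrow(d) != length(ids) * length(frames)) {
    stop("trajectory CSV has missing frame/id combinations: ", path)
  }
  if (length(frames) > 1 && length(unique(diff(frames))) != 1) {
    stop("trajectory CSV frames are not uniformly spaced: ", path)
  }
  pos <- array(NA_real_, c(length(frames), length(ids), 2))
  d <- d[order(d$frame, match(d$id, ids)), ]
  pos[, , 1] <- matrix(d$x_mm, nrow = length(frames), byrow = TRUE)
  pos[, , 2] <- matrix(d$y_mm, nrow = length(frames), byrow = TRUE)
  trajectory(pos, fps = fps, ids = as.character(ids))
}

#' @rdname read_trajectory_csv
#' @param traj a [trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  t_n <- n_frames(traj); n <- n_individuals(traj)
  d <- data.frame(
    frame = rep(seq_len(t_n), each = n),
    id = rep(traj$ids, times = t_n),
    x_mm = as.vector(t(traj$positions[, , 1])),
    y_mm = as.vector(t(traj$positions[, , 2])))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Resample a trajectory to a coarser timescale
#'
#' Takes every `dt_frames`-th sample (stride first) and then smooths each
#' coordinate with a centred unweighted 3-point moving average, truncating
#' the ends.  The resulting step length is `dt_frames / fps` seconds.  Set
#' `smooth_first = TRUE` to smooth on the raw time base before striding.
#'
#' @param traj a [trajectory()].
#' @param dt_frames positive integer stride; the analyses in this package
#'   use 5, 10, 20, 40, 80 and 120 frames (at 120 fps these give
#'   timescales 5/120 .. 120/120 s).
#' @param smooth_first smooth before striding instead of after.
#' @return a resampled `trajectory` with attributes `dt_frames` and
#'   `dt_seconds`.
#' @export
resample <- function(traj, dt_frames, smooth_first = FALSE) {
  stopifnot(inherits(traj, "trajectory"), dt_frames >= 1)
  dt_frames <- as.integer(dt_frames)
  smooth3 <- function(pos) {
    t_n <- dim(pos)[1]
    if (t_n < 3) stop("too few samples for 3-point smoothing (need >= 3)")
    (pos[1:(t_n - 2), , , drop = FALSE] +
       pos[2:(t_n - 1), , , drop = FALSE] +
       pos[3:t_n, , , drop = FALSE]) / 3
  }
  pos <- traj$positions
  if (smooth_first) {
    pos <- smooth3(pos)
    pos <- pos[seq(1, dim(pos)[1], by = dt_frames), , , drop = FALSE]
  } else {
    pos <- pos[seq(1, dim(pos)[1], by = dt_frames), , , drop = FALSE]
    pos <- smooth3(pos)
  }
  out <- trajectory(pos, fps = traj$fps, ids = traj$ids)
  attr(out, "dt_frames") <- dt_frames
  attr(out, "dt_seconds") <- dt_frames / traj$fps
  out
}

#' Per-step velocity vectors of a (resampled) trajectory
#'
#' `v_i(t) = x_i(t) - x_i(t - 1 step)` on the trajectory's own time base;
#' the first step is dropped, so `velocities(traj)[t - 1, , ]` is the
#' velocity at sample `t`.
#'
#' @param traj a [trajectory()] (usually the output of [resample()]).
#' @return numeric array `(time - 1, individual, 2)` in mm per step.
#' @export
velocities <- function(traj) {
  pos <- traj$positions
  t_n <- dim(pos)[1]
  if (t_n < 2) stop("need at least 2 samples to compute velocities")
  pos[2:t_n, , , drop = FALSE] - pos[1:(t_n - 1), , , drop = FALSE]
}

#' Threshold settings
#'
#' `local_thresholds()` bundles the three local interaction thresholds;
#' `global_thresholds()` the two global (mean-field) thresholds.
#'
#' @param xi_D distance threshold, mm (> 0).
#' @param xi_VF total visual-field width, rad, in (0, 2*pi]; a neighbour
#'   is seen when the angle between the focal fish's velocity and the
#'   direction to the neighbour is below `xi_VF / 2` (see Details).
#' @param xi_TR turning-rate threshold, rad per step (>= 0).
#' @return a `local_thresholds` / `global_thresholds` object.
#'
#' @details The literal source formula compares the full angle (which
#'   lives in `[0, pi]`) against `xi_VF`, making every width above `pi`
#'   equivalent to a complete field; since distinct behaviour is reported
#'   for widths between `pi` and `2*pi`, this package reads `xi_VF` as the
#'   *total* field width and compares the angle against `xi_VF / 2`.  The
#'   literal reading is available via the `vf_half_angle` encoder flag.
#' @export
local_thresholds <- function(xi_D, xi_VF, xi_TR) {
  stopifnot(xi_D > 0, xi_VF > 0, xi_VF <= 2 * pi, xi_TR >= 0)
  structure(list(xi_D = xi_D, xi_VF = xi_VF, xi_TR = xi_TR),
            class = "local_thresholds")
}

#' @rdname local_thresholds
#' @param Xi_AD maximum angular deviation from the mean group direction,
#'   rad (> 0).
#' @param Xi_CM maximum distance from the centre of mass, mm (> 0).
#' @export
global_thresholds <- function(Xi_AD, Xi_CM) {
  stopifnot(Xi_AD > 0, Xi_CM > 0)
  structure(list(Xi_AD = Xi_AD, Xi_CM = Xi_CM),
            class = "global_thresholds")
}

# ---- per-parameter bit functions ----------------------------------------

#' Per-parameter binary states
#'
#' The three local bit functions, exposed individually for testing and
#' exploratory use.  All operate on one time sample.
#'
#' `distance_state()`: 1 iff some other individual is strictly closer
#' than `xi_D`.
#' `visual_field_state()`: 1 iff some other individual lies within the
#' visual field of total width `xi_VF` around the focal velocity vector
#' (0 with a warning if the focal fish has zero velocity).
#' `turning_state()`: 1 iff the angle between the current and previous
#' velocity is `>= xi_TR`.
#'
#' @param positions numeric `(N, 2)` matrix of positions at one sample.
#' @param xi_D,xi_VF,xi_TR thresholds, see [local_thresholds()].
#' @return integer vector of N bits.
#' @export
distance_state <- function(positions, xi_D) {
  d <- as.matrix(stats::dist(positions))
  diag(d) <- Inf
  as.integer(apply(d < xi_D, 1, any))
}

#' @rdname distance_state
#' @param velocities_t numeric `(N, 2)` matrix of current velocities.
#' @param vf_half_angle compare the angle against `xi_VF / 2` (default;
#'   `FALSE` restores the literal full-angle reading).
#' @param view_toward_neighbour use the vector from the focal fish toward
#'   the neighbour (default).  `FALSE` restores the literal self-minus-
#'   neighbour vector, which points *away* from the neighbour and turns
#'   the visual field into a rear-facing one (angle becomes `pi - angle`).
#' @export
visual_field_state <- function(positions, velocities_t, xi_VF,
                               vf_half_angle = TRUE,
                               view_toward_neighbour = TRUE) {
  n <- nrow(positions)
  lim <- if (vf_half_angle) xi_VF / 2 else xi_VF
  # a half-angle of pi covers the whole plane: the complete visual field
  # (xi_VF = 2*pi) must see a neighbour exactly astern (angle == pi)
  if (lim >= pi) lim <- Inf
  out <- integer(n)
  for (i in seq_len(n)) {
    v <- velocities_t[i, ]
    if (sqrt(sum(v^2)) < 1e-12) { out[i] <- 0L; next }
    others <- setdiff(seq_len(n), i)
    rel <- positions[others, , drop = FALSE] -
      matrix(positions[i, ], length(others), 2, byrow = TRUE)
    if (!view_toward_neighbour) rel <- -rel
    ang <- vector_angle(matrix(v, length(others), 2, byrow = TRUE), rel)
    out[i] <- as.integer(any(ang < lim, na.rm = TRUE))
  }
  out
}

#' @rdname distance_state
#' @param velocities_prev numeric `(N, 2)` matrix of previous velocities.
#' @export
turning_state <- function(velocities_t, velocities_prev, xi_TR) {
  ang <- vector_angle(velocities_t, velocities_prev)
  out <- as.integer(ang >= xi_TR)
  out[is.na(ang)] <- 0L  # zero velocity: heading undefined
  out
}

# ---- collective-state encoders ------------------------------------------

new_state_seq <- function(states, thresholds, dt_frames, fps, setting,
                          time_index, n_zero_velocity, flags = list()) {
  structure(states,
            thresholds = thresholds, dt_frames = dt_frames, fps = fps,
            dt_seconds = dt_frames / fps, setting = setting,
            time_index = time_index, n_zero_velocity = n_zero_velocity,
            flags = flags, class = c("state_seq", "matrix"))
}

#' @export
print.state_seq <- function(x, ...) {
  cat(sprintf("Collective-state sequence: %d steps x %d individuals (%s setting, dt = %d frames)\n",
              nrow(x), ncol(x), attr(x, "setting"), attr(x, "dt_frames")))
  invisible(x)
}

#' Encode a trajectory into local collective states
#'
#' Resamples the trajectory to the requested timescale, computes the
#' distance, visual-field and turning-rate bits per individual, and takes
#' their conjunction (AND).  The sequence starts at the third resampled
#' point, where both the velocity and the previous-step velocity exist.
#'
#' @param traj a [trajectory()].
#' @param thresholds a [local_thresholds()].
#' @param dt_frames resampling stride in frames.
#' @param vf_half_angle,view_toward_neighbour,smooth_first convention
#'   flags; see [visual_field_state()] and [resample()].
#' @return a `state_seq`: integer 0/1 matrix `(time, individual)` with
#'   threshold, timescale and convention metadata as attributes, plus the
#'   number of zero-velocity samples encountered (`n_zero_velocity`
#'   attribute) and the resampled-trajectory time indices (`time_index`).
#' @export
local_collective_state <- function(traj, thresholds, dt_frames = 1,
                                   vf_half_angle = TRUE,
                                   view_toward_neighbour = TRUE,
                                   smooth_first = FALSE) {
  stopifnot(inherits(thresholds, "local_thresholds"))
  rs <- resample(traj, dt_frames, smooth_first = smooth_first)
  v <- velocities(rs)
  t_n <- n_frames(rs)
  if (t_n < 3) stop("resampled trajectory too short to encode")
  n <- n_individuals(rs)
  steps <- 3:t_n  # need v(t) and v(t-1)
  states <- matrix(0L, length(steps), n)
  zero_v <- 0L
  for (s in seq_along(steps)) {
    t <- steps[s]
    pos_t <- rs$positions[t, , ]
    v_t <- v[t - 1L, , , drop = TRUE]
    v_p <- v[t - 2L, , , drop = TRUE]
    dim(v_t) <- dim(v_p) <- c(n, 2)
    dim(pos_t) <- c(n, 2)
    zero_v <- zero_v + sum(sqrt(rowSums(v_t^2)) < 1e-12)
    d_bit <- distance_state(pos_t, thresholds$xi_D)
    b_bit <- visual_field_state(pos_t, v_t, thresholds$xi_VF,
                                vf_half_angle, view_toward_neighbour)
    t_bit <- turning_state(v_t, v_p, thresholds$xi_TR)
    states[s, ] <- d_bit * b_bit * t_bit
  }
  if (zero_v > 0) {
    warning(zero_v, " zero-velocity samples: visual-field/turning bits set to 0")
  }
  new_state_seq(states, thresholds, as.integer(dt_frames), traj$fps, "local",
                steps, zero_v,
                list(vf_half_angle = vf_half_angle,
                     view_toward_neighbour = view_toward_neighbour,
                     smooth_first = smooth_first))
}

#' Encode a trajectory into global collective states
#'
#' ON requires both alignment with the mean group direction (angle
#' `<= Xi_AD`) and proximity to the centre of mass (distance `<= Xi_CM`).
#' The sequence starts at the second resampled point (velocities needed).
#'
#' @inheritParams local_collective_state
#' @param thresholds a [global_thresholds()].
#' @return a `state_seq`, as for [local_collective_state()].
#' @export
global_collective_state <- function(traj, thresholds, dt_frames = 1,
                                    smooth_first = FALSE) {
  stopifnot(inherits(thresholds, "global_thresholds"))
  rs <- resample(traj, dt_frames, smooth_first = smooth_first)
  v <- velocities(rs)
  t_n <- n_frames(rs)
  n <- n_individuals(rs)
  steps <- 2:t_n
  states <- matrix(0L, length(steps), n)
  zero_v <- 0L
  for (s in seq_along(steps)) {
    t <- steps[s]
    pos_t <- rs$positions[t, , ]
    v_t <- v[t - 1L, , , drop = TRUE]
    dim(v_t) <- c(n, 2); dim(pos_t) <- c(n, 2)
    v_mean <- colMeans(v_t)
    x_mean <- colMeans(pos_t)
    ang <- vector_angle(v_t, matrix(v_mean, n, 2, byrow = TRUE))
    avd <- as.integer(ang <= thresholds$Xi_AD)
    avd[is.na(ang)] <- 0L
    zero_v <- zero_v + sum(is.na(ang))
    com <- as.integer(sqrt(rowSums(
      (pos_t - matrix(x_mean, n, 2, byrow = TRUE))^2)) <= thresholds$Xi_CM)
    states[s, ] <- avd * com
  }
  if (zero_v > 0) {
    warning(zero_v, " undefined headings: alignment bits set to 0")
  }
  new_state_seq(states, thresholds, as.integer(dt_frames), traj$fps, "global",
                steps, zero_v, list(smooth_first = smooth_first))
}

#' Write a collective-state sequence as CSV (+ JSON sidecar)
#'
#' @param seq a `state_seq`.
#' @param path output CSV (`t,bit_1,...,bit_N`); a `.json` sidecar with
#'   thresholds, timescale and convention flags is written next to it.
#' @export
write_state_seq <- function(seq, path) {
  d <- as.data.frame(unclass(seq))
  names(d) <- paste0("bit_", seq_len(ncol(seq)))
  d <- cbind(t = attr(seq, "time_index"), d)
  write.csv(d, path, row.names = FALSE)
  meta <- list(thresholds = unclass(attr(seq, "thresholds")),
               dt_frames = attr(seq, "dt_frames"),
               dt_seconds = attr(seq, "dt_seconds"),
               setting = attr(seq, "setting"),
               flags = attr(seq, "flags"),
               n_zero_velocity = attr(seq, "n_zero_velocity"))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
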