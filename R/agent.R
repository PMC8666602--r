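# Two-wheeled agent kinematics: four movement types (each wheel slow or
# fast), binary whisker sensors, wall-collision death.

# Movement constants. Both wheels fast: 0.6 length units straight; both
# slow: 0.2; one fast, one slow: a 10 degree turn toward the slow wheel with
# displacement 0.4 (the approximate turn is frozen to exactly 10 degrees for
# reproducibility).
.LF_SPEED_FAST <- 0.6
.LF_SPEED_SLOW <- 0.2
.LF_SPEED_TURN <- 0.4
.LF_TURN_RAD <- 10 * pi / 180

#' Sensor and body configuration
#'
#' @param length Sensor length in length units (the experiments sweep 0.5 to
#'   2.75).
#' @param mount_angles Mount angles of the two sensors relative to the
#'   heading, in radians (default +30 and -30 degrees).
#' @param body_radius Radius of the circular body.
#' @return An object of class `sensor_config`.
#' @export
sensor_config <- function(length, mount_angles = c(pi / 6, -pi / 6),
                          body_radius = 0.5) {
  stopifnot(length > 0, length(mount_angles) == 2L, body_radius > 0)
  structure(list(length = length, mount_angles = mount_angles,
                 body_radius = body_radius), class = "sensor_config")
}

#' Agent pose
#'
#' @param x,y Position of the body centre.
#' @param heading Heading in radians (wrapped to `[0, 2*pi)`).
#' @param alive Logical; death is absorbing.
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(x, y, heading, alive = TRUE) {
  structure(list(x = x, y = y, heading = heading %% (2 * pi), alive = alive),
            class = "agent_state")
}

#' Wheel command
#'
#' Each wheel spins either `"slow"` or `"fast"`, giving exactly four distinct
#' movements; the agents cannot stop.
#'
#' @param left,right `"slow"` or `"fast"`.
#' @return An object of class `move_command`.
#' @export
move_command <- function(left, right) {
  left <- match.arg(left, c("slow", "fast"))
  right <- match.arg(right, c("slow", "fast"))
  structure(list(left = left, right = right), class = "move_command")
}

# Vectorized kinematics: rotate-then-translate. lf, rf: logical "wheel is
# fast". Returns list(x, y, heading).
.lf_advance <- function(x, y, heading, lf, rf) {
  dh <- ifelse(lf & !rf, -.LF_TURN_RAD, ifelse(rf & !lf, .LF_TURN_RAD, 0))
  sp <- ifelse(lf & rf, .LF_SPEED_FAST, ifelse(!lf & !rf, .LF_SPEED_SLOW,
                                               .LF_SPEED_TURN))
  h <- (heading + dh) %% (2 * pi)
  list(x = x + sp * cos(h), y = y + sp * sin(h), heading = h)
}

#' Advance an agent by one movement
#'
#' Applies the commanded movement (fast/fast: 0.6 straight; slow/slow: 0.2;
#' mixed: rotate exactly 10 degrees toward the slow wheel, then translate
#' 0.4) and kills the agent if its body circle touches any wall after the
#' move.
#'
#' @param state A living [agent_state()].
#' @param move A [move_command()].
#' @param track A [make_track()] object (may have zero walls for open-space
#'   kinematics tests).
#' @param cfg A [sensor_config()] (supplies the body radius).
#' @return The new `agent_state`; `alive` is `FALSE` iff the body touches a
#'   wall at the new pose.
#' @examples
#' tr <- default_track()
#' cfg <- sensor_config(length = 1)
#' st <- agent_state(0, -9.5, 0)
#' step_agent(st, move_command("fast", "fast"), tr, cfg)
#' @export
step_agent <- function(state, move, track, cfg = sensor_config(1)) {
  stopifnot(inherits(state, "agent_state"), inherits(move, "move_command"))
  if (!state$alive) stop("cannot step a dead agent (death is absorbing)")
  nw <- .lf_advance(state$x, state$y, state$heading,
                    move$left == "fast", move$right == "fast")
  alive <- TRUE
  if (nrow(track$walls) > 0L) {
    alive <- .lf_min_wall_dist(nw$x, nw$y, track$walls) > cfg$body_radius
  }
  agent_state(nw$x, nw$y, nw$heading, alive)
}

# Sensor segment endpoints for vectorized poses; k indexes the sensor.
.lf_sensor_segment <- function(x, y, heading, cfg, k) {
  th <- heading + cfg$mount_angles[k]
  list(x1 = x + cfg$body_radius * cos(th), y1 = y + cfg$body_radius * sin(th),
       x2 = x + (cfg$body_radius + cfg$length) * cos(th),
       y2 = y + (cfg$body_radius + cfg$length) * sin(th))
}

# Vectorized sensor readings; returns n x 2 integer matrix.
.lf_read_sensors_vec <- function(x, y, heading, track, cfg) {
  out <- matrix(0L, nrow = length(x), ncol = 2L)
  if (nrow(track$walls) == 0L) return(out)
  for (k in 1:2) {
    s <- .lf_sensor_segment(x, y, heading, cfg, k)
    out[, k] <- as.integer(.lf_hits_any_wall(s$x1, s$y1, s$x2, s$y2,
                                             track$walls))
  }
  out
}

#' Read the binary whisker sensors
#'
#' Each sensor is a straight segment anchored at the body perimeter, of
#' length `cfg$length`, at its mount angle relative to the heading. A sensor
#' reports 1 iff its segment touches any wall; no distance is reported.
#'
#' @inheritParams step_agent
#' @return Integer vector of length two (left sensor first).
#' @export
read_sensors <- function(state, track, cfg) {
  stopifnot(inherits(state, "agent_state"))
  if (!state$alive) stop("cannot read sensors of a dead agent")
  as.integer(.lf_read_sensors_vec(state$x, state$y, state$heading, track, cfg))
}

#' Draw a random collision-free pose
#'
#' Uniform rejection sampling over the corridor and heading until the body
#' circle clears every wall. Uses the current RNG state.
#'
#' @inheritParams step_agent
#' @param max_tries Abort with an error after this many consecutive
#'   rejections (signals a degenerate geometry configuration).
#' @return A living [agent_state()].
#' @export
random_pose <- function(track, cfg, max_tries = 1e5) {
  bb <- track$bbox
  for (i in seq_len(max_tries)) {
    x <- stats::runif(1, bb["xmin"], bb["xmax"])
    y <- stats::runif(1, bb["ymin"], bb["ymax"])
    if (!.lf_in_corridor(x, y, track)) next
    if (.lf_min_wall_dist(x, y, track$walls) <= cfg$body_radius) next
    return(agent_state(x, y, stats::runif(1, 0, 2 * pi)))
  }
  stop("could not place an agent after ", max_tries,
       " tries; check the track geometry")
}

# Vectorized batch of random poses (rejection sampling in chunks).
.lf_random_poses <- function(n, track, cfg, max_tries = 1e5) {
  bb <- track$bbox
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 64L)
    tries <- tries + m
    if (tries > max_tries * max(n, 1)) {
      stop("could not place agents; check the track geometry")
    }
    x <- stats::runif(m, bb["xmin"], bb["xmax"])
    y <- stats::runif(m, bb["ymin"], bb["ymax"])
    ok <- .lf_in_corridor(x, y, track)
    ok[ok] <- .lf_min_wall_dist(x[ok], y[ok], track$walls) > cfg$body_radius
    xs <- c(xs, x[ok]); ys <- c(ys, y[ok])
  }
  list(x = xs[seq_len(n)], y = ys[seq_len(n)],
       heading = stats::runif(n, 0, 2 * pi))
}

#' Simulate a random-policy trajectory
#'
#' Rolls one agent forward under uniformly random wheel commands, respawning
#' on death, and records the per-step pose, sensor bits, action bits and
#' alive flag. Intended for visual debugging with [autoplot.track()].
#'
#' @inheritParams step_agent
#' @param n_steps Number of recorded steps.
#' @return A tibble with columns `step`, `episode`, `x`, `y`, `heading`,
#'   `s1`, `s2`, `a1`, `a2`, `alive`.
#' @export
simulate_trajectory <- function(track, cfg, n_steps = 200L) {
  st <- random_pose(track, cfg)
  episode <- 1L
  rows <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    s <- .lf_read_sensors_vec(st$x, st$y, st$heading, track, cfg)
    lf <- stats::runif(1) < 0.5
    rf <- stats::runif(1) < 0.5
    rows[[i]] <- tibble::tibble(
      step = i, episode = episode, x = st$x, y = st$y, heading = st$heading,
      s1 = s[1], s2 = s[2], a1 = as.integer(lf), a2 = as.integer(rf),
      alive = st$alive)
    mv <- move_command(if (lf) "fast" else "slow", if (rf) "fast" else "slow")
    st <- step_agent(st, mv, track, cfg)
    if (!st$alive) {
      st <- random_pose(track, cfg)
      episode <- episode + 1L
    }
  }
  dplyr::bind_rows(rows)
}
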