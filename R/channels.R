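# Monte-Carlo estimation of the intrinsic environment channels: the sensor
# channel gamma = P(S_{t+1} | S_t, A_t), the initial coupling P(S_t | A_t)
# and the goal channel P(G | S_t..S_{t+2}, A_t..A_{t+2}) with g = 1 iff the
# agent survives the two movements of the window.
#
# Rollouts use uniformly random wheel commands from random poses. A dead
# agent's pose freezes at the colliding pose; sensor readings keep being
# taken there and actions keep being drawn (but not executed) for the two
# records needed to close open goal windows, after which the walker
# respawns. Transitions into death feed the goal channel but not gamma,
# which conditions on the loop continuing.

#' Additive smoothing and row normalization of a count table
#'
#' Converts an integer count tensor into a strictly positive conditional
#' table: each entry becomes `(count + eps) / (row_total + eps * row_size)`,
#' where a row is one given-context. Strict positivity of all loop
#' distributions is a standing assumption of the framework; `eps` pseudo
#' counts guarantee it.
#'
#' @param counts Numeric array; the first `n_target_dims` dimensions index
#'   the target variables, the rest the given-context.
#' @param eps Pseudo count per cell (> 0 unless every context has counts).
#' @param n_target_dims Number of leading target dimensions.
#' @return A numeric array of the same shape with every context summing to
#'   one and (for `eps > 0`) all entries positive.
#' @examples
#' smooth_and_normalize(array(c(0, 0), 2), eps = 1, n_target_dims = 1)
#' @export
smooth_and_normalize <- function(counts, eps = 1, n_target_dims = 1L) {
  d <- dim(counts)
  if (is.null(d)) d <- length(counts)
  nt <- prod(d[seq_len(n_target_dims)])
  m <- matrix(as.numeric(counts), nrow = nt) + eps
  tot <- colSums(m)
  if (any(tot <= 0)) stop("all-zero context with eps = 0; cannot normalize")
  array(as.vector(sweep(m, 2, tot, "/")), dim = d)
}

.lf_goal_givens <- function() {
  as.vector(vapply(c("t", "t+1", "t+2"), function(s)
    paste0(c("S1", "S2", "A1", "A2"), "_", s), character(4)))
}

#' Sample the sensor and goal channels for one sensor length
#'
#' Runs vectorized random-policy rollouts on a track and tabulates (i) the
#' consecutive living triples (s_t, a_t, s_{t+1}) for the sensor channel and
#' (ii) the three-slice windows (s, a at t, t+1, t+2) with g = 1 iff the
#' agent is alive at the end of the window, for the goal channel. Episodes
#' are capped so pose coverage stays broad; on death a fresh random pose
#' restarts the episode.
#'
#' When `seed` is given the RNG is seeded with
#' `seed + round(sensor_length * 100)`, giving one independent, reproducible
#' run per sensor length.
#'
#' @param track A [make_track()] object.
#' @param cfg A [sensor_config()].
#' @param n_samples Total recorded steps (>= 1e4; default 2e5 is the
#'   desk-scale protocol, 2e7 reproduces the published scale).
#' @param smoothing_eps Pseudo count per cell, see [smooth_and_normalize()].
#' @param seed Optional integer base seed.
#' @param n_walkers Number of parallel rollout walkers (vectorized; affects
#'   only speed and the RNG stream, not the sampled distribution).
#' @param episode_cap Maximum records per episode before a respawn.
#' @return A list with elements `sensor` (class `sensor_channel`: `gamma`,
#'   `s_given_a`, `counts`, `n_samples`, `sensor_length`, `seed`, `eps`) and
#'   `goal` (class `goal_channel`: `table`, `counts`, `n_windows`).
#' @export
sample_channels <- function(track, cfg, n_samples = 2e5, smoothing_eps = 1,
                            seed = NULL, n_walkers = 1024L,
                            episode_cap = 500L) {
  if (n_samples < 1e4) stop("n_samples must be at least 1e4")
  if (!is.null(seed)) set.seed(as.integer(seed + round(cfg$length * 100)))

  nw <- as.integer(n_walkers)
  total_steps <- ceiling(n_samples / nw)
  pose <- .lf_random_poses(nw, track, cfg)
  x <- pose$x; y <- pose$y; h <- pose$heading
  alive <- rep(TRUE, nw)
  dead_records <- integer(nw)
  ep_id <- seq_len(nw)
  next_ep <- nw + 1L
  ep_steps <- integer(nw)

  cnt_gamma <- integer(64)        # [s'(4), s(4), a(4)]
  cnt_goal <- integer(8192)       # [g(2), s,a,s',a',s'',a'' (4 each)]
  n_windows <- 0L

  chunk <- 1024L
  # carried rows from the previous chunk (none initially)
  cs <- ca <- cal <- cep <- NULL

  count_chunk <- function(S, A, AL, EP, first) {
    # S, A: integer matrices (rows = time, cols = walkers), values 1..4
    T_ <- nrow(S)
    if (T_ >= 2L) {
      t0 <- if (first) 1L else 2L
      if (T_ - 1L >= t0) {
        tt <- t0:(T_ - 1L)
        ok <- AL[tt, , drop = FALSE] & AL[tt + 1L, , drop = FALSE] &
          (EP[tt, , drop = FALSE] == EP[tt + 1L, , drop = FALSE])
        if (any(ok)) {
          lin <- S[tt + 1L, , drop = FALSE][ok] +
            4L * (S[tt, , drop = FALSE][ok] - 1L) +
            16L * (A[tt, , drop = FALSE][ok] - 1L)
          cnt_gamma <<- cnt_gamma + tabulate(lin, nbins = 64L)
        }
      }
    }
    if (T_ >= 3L) {
      tt <- 1:(T_ - 2L)
      ok <- AL[tt, , drop = FALSE] &
        (EP[tt, , drop = FALSE] == EP[tt + 1L, , drop = FALSE]) &
        (EP[tt, , drop = FALSE] == EP[tt + 2L, , drop = FALSE])
      if (any(ok)) {
        g <- as.integer(AL[tt + 2L, , drop = FALSE][ok])   # 0 dead, 1 alive
        lin <- (g + 1L) +
          2L * (S[tt, , drop = FALSE][ok] - 1L) +
          8L * (A[tt, , drop = FALSE][ok] - 1L) +
          32L * (S[tt + 1L, , drop = FALSE][ok] - 1L) +
          128L * (A[tt + 1L, , drop = FALSE][ok] - 1L) +
          512L * (S[tt + 2L, , drop = FALSE][ok] - 1L) +
          2048L * (A[tt + 2L, , drop = FALSE][ok] - 1L)
        cnt_goal <<- cnt_goal + tabulate(lin, nbins = 8192L)
        n_windows <<- n_windows + sum(ok)
      }
    }
  }

  done <- 0L
  first <- TRUE
  while (done < total_steps) {
    k <- min(chunk, total_steps - done)
    nrow_buf <- k + if (first) 0L else 2L
    S <- matrix(0L, nrow_buf, nw); A <- matrix(0L, nrow_buf, nw)
    AL <- matrix(FALSE, nrow_buf, nw); EP <- matrix(0L, nrow_buf, nw)
    r0 <- 0L
    if (!first) {
      S[1:2, ] <- cs; A[1:2, ] <- ca; AL[1:2, ] <- cal; EP[1:2, ] <- cep
      r0 <- 2L
    }
    for (i in seq_len(k)) {
      sb <- .lf_read_sensors_vec(x, y, h, track, cfg)
      s_idx <- 1L + sb[, 1] + 2L * sb[, 2]
      a_idx <- sample.int(4L, nw, replace = TRUE)
      r <- r0 + i
      S[r, ] <- s_idx; A[r, ] <- a_idx; AL[r, ] <- alive; EP[r, ] <- ep_id
      ep_steps <- ep_steps + 1L
      dead_records <- dead_records + as.integer(!alive)

      lf <- a_idx == 2L | a_idx == 4L     # bit 1: left wheel fast
      rf <- a_idx >= 3L                   # bit 2: right wheel fast
      mv <- .lf_advance(x, y, h, lf, rf)
      live <- alive
      x[live] <- mv$x[live]; y[live] <- mv$y[live]; h[live] <- mv$heading[live]
      if (any(live)) {
        died <- live
        died[live] <- .lf_min_wall_dist(x[live], y[live], track$walls) <=
          cfg$body_radius
        alive[died] <- FALSE
      }
      respawn <- (!alive & dead_records >= 2L) | (alive & ep_steps >= episode_cap)
      if (any(respawn)) {
        np <- .lf_random_poses(sum(respawn), track, cfg)
        x[respawn] <- np$x; y[respawn] <- np$y; h[respawn] <- np$heading
        alive[respawn] <- TRUE
        dead_records[respawn] <- 0L
        ep_steps[respawn] <- 0L
        ep_id[respawn] <- next_ep + seq_len(sum(respawn)) - 1L
        next_ep <- next_ep + sum(respawn)
      }
    }
    count_chunk(S, A, AL, EP, first)
    last2 <- (nrow_buf - 1L):nrow_buf
    cs <- S[last2, ]; ca <- A[last2, ]; cal <- AL[last2, ]; cep <- EP[last2, ]
    first <- FALSE
    done <- done + k
  }

  cnt_gamma <- array(cnt_gamma, dim = c(4, 4, 4))
  cnt_goal <- array(cnt_goal, dim = c(2, rep(4, 6)))

  gamma_p <- smooth_and_normalize(array(cnt_gamma, dim = rep(2, 6)),
                                  smoothing_eps, n_target_dims = 2L)
  gamma <- cond_table(gamma_p, c("S1", "S2"), c(2L, 2L),
                      c("S1", "S2", "A1", "A2"), rep(2L, 4))
  sa_counts <- apply(cnt_gamma, c(2, 3), sum)    # [s(4), a(4)]
  sga_p <- smooth_and_normalize(array(sa_counts, dim = rep(2, 4)),
                                smoothing_eps, n_target_dims = 2L)
  s_given_a <- cond_table(sga_p, c("S1", "S2"), c(2L, 2L),
                          c("A1", "A2"), c(2L, 2L))
  goal_p <- smooth_and_normalize(array(cnt_goal, dim = c(2, rep(2, 12))),
                                 smoothing_eps, n_target_dims = 1L)
  goal <- cond_table(goal_p, "G", 2L, .lf_goal_givens(), rep(2L, 12))

  list(
    sensor = structure(list(
      gamma = gamma, s_given_a = s_given_a, counts = cnt_gamma,
      n_samples = n_samples, sensor_length = cfg$length, seed = seed,
      eps = smoothing_eps), class = "sensor_channel"),
    goal = structure(list(
      table = goal, counts = cnt_goal, n_windows = n_windows,
      sensor_length = cfg$length, seed = seed, eps = smoothing_eps),
      class = "goal_channel")
  )
}

#' @export
print.sensor_channel <- function(x, ...) {
  cat("<sensor_channel> sensor length ", x$sensor_length, ", ",
      format(x$n_samples, big.mark = ","), " samples\n", sep = "")
  invisible(x)
}

#' @export
print.goal_channel <- function(x, ...) {
  cat("<goal_channel> ", format(x$n_windows, big.mark = ","),
      " windows, overall survival ",
      signif(sum(x$counts[2, , , , , , ]) / max(sum(x$counts), 1), 4),
      "\n", sep = "")
  invisible(x)
}

#' Persist sampled channels as JSON
#'
#' Stores metadata and the raw integer count tensors; conditionals are
#' rebuilt on read with the stored smoothing, so a round trip is exact.
#'
#' @param channels Result of [sample_channels()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channels_json <- function(channels, path) {
  s <- channels$sensor
  g <- channels$goal
  jsonlite::write_json(list(
    sensor_length = s$sensor_length, n_samples = s$n_samples,
    seed = if (is.null(s$seed)) NA else s$seed, eps = s$eps,
    n_windows = g$n_windows,
    gamma_counts = as.vector(s$counts), goal_counts = as.vector(g$counts)
  ), path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read channels written by [write_channels_json()]
#' @param path JSON file path.
#' @return A list with `sensor` and `goal` channels.
#' @export
read_channels_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$sensor_length <- as.numeric(x$sensor_length)
  x$n_samples <- as.numeric(x$n_samples)
  cnt_gamma <- array(as.integer(x$gamma_counts), dim = c(4, 4, 4))
  cnt_goal <- array(as.integer(x$goal_counts), dim = c(2, rep(4, 6)))
  eps <- x$eps
  gamma <- cond_table(
    smooth_and_normalize(array(cnt_gamma, dim = rep(2, 6)), eps, 2L),
    c("S1", "S2"), c(2L, 2L), c("S1", "S2", "A1", "A2"), rep(2L, 4))
  s_given_a <- cond_table(
    smooth_and_normalize(array(apply(cnt_gamma, c(2, 3), sum), dim = rep(2, 4)),
                         eps, 2L),
    c("S1", "S2"), c(2L, 2L), c("A1", "A2"), c(2L, 2L))
  goal <- cond_table(
    smooth_and_normalize(array(cnt_goal, dim = c(2, rep(2, 12))), eps, 1L),
    "G", 2L, .lf_goal_givens(), rep(2L, 12))
  list(
    sensor = structure(list(
      gamma = gamma, s_given_a = s_given_a, counts = cnt_gamma,
      n_samples = x$n_samples, sensor_length = x$sensor_length,
      seed = if (is.na(x$seed)) NULL else x$seed, eps = eps),
      class = "sensor_channel"),
    goal = structure(list(
      table = goal, counts = cnt_goal, n_windows = x$n_windows,
      sensor_length = x$sensor_length,
      seed = if (is.na(x$seed)) NULL else x$seed, eps = eps),
      class = "goal_channel")
  )
}
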