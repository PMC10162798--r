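#' Arena geometry defaults
#'
#' The arena is a 30 x 30 cm box so the analysis grid of 15 x 15 bins at
#' 2 x 2 cm tiles it exactly. Levers sit on the y = 0 wall at x = 7.5 cm
#' (left) and x = 22.5 cm (right); the food port is centered between them.
#'
#' @return Named list: `width`, `height` (cm), `lever_left`, `lever_right`,
#'   `food_port` (each an `(x, y)` pair in cm).
#' @export
arena_geometry <- function() {
  list(width = 30, height = 30,
       lever_left = c(x = 7.5, y = 1),
       lever_right = c(x = 22.5, y = 1),
       food_port = c(x = 15, y = 1))
}

#' Construct a position track
#'
#' @param t Sample times in seconds (strictly increasing, constant step).
#' @param x,y Positions in cm.
#' @param rate Sampling rate in Hz.
#' @param arena_width,arena_height Arena dimensions in cm.
#' @return An object of class `position_track`: list with `samples`
#'   (data.frame `t_s`, `x_cm`, `y_cm`), `rate`, `arena_width`,
#'   `arena_height`.
#' @export
position_track <- function(t, x, y, rate, arena_width = 30,
                           arena_height = 30) {
  check_positive_scalar(rate, "rate")
  if (length(t) != length(x) || length(t) != length(y))
    stop_invalid("t, x, y must have equal length")
  if (any(x < 0 | x > arena_width | y < 0 | y > arena_height))
    stop_invalid("positions outside the arena")
  structure(list(samples = data.frame(t_s = t, x_cm = x, y_cm = y),
                 rate = rate, arena_width = arena_width,
                 arena_height = arena_height),
            class = "position_track")
}

#' @export
print.position_track <- function(x, ...) {
  cat(sprintf("<position_track> %d samples @ %g Hz, arena %g x %g cm\n",
              nrow(x$samples), x$rate, x$arena_width, x$arena_height))
  invisible(x)
}

# specular reflection into [0, hi]: fold the coordinate, flipping the
# velocity at every wall crossing
reflect <- function(p, v, hi) {
  repeat {
    if (p < 0) { p <- -p; v <- -v }
    else if (p > hi) { p <- 2 * hi - p; v <- -v }
    else break
  }
  list(p = p, v = v)
}

#' Simulate an animal trajectory for a session
#'
#' Smooth bounded-velocity random walk (Ornstein-Uhlenbeck velocity,
#' positions reflected at the walls). When a lever is extended the walk is
#' attracted toward that lever; for `port_dwell` seconds after each reward
#' it is attracted toward the food port. With `bias = 0` the walk is
#' unbiased and its long-run occupancy is approximately uniform.
#'
#' `teleport = TRUE` is a degenerate test hook: the x-coordinate is pinned
#' to the extended lever's x whenever one is out.
#'
#' @param log An [event_log()] providing session duration and lever/reward
#'   times.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @param bias Attraction gain toward the current target, 1/s^2 scale;
#'   0 disables task bias.
#' @param arena_width,arena_height Arena size in cm.
#' @param speed_sd Stationary speed scale of the walk, cm/s.
#' @param vel_tau Velocity correlation time, seconds.
#' @param max_speed Hard speed cap, cm/s.
#' @param port_dwell Seconds after each reward during which the food port is
#'   the target.
#' @param port_gain Multiplier on `bias` while the port is the target:
#'   pellet retrieval is a reliable directed dash, unlike loose hovering
#'   near an extended lever.
#' @param teleport Degenerate hook pinning x to the extended lever.
#' @return A [position_track()] whose samples cover `[0, log$duration]`.
#' @export
simulate_position_track <- function(log, rate = 30, seed = 1L, bias = 2,
                                    arena_width = 30, arena_height = 30,
                                    speed_sd = 8, vel_tau = 0.5,
                                    max_speed = 30, port_dwell = 3,
                                    port_gain = 2, teleport = FALSE) {
  stopifnot(inherits(log, "event_log"))
  check_positive_scalar(rate, "rate")
  check_positive_scalar(arena_width, "arena_width")
  check_positive_scalar(arena_height, "arena_height")

  geom <- arena_geometry()
  dt <- 1 / rate
  n <- floor(log$duration * rate) + 1L
  t <- (seq_len(n) - 1L) * dt

  iv <- lever_intervals(log)
  rewards <- event_times(log, "reward")

  in_intervals <- function(tt, m) {
    if (!nrow(m)) return(rep(FALSE, length(tt)))
    out <- rep(FALSE, length(tt))
    for (i in seq_len(nrow(m))) out <- out | (tt >= m[i, 1] & tt < m[i, 2])
    out
  }
  left_out <- in_intervals(t, iv$left)
  right_out <- in_intervals(t, iv$right)
  near_reward <- rep(FALSE, n)
  for (r in rewards) near_reward <- near_reward | (t >= r & t < r + port_dwell)

  # per-sample target: food port wins just after reward, then active lever
  tx <- rep(NA_real_, n); ty <- rep(NA_real_, n)
  tx[left_out] <- geom$lever_left["x"]; ty[left_out] <- geom$lever_left["y"]
  tx[right_out] <- geom$lever_right["x"]; ty[right_out] <- geom$lever_right["y"]
  tx[near_reward] <- geom$food_port["x"]; ty[near_reward] <- geom$food_port["y"]

  x <- numeric(n); y <- numeric(n)
  with_seed(seed, {
    px <- stats::runif(1, 0, arena_width)
    py <- stats::runif(1, 0, arena_height)
    vx <- 0; vy <- 0
    a <- exp(-dt / vel_tau)
    sig <- speed_sd * sqrt(1 - a^2)
    ex <- stats::rnorm(n); ey <- stats::rnorm(n)
    for (i in seq_len(n)) {
      x[i] <- px; y[i] <- py
      vx <- a * vx + sig * ex[i]
      vy <- a * vy + sig * ey[i]
      if (bias > 0 && !is.na(tx[i])) {
        g <- if (near_reward[i]) bias * port_gain else bias
        vx <- vx + g * (tx[i] - px) * dt
        vy <- vy + g * (ty[i] - py) * dt
      }
      sp <- sqrt(vx^2 + vy^2)
      if (sp > max_speed) { vx <- vx * max_speed / sp; vy <- vy * max_speed / sp }
      rx <- reflect(px + vx * dt, vx, arena_width)
      ry <- reflect(py + vy * dt, vy, arena_height)
      px <- rx$p; vx <- rx$v
      py <- ry$p; vy <- ry$v
    }
  })
  if (teleport) {
    x[left_out] <- geom$lever_left["x"]
    x[right_out] <- geom$lever_right["x"]
  }
  position_track(t, x, y, rate, arena_width, arena_height)
}

#' Write / read a position track as CSV with a JSON sidecar
#'
#' CSV columns `t_s,x_cm,y_cm`; rate and arena dimensions in `<path>.json`.
#'
#' @param track A [position_track()].
#' @param path CSV file path.
#' @return `write_track` returns `path` invisibly; `read_track` the
#'   reconstructed track.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "position_track"))
  utils::write.csv(track$samples, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(rate = track$rate,
                            arena_width = track$arena_width,
                            arena_height = track$arena_height),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  s <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  position_track(s$t_s, s$x_cm, s$y_cm, meta$rate, meta$arena_width,
                 meta$arena_height)
}
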