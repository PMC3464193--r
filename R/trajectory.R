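#' Trajectory objects
#'
#' A `trajectory` is a list with uniformly (or raw, before resampling)
#' sampled position data for an animal in a square arena:
#' \describe{
#'   \item{times}{sample times in seconds}
#'   \item{x, y}{positions in cm within \[0, arena_size\]}
#'   \item{heading}{direction of motion in radians, `atan2(dy, dx)` of the
#'     local displacement; zero-speed samples carry the previous heading}
#'   \item{speed}{running speed in cm/s, displacement / dt}
#'   \item{dt}{sampling interval in seconds (NA if non-uniform)}
#'   \item{arena_size}{side length of the square arena in cm}
#' }
#' Heading is taken parallel to the trajectory, as is standard when no
#' independent head-direction signal is recorded.
#'
#' @param times,x,y numeric vectors of equal length
#' @param arena_size arena side length in cm
#' @return a `trajectory` object
#' @export
new_trajectory <- function(times, x, y, arena_size = 100) {
  stopifnot(length(times) == length(x), length(x) == length(y))
  if (length(times) < 2L) stop("trajectory needs at least 2 samples")
  dts <- diff(times)
  if (any(dts <= 0)) stop("trajectory times must be strictly increasing")
  dt <- if (max(dts) - min(dts) < 1e-9) dts[1] else NA_real_
  hs <- derive_heading_speed(times, x, y)
  structure(
    list(times = as.numeric(times), x = as.numeric(x), y = as.numeric(y),
         heading = hs$heading, speed = hs$speed,
         dt = dt, arena_size = arena_size),
    class = "trajectory")
}

# heading/speed from finite displacements; sample i gets the displacement
# into sample i (forward difference assigned to the interval start), last
# sample repeats. Zero-speed samples inherit the previous defined heading.
derive_heading_speed <- function(times, x, y) {
  n <- length(times)
  dx <- diff(x); dy <- diff(y); dts <- diff(times)
  sp <- sqrt(dx^2 + dy^2) / dts
  hd <- atan2(dy, dx)
  hd[sp == 0] <- NA
  # carry last defined heading forward; leading NAs -> 0
  if (anyNA(hd)) {
    idx <- cumsum(!is.na(hd))
    filled <- c(0, hd[!is.na(hd)])[idx + 1L]
    hd <- filled
  }
  list(heading = c(hd, hd[n - 1L]), speed = c(sp, sp[n - 1L]))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d samples, %.1f s, arena %g cm, dt %s s\n",
    length(x$times), diff(range(x$times)), x$arena_size,
    if (is.na(x$dt)) "irregular" else format(x$dt)))
  cat(sprintf("  speed: mean %.2f cm/s, sd %.2f cm/s, max %.1f cm/s\n",
              mean(x$speed), stats::sd(x$speed), max(x$speed)))
  invisible(x)
}

#' Load a trajectory from a delimited text file
#'
#' The canonical dialect is delimited text with a header naming columns
#' `t` (or `time`), `x` and `y`, in seconds and cm. A reader hook
#' (`dialect = "custom"` with a `reader` function) accommodates other
#' formats.
#'
#' @param path file path
#' @param dialect `"csv"`, `"tsv"`, or `"custom"`
#' @param arena_size arena side length in cm
#' @param reader for `dialect = "custom"`, a function `path -> data.frame`
#'   with columns t, x, y
#' @return a [new_trajectory()] object with raw timestamps preserved
#' @export
load_trajectory <- function(path, dialect = c("csv", "tsv", "custom"),
                            arena_size = 100, reader = NULL) {
  dialect <- match.arg(dialect)
  df <- switch(dialect,
    csv = utils::read.csv(path, header = TRUE),
    tsv = utils::read.delim(path, header = TRUE),
    custom = {
      if (!is.function(reader)) stop("dialect 'custom' requires a reader function")
      as.data.frame(reader(path))
    })
  names(df) <- tolower(names(df))
  if ("time" %in% names(df) && !("t" %in% names(df))) df$t <- df$time
  missing <- setdiff(c("t", "x", "y"), names(df))
  if (length(missing))
    stop("trajectory file lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) < 2L) stop("trajectory needs at least 2 samples")
  if (any(diff(df$t) <= 0)) stop("trajectory times must be strictly increasing")
  new_trajectory(df$t, df$x, df$y, arena_size = arena_size)
}

#' Resample a trajectory onto a uniform time grid
#'
#' Positions are linearly interpolated onto a grid of step `dt` (matching
#' the integration step of the model dynamics); heading and speed are then
#' recomputed from the interpolated positions.
#'
#' @param traj a trajectory
#' @param dt target sampling interval in seconds
#' @return a trajectory with constant step `dt`
#' @export
resample_trajectory <- function(traj, dt = 0.002) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive number")
  native <- min(diff(traj$times))
  if (dt > native + 1e-12)
    stop("dt must not exceed the native sampling interval (", signif(native, 3), " s)")
  t0 <- traj$times[1]; t1 <- traj$times[length(traj$times)]
  grid <- seq(t0, t1, by = dt)
  xs <- stats::approx(traj$times, traj$x, xout = grid)$y
  ys <- stats::approx(traj$times, traj$y, xout = grid)$y
  new_trajectory(grid, xs, ys, arena_size = traj$arena_size)
}

#' Synthesize a realistic open-field trajectory
#'
#' Generates a correlated random walk emulating rat foraging kinematics:
#' log running speed follows a mean-reverting Ornstein-Uhlenbeck process
#' whose stationary distribution is lognormal with exactly the target mean
#' and sd (always positive and right-skewed, like real rat speeds), and
#' heading follows a wrapped Brownian walk; the unbounded path is folded
#' back into the arena by specular reflection at the walls, which preserves
#' the speed statistics. Defaults target the running-speed statistics of a
#' typical foraging rat (mean 14.03 cm/s, sd 9.8 cm/s).
#'
#' @param duration total duration in seconds
#' @param arena_size arena side length in cm
#' @param speed_mean,speed_sd target mean and sd of running speed (cm/s)
#' @param turn_sd heading diffusion in rad/sqrt(s)
#' @param dt sampling interval in seconds
#' @param seed integer seed; identical seeds give identical trajectories
#' @param speed_tau relaxation time of the speed process in seconds
#' @return a trajectory
#' @export
synthesize_trajectory <- function(duration, arena_size = 100,
                                  speed_mean = 14.03, speed_sd = 9.8,
                                  turn_sd = 1, dt = 0.002, seed = 1,
                                  speed_tau = 1) {
  stopifnot(duration > 0, arena_size > 0, speed_mean > 0, speed_sd > 0,
            turn_sd >= 0, dt > 0, speed_tau > 0)
  n <- max(2L, floor(duration / dt) + 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  theta <- 1 / speed_tau
  # lognormal parameters matching the target moments
  sd_ln <- sqrt(log(1 + (speed_sd / speed_mean)^2))
  mu_ln <- log(speed_mean) - sd_ln^2 / 2
  # OU on log speed: stationary sd = sd_ln, relaxation time speed_tau
  a <- 1 - theta * dt
  innov <- stats::rnorm(n - 1L, 0, sd_ln * sqrt(2 * theta * dt))
  dev <- stats::filter(innov, a, method = "recursive",
                       init = stats::rnorm(1, 0, sd_ln))
  sp <- exp(mu_ln + as.numeric(dev))
  hd <- cumsum(c(stats::runif(1, -pi, pi),
                 stats::rnorm(n - 2L, 0, turn_sd * sqrt(dt))))
  step <- sp * dt
  x <- cumsum(c(arena_size / 2, step * cos(hd)))
  y <- cumsum(c(arena_size / 2, step * sin(hd)))
  new_trajectory(seq(0, by = dt, length.out = n),
                 reflect_fold(x, arena_size),
                 reflect_fold(y, arena_size),
                 arena_size = arena_size)
}

# fold an unbounded coordinate into [0, L] by specular reflection
# (triangle-wave map); equivalent to elastic bounces off the walls
reflect_fold <- function(u, L) {
  v <- u %% (2 * L)
  L - abs(v - L)
}

#' Rotate a trajectory and prepend a run-in from the origin
#'
#' Produces a novel trajectory from an existing one by rotating all
#' positions by `angle` about the arena origin (0, 0) and prepending a
#' straight run from the origin to the rotated starting position at
#' `prefix_speed`. Excursions outside the arena are clipped to its limits.
#' Used to generate a fresh trajectory for each learning trial.
#'
#' @param traj a uniformly sampled trajectory
#' @param angle rotation angle in radians
#' @param prefix_speed speed of the prepended straight run in cm/s
#' @return a trajectory
#' @export
rotate_and_prefix <- function(traj, angle, prefix_speed = 15) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.na(traj$dt)) traj <- resample_trajectory(traj, min(diff(traj$times)))
  dt <- traj$dt
  xr <- traj$x * cos(angle) - traj$y * sin(angle)
  yr <- traj$x * sin(angle) + traj$y * cos(angle)
  x0 <- xr[1]; y0 <- yr[1]
  d0 <- sqrt(x0^2 + y0^2)
  npre <- ceiling(d0 / (prefix_speed * dt))
  if (npre > 0) {
    frac <- seq_len(npre) / (npre + 1)  # strictly before the start point
    px <- frac * x0; py <- frac * y0
  } else {
    px <- numeric(0); py <- numeric(0)
  }
  L <- traj$arena_size
  x <- pmin(pmax(c(0, px, xr), 0), L)
  y <- pmin(pmax(c(0, py, yr), 0), L)
  new_trajectory(seq(0, by = dt, length.out = length(x)), x, y,
                 arena_size = L)
}
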