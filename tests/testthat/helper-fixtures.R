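# shared builders for small test inputs

write_traj_csv <- function(t, x, y, path = tempfile(fileext = ".csv")) {
  utils::write.csv(data.frame(t = t, x = x, y = y), path, row.names = FALSE)
  path
}

straight_trajectory <- function(speed = 10, duration = 1, dt = 0.002,
                                x0 = 10, y0 = 50, heading = 0) {
  n <- floor(duration / dt) + 1
  tt <- seq(0, by = dt, length.out = n)
  new_trajectory(tt, x0 + speed * tt * cos(heading),
                 y0 + speed * tt * sin(heading))
}

# a rate_map object wrapping a given rate matrix (fully visited arena)
as_rate_map <- function(rate, bin_size = 2.5) {
  occ <- matrix(1, nrow(rate), ncol(rate))
  m <- structure(list(occupancy = occ, activity = rate * occ,
                      bin_size = bin_size,
                      arena_size = nrow(rate) * bin_size),
                 class = "rate_map")
  smooth_and_rate(m)
}

desk_params <- function(...) som_params(...)
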