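test_that("map accumulation tracks occupancy and activity per bin", {
  tr <- straight_trajectory(speed = 10, duration = 1, x0 = 10, y0 = 50)
  m <- accumulate_maps(tr, rep(2, length(tr$times)))
  expect_s3_class(m, "rate_map")
  expect_equal(sum(m$occupancy), length(tr$times) * tr$dt)
  # constant output: rate equals the constant wherever visited
  sm <- smooth_and_rate(m)
  expect_equal(unique(round(m$activity[m$occupancy > 0] /
                              m$occupancy[m$occupancy > 0], 9)), 2)
  # unvisited bins have zero occupancy and undefined rate
  expect_true(is.na(sm$rate_raw[40, 40]))
  expect_error(accumulate_maps(tr, rep(1, 5)), "match")
})

test_that("a bin visited with outputs 1 then 3 has rate 2", {
  # stationary path: two halves in the same bin
  n <- 1000
  tr <- new_trajectory(seq(0, by = 0.002, length.out = n),
                       rep(11, n), rep(11, n))
  out <- c(rep(1, n / 2), rep(3, n / 2))
  m <- accumulate_maps(tr, out)
  raw <- m$activity / pmax(m$occupancy, 1e-12)
  expect_equal(raw[5, 5], 2)
})

test_that("smoothing uses a unit-mass 5x5 Gaussian kernel", {
  k <- gridsom:::gaussian_kernel_5x5()
  expect_equal(dim(k), c(5, 5))
  expect_equal(sum(k), 1)
  expect_equal(k, t(k))
  # impulse response reproduces the kernel; interior mass is preserved
  m <- structure(list(occupancy = matrix(1, 20, 20),
                      activity = matrix(0, 20, 20),
                      bin_size = 2.5, arena_size = 50),
                 class = "rate_map")
  m$activity[10, 10] <- 1
  sm <- smooth_and_rate(m)
  expect_equal(sm$rate[8:12, 8:12], k, tolerance = 1e-12)
  expect_equal(sum(sm$rate), 1)
  expect_error(smooth_and_rate(structure(list(
    occupancy = matrix(0, 4, 4), activity = matrix(0, 4, 4),
    bin_size = 2.5, arena_size = 10), class = "rate_map")), "empty")
})

test_that("autocorrelogram has unit central peak and even symmetry", {
  set.seed(8)
  rate <- matrix(runif(1600), 40, 40)
  ac <- autocorrelogram(rate)
  n <- nrow(ac$corr)
  c0 <- (n + 1) / 2
  expect_equal(ac$corr[c0, c0], 1, tolerance = 1e-9)
  flipped <- ac$corr[n:1, n:1]
  expect_equal(ac$corr, flipped, tolerance = 1e-9)
  # lags with too little overlap are undefined
  expect_true(is.na(ac$corr[1, 1]))
  expect_gte(min(ac$n_overlap[!is.na(ac$corr)]), 20)
})

test_that("autocorrelogram agrees with a direct masked-correlation oracle", {
  set.seed(12)
  rate <- matrix(runif(400), 20, 20)
  rate[sample(400, 40)] <- NA
  ac <- autocorrelogram(rate, min_overlap = 10)
  direct <- function(dx, dy) {
    n <- 20
    xs <- max(1, 1 - dx):min(n, n - dx)
    ys <- max(1, 1 - dy):min(n, n - dy)
    a <- rate[xs, ys]; b <- rate[xs + dx, ys + dy]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 10) return(NA_real_)
    stats::cor(a[ok], b[ok])
  }
  for (lag in list(c(0, 0), c(3, 0), c(0, -4), c(5, 7), c(-2, 6))) {
    expect_equal(ac$corr[20 + lag[1], 20 + lag[2]],
                 direct(lag[1], lag[2]), tolerance = 1e-8,
                 info = paste(lag, collapse = ","))
  }
})

test_that("hexagonal fixtures yield six first-ring peaks and high gridness", {
  for (case in list(c(30, 0), c(23, 10), c(40, 25))) {
    rate <- make_lattice_map(spacing = case[1], orientation = case[2])
    ac <- autocorrelogram(rate)
    gm <- grid_metrics(ac, NULL)
    expect_gte(gm$n_peaks, 6)
    expect_gt(gm$gridness, 1)
    expect_true(gm$is_grid)
    expect_lt(abs(gm$spacing_cm - case[1]), 2.5,
              label = paste("spacing at", case[1], "cm"))
    d_or <- abs(gm$orientation_deg - case[2] %% 60)
    expect_lt(min(d_or, 60 - d_or), 4)
  }
})

test_that("square lattices and random maps are not classified as grids", {
  sq <- make_lattice_map(spacing = 30, lattice = "square")
  gm <- grid_metrics(autocorrelogram(sq), NULL)
  expect_lte(gm$gridness, 0)
  expect_false(gm$is_grid)

  # the gridness > 0 classification rule is permissive by construction;
  # on featureless noise it fires in a minority of draws and the gridness
  # distribution is centred near zero
  set.seed(99)
  gr <- vapply(1:30, function(i) {
    r <- matrix(runif(1600), 40, 40)
    m <- structure(list(occupancy = matrix(1, 40, 40), activity = r,
                        bin_size = 2.5, arena_size = 100),
                   class = "rate_map")
    g <- grid_metrics(autocorrelogram(smooth_and_rate(m)), NULL)
    if (is.na(g$gridness)) 0 else g$gridness
  }, 0)
  expect_lt(mean(gr > 0), 0.5)
  expect_lt(mean(gr), 0.1)      # no systematic hexagonal bias in noise
})

test_that("gridness is invariant to rate scaling and 60-degree rotation", {
  rate <- make_lattice_map(spacing = 30, orientation = 12)
  g1 <- grid_metrics(autocorrelogram(rate), NULL)$gridness
  g2 <- grid_metrics(autocorrelogram(rate * 7.3), NULL)$gridness
  expect_equal(g1, g2, tolerance = 1e-9)
  rot <- make_lattice_map(spacing = 30, orientation = 72)  # 12 + 60
  g3 <- grid_metrics(autocorrelogram(rot), NULL)$gridness
  expect_equal(g1, g3, tolerance = 0.15)
})

test_that("field width tracks the central autocorrelogram peak", {
  narrow <- make_lattice_map(spacing = 30, field_sd = 3)
  wide <- make_lattice_map(spacing = 45, field_sd = 7)
  wn <- grid_metrics(autocorrelogram(narrow), NULL)$field_width_cm
  ww <- grid_metrics(autocorrelogram(wide), NULL)$field_width_cm
  expect_lt(wn, ww)
  expect_gt(wn, 0)
})

test_that("peak and mean rates survive even when peaks are missing", {
  rate <- matrix(0.3, 40, 40)
  rate[20, 20] <- 0.9
  rm <- as_rate_map(rate)
  suppressWarnings(gm <- grid_metrics(autocorrelogram(rm), rm))
  expect_false(gm$is_grid)
  expect_true(is.na(gm$gridness))
  expect_gt(gm$peak_rate, 0.3)
  expect_equal(gm$mean_rate, mean(rm$rate, na.rm = TRUE))
})

test_that("inter-trial stability behaves like a masked correlation", {
  a <- matrix(runif(1600), 40, 40)
  expect_equal(inter_trial_stability(a, a), 1)
  expect_equal(inter_trial_stability(a, a + 0.5), 1)
  set.seed(21)
  b <- matrix(runif(1600), 40, 40)
  expect_lt(abs(inter_trial_stability(a, b)), 0.1)
  # fewer than 3 qualifying bins -> undefined
  za <- matrix(0, 4, 4); zb <- matrix(0, 4, 4)
  za[1, 1] <- 1
  expect_true(is.na(inter_trial_stability(za, zb)))
})

test_that("gridness agrees with an exhaustive-rotation oracle on fixtures", {
  rate <- make_lattice_map(spacing = 30, orientation = 15)
  ac <- autocorrelogram(rate)
  gm <- grid_metrics(ac, NULL)
  # oracle: rotate the autocorrelogram at 1-degree resolution and find the
  # extrema of annulus correlation at the canonical angles
  corr <- ac$corr
  n <- nrow(corr); c0 <- (n + 1) / 2
  r0 <- gridsom:::central_peak_radius(corr)
  ann_out <- 1.25 * max(gm$peaks$dist)
  d <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+"))
  sel <- d > r0 & d <= ann_out
  prof <- vapply(1:179, function(a)
    gridsom:::masked_cor(corr, gridsom:::rotate_matrix(corr, a), sel), 0)
  oracle <- min(prof[c(60, 120)]) - max(prof[c(30, 90, 150)])
  expect_equal(gm$gridness, oracle, tolerance = 1e-9)
  # on a hexagonal fixture the 60/120 rotations are near-maximal
  expect_gt(min(prof[c(60, 120)]), max(prof[c(30, 90, 150)]))
})
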