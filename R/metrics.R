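#' Accumulate occupancy and activity maps over a trial
#'
#' The arena is divided into square bins (2.5 cm by default); each
#' trajectory sample adds `dt` seconds to its bin's occupancy and
#' `output * dt` to its activity.
#'
#' @param traj a uniformly sampled trajectory
#' @param activity per-sample cell output: a vector, or a samples x cells
#'   matrix (one map per column)
#' @param bin_size bin side length in cm
#' @return a `rate_map` (occupancy, activity, bin_size, arena_size), or a
#'   list of them for matrix input
#' @export
accumulate_maps <- function(traj, activity, bin_size = 2.5) {
  act <- as.matrix(activity)
  if (nrow(act) != length(traj$times))
    stop("activity length does not match the trajectory")
  if (is.na(traj$dt)) stop("trajectory must be uniformly sampled")
  L <- traj$arena_size
  nb <- ceiling(L / bin_size)
  ix <- pmin(pmax(floor(traj$x / bin_size), 0), nb - 1)
  iy <- pmin(pmax(floor(traj$y / bin_size), 0), nb - 1)
  bin <- ix + nb * iy + 1
  occ_v <- numeric(nb * nb)
  tab <- tabulate(bin, nbins = nb * nb) * traj$dt
  occ <- matrix(tab, nb, nb)
  amaps <- rowsum(act * traj$dt, group = bin, reorder = FALSE)
  idx <- as.integer(rownames(amaps))
  maps <- lapply(seq_len(ncol(act)), function(j) {
    av <- occ_v
    av[idx] <- amaps[, j]
    structure(list(occupancy = occ, activity = matrix(av, nb, nb),
                   bin_size = bin_size, arena_size = L),
              class = "rate_map")
  })
  if (ncol(act) == 1L) maps[[1L]] else maps
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %dx%d bins of %g cm, %.1f s occupancy%s\n",
              nrow(x$occupancy), ncol(x$occupancy), x$bin_size,
              sum(x$occupancy),
              if (is.null(x$rate)) " (unsmoothed)" else ""))
  invisible(x)
}

# truncated 5x5 Gaussian kernel, sd = 1 bin, normalized to sum 1
gaussian_kernel_5x5 <- function() {
  g <- stats::dnorm(-2:2)
  k <- outer(g, g)
  k / sum(k)
}

# zero-padded 2-D convolution with a small centered kernel
conv2_same <- function(m, k) {
  kr <- (nrow(k) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  for (di in -kr:kr) for (dj in -kr:kr) {
    w <- k[di + kr + 1L, dj + kr + 1L]
    si <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 - dj):min(nc, nc - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] + w * m[si, sj]
  }
  out
}

#' Smooth accumulated maps and derive rate maps
#'
#' Occupancy and activity maps are each convolved with a truncated 5x5
#' Gaussian kernel (sd = 1 bin, normalized to sum 1); the smoothed rate is
#' smoothed activity / smoothed occupancy, and the unsmoothed rate
#' (activity / occupancy over visited bins) is retained alongside. Rates
#' are `NA` where the corresponding occupancy is zero.
#'
#' @param map a `rate_map` from [accumulate_maps()]
#' @return the map with `rate` (smoothed) and `rate_raw` fields
#' @export
smooth_and_rate <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  if (all(map$occupancy == 0)) stop("empty occupancy map")
  k <- gaussian_kernel_5x5()
  so <- conv2_same(map$occupancy, k)
  sa <- conv2_same(map$activity, k)
  rate <- ifelse(so > 0, sa / so, NA_real_)
  raw <- ifelse(map$occupancy > 0, map$activity / map$occupancy, NA_real_)
  map$rate <- rate
  map$rate_raw <- raw
  map
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the (smoothed) rate map with itself at every 2-D
#' lag, computed over the overlapping defined bins; lags with fewer than
#' `min_overlap` overlapping bins are `NA`. Computed with FFT-based
#' cross-correlations of the map and its validity mask.
#'
#' @param rate a matrix (NAs for undefined bins) or a smoothed `rate_map`
#' @param min_overlap minimum overlapping bins per lag
#' @return an `autocorrelogram`: `corr` ((2n-1) x (2n-1) matrix, zero lag
#'   at the center), `bin_size`, and `n_overlap`
#' @export
autocorrelogram <- function(rate, min_overlap = 20) {
  bin_size <- 2.5
  if (inherits(rate, "rate_map")) {
    bin_size <- rate$bin_size
    rate <- rate$rate
    if (is.null(rate)) stop("rate map must be smoothed first")
  }
  m <- as.matrix(rate)
  U <- !is.na(m)                       # validity mask
  if (sum(U) < 2) stop("rate map has too few defined bins")
  A <- ifelse(U, m, 0)
  if (stats::sd(A[U]) == 0)
    warning("constant rate map: autocorrelations undefined")
  nr <- nrow(m); nc <- ncol(m)
  pr <- 2L * nr; pc <- 2L * nc        # zero padding for linear correlation
  pad <- function(x) { p <- matrix(0, pr, pc); p[1:nr, 1:nc] <- x; p }
  F <- function(x) stats::fft(pad(x))
  xcorr <- function(fa, fb) {
    # sum over overlap of a[i] * b[i + lag]
    re <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / (pr * pc)
    # lags -(n-1)..(n-1) along each axis
    idx_r <- c((pr - nr + 2L):pr, 1L:nr)
    idx_c <- c((pc - nc + 2L):pc, 1L:nc)
    re[idx_r, idx_c]
  }
  fU <- F(U); fA <- F(A); fA2 <- F(A^2)
  n  <- xcorr(fU, fU)
  Sx <- xcorr(fA, fU)
  Sy <- xcorr(fU, fA)
  Sxx <- xcorr(fA2, fU)
  Syy <- xcorr(fU, fA2)
  Sxy <- xcorr(fA, fA)
  n <- round(n)
  num <- n * Sxy - Sx * Sy
  den2 <- (n * Sxx - Sx^2) * (n * Syy - Sy^2)
  corr <- ifelse(n >= min_overlap & den2 > 1e-12, num / sqrt(pmax(den2, 0)),
                 NA_real_)
  corr <- pmin(pmax(corr, -1), 1)
  structure(list(corr = corr, bin_size = bin_size, n_overlap = n),
            class = "autocorrelogram")
}

#' @export
print.autocorrelogram <- function(x, ...) {
  cat(sprintf("<autocorrelogram> %dx%d lags, bin %g cm\n",
              nrow(x$corr), ncol(x$corr), x$bin_size))
  invisible(x)
}

# radial profile of the autocorrelogram about its center; returns the
# radius (in bins) where the azimuthal-mean correlation first reaches zero
# or a local minimum, whichever comes first
central_peak_radius <- function(corr) {
  n <- nrow(corr)
  c0 <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+"))
  rmax <- floor((n - 1) / 2)
  prof <- vapply(seq_len(rmax), function(r) {
    sel <- d >= r - 0.5 & d < r + 0.5
    mean(corr[sel], na.rm = TRUE)
  }, 0)
  prof <- c(1, prof)                   # radius 0
  zero_r <- NA_real_
  for (r in 2:length(prof)) {
    if (!is.na(prof[r]) && prof[r] <= 0) {
      # linear interpolation to the zero crossing
      p0 <- prof[r - 1]; p1 <- prof[r]
      zero_r <- (r - 2) + p0 / (p0 - p1)
      break
    }
    if (r < length(prof) && !anyNA(prof[(r - 1):(r + 1)]) &&
        prof[r] < prof[r - 1] && prof[r] <= prof[r + 1]) {
      zero_r <- r - 1
      break
    }
  }
  if (is.na(zero_r)) zero_r <- rmax
  zero_r
}

# rotate a centered square matrix by `angle` degrees about its center
# (bilinear interpolation; NA outside or where sources are NA)
rotate_matrix <- function(m, angle) {
  n <- nrow(m)
  c0 <- (n + 1) / 2
  th <- angle * pi / 180
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  x <- ij$i - c0; y <- ij$j - c0
  xs <- cos(th) * x + sin(th) * y + c0
  ys <- -sin(th) * x + cos(th) * y + c0
  i0 <- floor(xs); j0 <- floor(ys)
  fi <- xs - i0; fj <- ys - j0
  get <- function(ii, jj) {
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n
    v <- rep(NA_real_, length(ii))
    v[ok] <- m[cbind(ii[ok], jj[ok])]
    v
  }
  v <- get(i0, j0) * (1 - fi) * (1 - fj) + get(i0 + 1, j0) * fi * (1 - fj) +
    get(i0, j0 + 1) * (1 - fi) * fj + get(i0 + 1, j0 + 1) * fi * fj
  matrix(v, n, n)
}

#' Grid metrics from an autocorrelogram
#'
#' Identifies the six local maxima (correlation above `peak_thresh`)
#' closest to the central peak and derives:
#' \describe{
#'   \item{gridness}{min correlation of the annulus (inner radius = central
#'     peak extent, outer = `annulus_outer` times the outermost of the six
#'     peak distances) with its 60/120-degree rotations minus the max with
#'     its 30/90/150-degree rotations; > 0 classifies the cell as a grid
#'     cell.}
#'   \item{spacing_cm}{median distance of the six peaks from the center.}
#'   \item{orientation_deg}{smallest positive angle with the horizontal
#'     axis among the six peak directions, reported in \[0, 60).}
#'   \item{field_width_cm}{width of the central peak: twice the radius at
#'     which the radial correlation profile reaches zero or a local
#'     minimum, whichever is closer.}
#' }
#' Peak and mean rates (over all defined bins of the smoothed map) are
#' attached when a rate map is supplied; they remain defined even when
#' fewer than six qualifying peaks exist and the grid measures are NA.
#'
#' @param acorr an [autocorrelogram()]
#' @param rate_map optionally, the smoothed `rate_map` the autocorrelogram
#'   came from
#' @param peak_thresh minimum correlation for a qualifying local maximum
#' @param annulus_outer outer annulus radius as a multiple of the
#'   outermost peak distance
#' @return a `grid_metrics` list: gridness, spacing_cm, orientation_deg,
#'   field_width_cm, peak_rate, mean_rate, n_peaks, is_grid, peaks (bins)
#' @export
grid_metrics <- function(acorr, rate_map = NULL, peak_thresh = 0.1,
                         annulus_outer = 1.25) {
  stopifnot(inherits(acorr, "autocorrelogram"))
  corr <- acorr$corr
  n <- nrow(corr)
  c0 <- (n + 1) / 2
  r0 <- central_peak_radius(corr)
  peak_rate <- mean_rate <- NA_real_
  if (!is.null(rate_map)) {
    if (is.null(rate_map$rate)) rate_map <- smooth_and_rate(rate_map)
    peak_rate <- max(rate_map$rate, na.rm = TRUE)
    mean_rate <- mean(rate_map$rate, na.rm = TRUE)
  }
  # 8-neighbour local maxima above threshold, outside the central peak
  pk <- find_local_maxima(corr, peak_thresh)
  if (nrow(pk)) {
    pk$dist <- sqrt((pk$i - c0)^2 + (pk$j - c0)^2)
    pk <- pk[pk$dist > r0, , drop = FALSE]
    pk <- pk[order(pk$dist), , drop = FALSE]
  }
  base <- list(gridness = NA_real_, spacing_cm = NA_real_,
               orientation_deg = NA_real_, field_width_cm = 2 * r0 * acorr$bin_size,
               peak_rate = peak_rate, mean_rate = mean_rate,
               n_peaks = nrow(pk), is_grid = FALSE, peaks = pk)
  if (nrow(pk) < 6) return(structure(base, class = "grid_metrics"))
  six <- pk[1:6, ]
  base$peaks <- six
  base$spacing_cm <- stats::median(six$dist) * acorr$bin_size
  ang <- atan2(six$j - c0, six$i - c0) * 180 / pi
  ang <- ang %% 180                        # segment angle with horizontal
  base$orientation_deg <- min(ang) %% 60
  ann_out <- annulus_outer * max(six$dist)
  d <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+"))
  sel <- d > r0 & d <= ann_out
  rots60 <- vapply(c(60, 120), function(a)
    masked_cor(corr, rotate_matrix(corr, a), sel), 0)
  rots30 <- vapply(c(30, 90, 150), function(a)
    masked_cor(corr, rotate_matrix(corr, a), sel), 0)
  base$gridness <- min(rots60) - max(rots30)
  base$is_grid <- is.finite(base$gridness) && base$gridness > 0
  structure(base, class = "grid_metrics")
}

find_local_maxima <- function(m, thresh) {
  n <- nrow(m); p <- ncol(m)
  v <- ifelse(is.na(m), -Inf, m)
  core_i <- 2:(n - 1); core_j <- 2:(p - 1)
  x <- v[core_i, core_j]
  ismax <- x > thresh
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (x >= v[core_i + di, core_j + dj])
  }
  # strictness against at least one neighbour avoids plateaus double-counting
  strict <- matrix(FALSE, length(core_i), length(core_j))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    strict <- strict | (x > v[core_i + di, core_j + dj])
  }
  idx <- which(ismax & strict, arr.ind = TRUE)
  data.frame(i = idx[, 1] + 1L, j = idx[, 2] + 1L,
             corr = x[idx])
}

masked_cor <- function(a, b, sel) {
  ok <- sel & !is.na(a) & !is.na(b)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(a[ok], b[ok])
}

#' @export
print.grid_metrics <- function(x, ...) {
  cat(sprintf(paste0("<grid_metrics> gridness %.2f, spacing %.1f cm, ",
                     "orientation %.1f deg, field width %.1f cm\n",
                     "  peak rate %.3f, mean rate %.3f, grid: %s\n"),
              x$gridness, x$spacing_cm, x$orientation_deg,
              x$field_width_cm, x$peak_rate, x$mean_rate, x$is_grid))
  invisible(x)
}

#' Inter-trial stability of a cell's firing map
#'
#' Pearson correlation between the smoothed rate maps of two consecutive
#' trials, over bins with rate greater than zero in at least one of the two
#' trials (and defined in both).
#'
#' @param rate_a,rate_b smoothed rate matrices or `rate_map`s of equal size
#' @return correlation in \[-1, 1\], or NA when fewer than 3 bins qualify
#' @export
inter_trial_stability <- function(rate_a, rate_b) {
  if (inherits(rate_a, "rate_map")) rate_a <- rate_a$rate
  if (inherits(rate_b, "rate_map")) rate_b <- rate_b$rate
  stopifnot(all(dim(rate_a) == dim(rate_b)))
  ok <- !is.na(rate_a) & !is.na(rate_b) & (rate_a > 0 | rate_b > 0)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(rate_a[ok]) == 0 || stats::sd(rate_b[ok]) == 0)
    return(NA_real_)
  stats::cor(rate_a[ok], rate_b[ok])
}

#' Build an idealized hexagonal (or square) firing-rate map
#'
#' Places Gaussian firing fields on the vertices of a hexagonal or square
#' lattice; used as a ground-truth fixture for validating the grid metrics.
#'
#' @param spacing lattice spacing in cm
#' @param orientation lattice orientation in degrees
#' @param arena_size arena side length in cm
#' @param bin_size bin side length in cm
#' @param field_sd sd of each firing field in cm
#' @param peak peak rate
#' @param lattice `"hex"` or `"square"`
#' @param center lattice anchor (cm); defaults to the arena center
#' @return a matrix of rates (no NAs)
#' @export
make_lattice_map <- function(spacing, orientation = 0, arena_size = 100,
                             bin_size = 2.5, field_sd = spacing / 6,
                             peak = 1, lattice = c("hex", "square"),
                             center = NULL) {
  lattice <- match.arg(lattice)
  if (is.null(center)) center <- c(arena_size / 2, arena_size / 2)
  nb <- ceiling(arena_size / bin_size)
  cc <- (seq_len(nb) - 0.5) * bin_size
  th <- orientation * pi / 180
  u <- spacing * c(cos(th), sin(th))
  v <- if (lattice == "hex") {
    spacing * c(cos(th + pi / 3), sin(th + pi / 3))
  } else {
    spacing * c(cos(th + pi / 2), sin(th + pi / 2))
  }
  m <- ceiling(2 * arena_size / spacing) + 2L
  ij <- expand.grid(i = -m:m, j = -m:m)
  px <- center[1] + ij$i * u[1] + ij$j * v[1]
  py <- center[2] + ij$i * u[2] + ij$j * v[2]
  keep <- px > -2 * spacing & px < arena_size + 2 * spacing &
    py > -2 * spacing & py < arena_size + 2 * spacing
  px <- px[keep]; py <- py[keep]
  out <- matrix(0, nb, nb)
  for (q in seq_along(px)) {
    gx <- exp(-(cc - px[q])^2 / (2 * field_sd^2))
    gy <- exp(-(cc - py[q])^2 / (2 * field_sd^2))
    out <- out + peak * outer(gx, gy)
  }
  out
}
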