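#' Stripe-cell banks
#'
#' Stripe cells perform linear path integration: each cell integrates the
#' component of running velocity along its preferred direction and fires in
#' parallel periodic bands (Gaussian profile of sd `sigma` about each band,
#' period `lambda`, spatial phase `psi`). A bank holds every combination of
#' preferred direction, spatial phase, and spatial scale.
#'
#' Cross-scale normalization modes (`mode`):
#' \describe{
#'   \item{normalized}{field width grows with spacing
#'     (`sigma = sigma_frac * lambda`) and peak activity shrinks so the area
#'     under each stripe field (`omega * sigma * sqrt(2*pi)`) is identical
#'     across scales; the smallest scale has peak 1.}
#'   \item{equal_peak}{peak activity 1 at every scale, widths as in
#'     normalized mode (fields are no longer normalized).}
#'   \item{equal_width}{every scale keeps the smallest scale's field width;
#'     peaks as in normalized mode by default, or equal (area-preserving)
#'     when `equal_width_preserve_area = TRUE`.}
#'   \item{equal_both}{smallest-scale width and peak 1 at every scale.}
#' }
#'
#' @param scales stripe spacings in cm (positive, non-empty)
#' @param mode cross-scale normalization mode, see Details
#' @param directions preferred directions in degrees
#' @param n_phases number of equally spaced spatial phases per scale
#' @param sigma_frac field sd as a fraction of spacing (default 0.0884)
#' @param omega0 peak activity of the smallest scale (the activity unit of
#'   the bank). The default 1.25 is calibrated so that a category cell
#'   whose learned afferent weights have self-normalized (total weight 1)
#'   still receives suprathreshold drive at its firing fields; at 1 the
#'   learned network sits marginally at its output threshold
#' @param equal_width_preserve_area in `equal_width` mode, scale peaks to
#'   keep the field area constant instead of keeping normalized-mode peaks
#' @return a `stripe_bank`: per-cell vectors `dir_idx`, `theta` (rad),
#'   `psi`, `lambda`, `sigma`, `omega`, plus the direction set and metadata
#' @export
make_stripe_bank <- function(scales = c(20, 35),
                             mode = c("normalized", "equal_peak",
                                      "equal_width", "equal_both"),
                             directions = seq(-80, 80, by = 20),
                             n_phases = 4, sigma_frac = 0.0884,
                             omega0 = 1.25,
                             equal_width_preserve_area = FALSE) {
  mode <- match.arg(mode)
  if (length(scales) == 0 || any(scales <= 0)) stop("scales must be positive")
  scales <- sort(scales)
  lam0 <- scales[1]
  sig0 <- sigma_frac * lam0
  per_scale <- lapply(scales, function(lam) {
    sigma <- switch(mode,
      normalized = sigma_frac * lam,
      equal_peak = sigma_frac * lam,
      equal_width = sig0,
      equal_both = sig0)
    omega <- switch(mode,
      normalized = lam0 / lam,           # omega*sigma constant, omega0 = 1
      equal_peak = 1,
      equal_width = if (equal_width_preserve_area) 1 else lam0 / lam,
      equal_both = 1)
    list(lambda = lam, sigma = sigma, omega = omega0 * omega,
         psi = lam * (seq_len(n_phases) - 1) / n_phases)
  })
  nd <- length(directions)
  cells <- do.call(rbind, lapply(per_scale, function(s) {
    expand.grid(dir_idx = seq_len(nd), psi = s$psi,
                lambda = s$lambda, sigma = s$sigma, omega = s$omega)
  }))
  structure(
    list(directions_deg = directions,
         theta = directions[cells$dir_idx] * pi / 180,
         dir_idx = cells$dir_idx,
         psi = cells$psi, lambda = cells$lambda,
         sigma = cells$sigma, omega = cells$omega,
         scales = scales, mode = mode, n_phases = n_phases,
         sigma_frac = sigma_frac, omega0 = omega0),
    class = "stripe_bank")
}

#' @export
print.stripe_bank <- function(x, ...) {
  cat(sprintf("<stripe_bank> %d cells: %d directions x %d phases x %d scales (%s), mode %s\n",
              length(x$theta), length(x$directions_deg), x$n_phases,
              length(x$scales), paste(x$scales, collapse = "/"), x$mode))
  invisible(x)
}

#' Number of stripe cells in a bank
#' @param bank a stripe bank
#' @export
n_stripe_cells <- function(bank) length(bank$theta)

#' Velocity component along a preferred direction
#'
#' Projects the current movement onto a stripe cell's preferred direction
#' via the cosine law; the result is signed (backwards movement moves the
#' integrated displacement backwards).
#'
#' @param speed running speed in cm/s (non-negative)
#' @param heading movement direction in radians
#' @param theta preferred direction in radians
#' @return directional velocity in cm/s
#' @export
directional_velocity <- function(speed, heading, theta) {
  speed * cos(heading - theta)
}

#' Path-integrate a directional velocity
#'
#' One Euler increment of the per-direction displacement variable; the
#' displacement is reset to 0 at the start of each learning trial.
#'
#' @param D current displacement in cm
#' @param v directional velocity in cm/s
#' @param dt time step in seconds
#' @export
integrate_displacement <- function(D, v, dt) D + v * dt

#' Stripe-cell activity at a given displacement
#'
#' The displacement is reset modulo the spacing and compared with the
#' cell's spatial phase; the wrapped residual (in (-lambda/2, lambda/2\])
#' drives a Gaussian tuning curve of sd `sigma` and peak `omega`. Activity
#' is maximal exactly when `D == psi (mod lambda)` and is lambda-periodic.
#'
#' @param D displacement along the preferred direction, cm
#' @param psi spatial phase, cm
#' @param lambda stripe spacing, cm (> 0)
#' @param sigma field sd, cm (> 0)
#' @param omega peak activity
#' @export
stripe_activity <- function(D, psi, lambda, sigma, omega = 1) {
  stopifnot(all(lambda > 0), all(sigma > 0))
  r <- (D - psi) %% lambda
  r <- r - lambda * (r > lambda / 2)   # wrap to (-lambda/2, lambda/2]
  omega * exp(-r^2 / (2 * sigma^2))
}

#' Evaluate all stripe cells of a bank at given per-direction displacements
#'
#' @param bank a stripe bank
#' @param D per-direction displacement vector (cm), one entry per direction
#'   in `bank$directions_deg`
#' @return activity vector, one entry per stripe cell
#' @export
stripe_activities <- function(bank, D) {
  stopifnot(length(D) == length(bank$directions_deg))
  stripe_activity(D[bank$dir_idx], bank$psi, bank$lambda, bank$sigma,
                  bank$omega)
}

#' Count triple-coactivation maxima of three stripe families in an arena
#'
#' Three stripe-field families of equal spacing `lambda` whose preferred
#' directions differ by 60 degrees are simultaneously at a field maximum on
#' the vertices of a hexagonal lattice with lattice constant
#' `2 * lambda / sqrt(3)`. With one shared maximum anchored at the arena
#' center, this returns the number of such vertices inside the square arena
#' (boundaries included). The count falls with spacing, quantifying why
#' small-scale coactivations are sampled more often during navigation.
#'
#' @param lambda stripe spacing in cm (> 0)
#' @param arena_size arena side length in cm
#' @return integer count of coactivation maxima
#' @export
count_coactivation_maxima <- function(lambda, arena_size = 100) {
  stopifnot(lambda > 0, arena_size > 0)
  a <- 2 * lambda / sqrt(3)
  cx <- arena_size / 2
  m <- ceiling(2 * arena_size / a) + 2L
  ij <- expand.grid(i = -m:m, j = -m:m)
  x <- cx + a * (ij$i + 0.5 * ij$j)
  y <- cx + a * (sqrt(3) / 2) * ij$j
  tol <- 1e-9
  sum(x >= -tol & x <= arena_size + tol &
      y >= -tol & y <= arena_size + tol)
}
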