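#' Steady current injection into a single category cell
#'
#' Simulates the in-vitro paradigm: a constant current `I` drives one
#' category cell in the absence of bottom-up stripe inputs and recurrent
#' inhibition,
#' \deqn{dV/dt = \beta[-A V + (B - V)(I + \gamma f(V) z)]}
#' with the habituative gate following its usual dynamics. The interplay of
#' self-excitatory amplification and activity-dependent habituation
#' produces (damped) membrane-potential oscillations; optional Brownian
#' noise unmasks them.
#'
#' @param I injected current amplitude (dimensionless, >= 0)
#' @param beta response rate
#' @param eps habituation rate
#' @param params a [som_params()]
#' @param duration trace duration in seconds
#' @param noise logical; add Brownian increments of intensity
#'   `params$sigma_noise`
#' @param seed optional integer seed set before integrating
#' @return an `mpo_trace`: `times`, `V`, `z`, `I`, `beta`, `eps`, `dt`
#' @export
inject_current <- function(I, beta = 1, eps = 0.05, params = som_params(),
                           duration = 50, noise = TRUE, seed = NULL) {
  stopifnot(I >= 0, duration > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- params
  n <- floor(duration / p$dt)
  tr <- inject_current_cpp(rep(I, n), beta, eps, p$A, p$B, p$gamma,
                           p$Gamma, p$mu,
                           if (noise) p$sigma_noise else 0, p$dt, TRUE)
  structure(list(times = seq(0, by = p$dt, length.out = n),
                 V = tr$V, z = tr$z, I = I, beta = beta, eps = eps,
                 dt = p$dt),
            class = "mpo_trace")
}

#' @export
print.mpo_trace <- function(x, ...) {
  cat(sprintf("<mpo_trace> I = %g, beta = %g, eps = %g, %.0f s at dt = %g s\n",
              x$I, x$beta, x$eps, length(x$V) * x$dt, x$dt))
  invisible(x)
}

#' Dominant oscillation frequency of a potential trace
#'
#' Subtracts the trace mean and takes the FFT; returns the frequency (in
#' Hz, on the grid `1/duration`) maximizing the power spectrum over
#' (0, Nyquist\]. No window or taper is applied, so spectra are
#' bit-reproducible. A constant trace has an empty spectrum and returns 0
#' with attribute `flat = TRUE`.
#'
#' @param trace numeric potential series, or an `mpo_trace`
#' @param dt sampling interval in seconds (taken from an `mpo_trace`)
#' @return frequency in Hz with attribute `flat`
#' @export
mpo_frequency <- function(trace, dt = 0.002) {
  if (inherits(trace, "mpo_trace")) { dt <- trace$dt; trace <- trace$V }
  n <- length(trace)
  if (n < 2) stop("trace must have at least 2 samples")
  x <- trace - mean(trace)
  if (all(abs(x) < 1e-14))
    return(structure(0, flat = TRUE))
  pw <- Mod(stats::fft(x))^2
  kmax <- floor(n / 2)                  # positive frequencies up to Nyquist
  k <- which.max(pw[2:(kmax + 1)])
  structure(k / (n * dt), flat = FALSE)
}

#' Sweep current amplitudes across rate gradients and estimate MPO
#' frequencies
#'
#' Runs [inject_current()] + [mpo_frequency()] for every combination of
#' response rate, habituation rate, and current amplitude, with `reps`
#' noisy replicates each, and aggregates mean and SEM of the estimated
#' frequency. MPO frequency covaries with both the response rate and the
#' habituation rate.
#'
#' @param beta_values,eps_values,amplitudes non-empty numeric grids
#' @param reps replicates per combination (use >= 5 with noise)
#' @param seed master seed; replicate seeds are derived deterministically
#' @param params a [som_params()]
#' @param duration seconds per trace
#' @param noise logical
#' @return a tibble (beta, eps, I, mean_freq, sem_freq, n)
#' @export
sweep_mpo <- function(beta_values = c(0.2, 0.6, 1),
                      eps_values = 0.05,
                      amplitudes = c(0.5, 1, 1.5),
                      reps = 5, seed = 1, params = som_params(),
                      duration = 50, noise = TRUE) {
  stopifnot(length(beta_values) > 0, length(eps_values) > 0,
            length(amplitudes) > 0, reps >= 1)
  grid <- expand.grid(beta = beta_values, eps = eps_values,
                      I = amplitudes, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    freqs <- vapply(seq_len(reps), function(r) {
      s <- (as.integer(seed) + 7919L * g + 104729L * r) %% 2147483647L
      as.numeric(mpo_frequency(inject_current(
        grid$I[g], grid$beta[g], grid$eps[g], params,
        duration = duration, noise = noise, seed = s)))
    }, 0)
    tibble::tibble(beta = grid$beta[g], eps = grid$eps[g], I = grid$I[g],
                   mean_freq = mean(freqs),
                   sem_freq = if (reps > 1) stats::sd(freqs) / sqrt(reps) else NA_real_,
                   n = reps)
  })
  dplyr::bind_rows(rows)
}
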