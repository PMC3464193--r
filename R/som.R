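#' Shared dynamical parameters of the category-cell network
#'
#' Category (map) cells obey shunting dynamics in a recurrent on-center
#' off-surround network. The on-center is a habituatively gated
#' self-excitatory feedback signal; the off-surround is threshold-linear
#' recurrent inhibition from the other cells of the local population.
#'
#' @param A passive decay rate (leak)
#' @param B excitatory saturation (upper potential bound)
#' @param C inhibitory saturation (potentials stay above -C)
#' @param gamma self-excitatory feedback gain
#' @param D_inh recurrent off-surround inhibition strength
#' @param Gamma output threshold of the threshold-linear signal function
#' @param lambda_w instar learning rate
#' @param mu transmitter depletion coefficient
#' @param sigma_noise Brownian noise intensity; each Euler step adds a
#'   N(0, sigma_noise^2 * dt) increment to every potential when noise is on
#' @param dt Euler integration step in seconds
#' @return a `som_params` list
#' @export
som_params <- function(A = 3, B = 1, C = 0.5, gamma = 17.5, D_inh = 17.5,
                       Gamma = 0.1, lambda_w = 0.025, mu = 1.5,
                       sigma_noise = 0.2, dt = 0.002) {
  p <- list(A = A, B = B, C = C, gamma = gamma, D_inh = D_inh,
            Gamma = Gamma, lambda_w = lambda_w, mu = mu,
            sigma_noise = sigma_noise, dt = dt)
  if (any(unlist(p) < 0)) stop("som_params must be non-negative")
  if (B <= Gamma) stop("B must exceed the output threshold Gamma")
  if (dt <= 0) stop("dt must be positive")
  structure(p, class = "som_params")
}

#' One local population of category cells
#'
#' A population shares a response rate `beta` (multiplicative rate constant
#' of the membrane dynamics, decreasing dorsoventrally) and a habituation
#' rate `eps` (rate constant of the transmitter dynamics). State: membrane
#' potentials `V` (init 0), habituative transmitter gates `z` (init 1), and
#' adaptive weights `W` from every stripe cell to every category cell
#' (init Uniform(0, 0.1) at the start of the first learning trial).
#'
#' @param n_cells number of category cells
#' @param n_stripe number of afferent stripe cells
#' @param beta response rate in (0, 1]
#' @param eps habituation rate
#' @param W optional initial weight matrix (`n_stripe` x `n_cells`);
#'   drawn Uniform(0, 0.1) from the current RNG state when omitted
#' @return a `som_population`
#' @export
som_population <- function(n_cells, n_stripe, beta = 1, eps = 0.05,
                           W = NULL) {
  stopifnot(n_cells >= 1, n_stripe >= 1, beta > 0, eps > 0)
  if (is.null(W)) {
    W <- matrix(stats::runif(n_stripe * n_cells, 0, 0.1), n_stripe, n_cells)
  }
  stopifnot(nrow(W) == n_stripe, ncol(W) == n_cells)
  structure(list(beta = beta, eps = eps,
                 V = numeric(n_cells), z = rep(1, n_cells), W = W,
                 n_cells = n_cells, n_stripe = n_stripe),
            class = "som_population")
}

#' @export
print.som_population <- function(x, ...) {
  cat(sprintf("<som_population> %d cells, beta %g, eps %g, %d stripe inputs\n",
              x$n_cells, x$beta, x$eps, x$n_stripe))
  invisible(x)
}

#' Threshold-linear output signal
#'
#' @param V membrane potential(s)
#' @param Gamma output threshold
#' @return `max(V - Gamma, 0)`
#' @export
output_signal <- function(V, Gamma = 0.1) pmax(V - Gamma, 0)

#' One Euler step of a category-cell population (reference implementation)
#'
#' Advances potentials and transmitter gates by one time step given the
#' current stripe input vector. This is the plain-R reference for the
#' compiled trial loop ([run_trial()]); both implement, per cell i,
#' \deqn{dV_i/dt = \beta[-A V_i + (B - V_i) E_i - (C + V_i) D \sum_{j \ne i} O_j]}
#' with on-center drive \eqn{E_i} and output/inhibitory signal \eqn{O_j}
#' depending on the model variant:
#' \itemize{
#'   \item `base`: \eqn{E_i = \sum_k W_{ki} S_k + \gamma f(V_i) z_i},
#'     \eqn{O_j = f(V_j)}; the gate depletes with the signal it gates,
#'     \eqn{dz_i/dt = \epsilon[(1 - z_i) - \mu z_i (\gamma f(V_i))^2]}.
#'   \item `v1`: the gate multiplies bottom-up input plus on-center
#'     feedback, \eqn{E_i = z_i(\sum_k W_{ki} S_k + \gamma f(V_i))}, and its
#'     depletion uses that full gated signal.
#'   \item `v2`: output and inhibitory signals are also gated,
#'     \eqn{O_j = f(V_j) z_j}, with \eqn{E_i} and the gate law as in `base`.
#' }
#' Noise, when enabled, adds independent N(0, sigma_noise^2 dt) increments.
#'
#' @param pop a [som_population()]
#' @param S stripe activity vector (length `pop$n_stripe`)
#' @param params a [som_params()]
#' @param variant `"base"`, `"v1"`, or `"v2"`
#' @param noise logical; add Brownian increments to the potentials
#' @return the population with updated `V` and `z`
#' @export
step_population <- function(pop, S, params = som_params(),
                            variant = c("base", "v1", "v2"),
                            noise = FALSE) {
  variant <- match.arg(variant)
  if (length(S) != pop$n_stripe)
    stop("stripe input length does not match the weight matrix")
  p <- params
  f <- output_signal(pop$V, p$Gamma)
  bu <- as.numeric(crossprod(pop$W, S))       # bottom-up  sum_k W_ki S_k
  out <- switch(variant, base = f, v1 = f, v2 = f * pop$z)
  E <- switch(variant,
    base = bu + p$gamma * f * pop$z,
    v1   = pop$z * (bu + p$gamma * f),
    v2   = bu + p$gamma * f * pop$z)
  G <- switch(variant,                        # signal the gate depletes with
    base = p$gamma * f,
    v1   = bu + p$gamma * f,
    v2   = p$gamma * f)
  inh <- sum(out) - out
  dV <- pop$beta * (-p$A * pop$V + (p$B - pop$V) * E -
                      (p$C + pop$V) * p$D_inh * inh)
  dz <- pop$eps * ((1 - pop$z) - p$mu * pop$z * G^2)
  pop$V <- pop$V + p$dt * dV
  if (noise && p$sigma_noise > 0)
    pop$V <- pop$V + stats::rnorm(pop$n_cells, 0, p$sigma_noise * sqrt(p$dt))
  pop$z <- pop$z + p$dt * dz
  pop
}

#' One Euler step of the competitive instar learning law
#'
#' Weights onto each category cell track the normalized time-average of the
#' stripe input pattern while the cell's learning gate is open:
#' \deqn{dW_{ki}/dt = \lambda_w g_i [S_k (1 - W_{ki}) - W_{ki} \sum_{m \ne k} S_m]}
#' whose equilibrium is \eqn{W_{ki} = S_k / \sum_m S_m}; afferent weights
#' self-normalize toward a total of at most 1. Under `v1` all afferents
#' compete for a constant total available weight of 2: the growth term uses
#' \eqn{(2 - \sum_m W_{mi})} in place of \eqn{(1 - W_{ki})}.
#'
#' @param W weight matrix (`n_stripe` x `n_cells`)
#' @param S stripe activity vector
#' @param f learning-gate vector (category-cell output signals; for `v2`
#'   pass the gated outputs `f * z`) -- learning occurs only where `f > 0`
#' @param lambda_w learning rate
#' @param dt time step in seconds
#' @param variant `"base"`, `"v1"`, or `"v2"`
#' @return updated weight matrix
#' @export
update_weights <- function(W, S, f, lambda_w = 0.025, dt = 0.002,
                           variant = c("base", "v1", "v2")) {
  variant <- match.arg(variant)
  stopifnot(length(S) == nrow(W), length(f) == ncol(W), all(f >= 0))
  act <- which(f > 0)
  if (!length(act)) return(W)
  Stot <- sum(S)
  for (i in act) {
    w <- W[, i]
    dw <- if (variant == "v1") {
      S * (2 - sum(w)) - w * (Stot - S)
    } else {
      S - w * Stot          # = S*(1 - w) - w*(Stot - S)
    }
    W[, i] <- w + dt * lambda_w * f[i] * dw
  }
  W
}

#' Run one learning trial of the full model
#'
#' Resets potentials to 0, transmitter gates to 1, and the per-direction
#' displacement variables to 0 (weights persist across trials), then
#' iterates stripe evaluation, population dynamics, and (optionally)
#' weight updates at every trajectory sample. The per-sample output of
#' every cell (`f`, or `f * z` under `v2`) is logged for rate-map
#' accumulation. All populations are advanced in lock-step so stripe
#' activities are evaluated once per sample.
#'
#' @param model a list of [som_population()]s (independent populations)
#' @param bank a [make_stripe_bank()]
#' @param traj a uniformly sampled trajectory (its `dt` must equal
#'   `params$dt`)
#' @param params a [som_params()]
#' @param variant model variant, see [step_population()]
#' @param learn logical; apply the instar learning law
#' @param noise logical; inject Brownian noise into the potentials
#' @return list with the updated `model` and `log`, a samples x cells
#'   matrix of output activities (columns ordered population by population)
#' @export
run_trial <- function(model, bank, traj, params = som_params(),
                      variant = c("base", "v1", "v2"),
                      learn = TRUE, noise = FALSE) {
  variant <- match.arg(variant)
  if (inherits(model, "som_population")) model <- list(model)
  ns <- n_stripe_cells(bank)
  for (pop in model)
    if (pop$n_stripe != ns) stop("population/stripe-bank shape mismatch")
  if (length(traj$times) == 0)
    return(list(model = model,
                log = matrix(0, 0, sum(vapply(model, function(p) as.integer(p$n_cells), 0L)))))
  if (is.na(traj$dt) || abs(traj$dt - params$dt) > 1e-9)
    stop("trajectory must be resampled to the integration step params$dt")
  W <- do.call(cbind, lapply(model, `[[`, "W"))
  ncell <- vapply(model, function(p) as.integer(p$n_cells), 0L)
  pop_id <- rep(seq_along(model), ncell)
  beta <- rep(vapply(model, `[[`, 0, "beta"), ncell)
  eps <- rep(vapply(model, `[[`, 0, "eps"), ncell)
  res <- run_trial_cpp(traj$speed, traj$heading, params$dt,
                       bank$directions_deg * pi / 180,
                       bank$dir_idx - 1L, bank$psi, bank$lambda,
                       bank$sigma, bank$omega,
                       W, pop_id - 1L, beta, eps,
                       params$A, params$B, params$C, params$D_inh,
                       params$gamma, params$Gamma, params$lambda_w,
                       params$mu,
                       if (noise) params$sigma_noise else 0,
                       match(variant, c("base", "v1", "v2")) - 1L,
                       learn)
  off <- c(0L, cumsum(ncell))
  for (j in seq_along(model)) {
    idx <- (off[j] + 1L):off[j + 1L]
    model[[j]]$W <- res$W[, idx, drop = FALSE]
    model[[j]]$V <- res$V[idx]
    model[[j]]$z <- res$z[idx]
  }
  list(model = model, log = res$log)
}

#' Single-cell dynamics under a stripe-field input (Case-1 paradigm)
#'
#' Simulates one category cell (no recurrent inhibition, no learning)
#' driven by the Gaussian activity profile of a single small-scale stripe
#' field traversed at constant speed, for several response rates and three
#' feedback circuits: no self-excitatory feedback (`gamma = 0`), ungated
#' feedback (`z` pinned at 1), and habituatively gated feedback. Slower
#' response rates yield temporally delayed, broader responses with smaller
#' peaks under gated feedback; ungated feedback perseverates after the
#' input ends.
#'
#' @param betas response rates to simulate
#' @param eps habituation rate
#' @param params a [som_params()]
#' @param speed traversal speed in cm/s
#' @param lambda,sigma_frac spacing and relative width of the input stripe
#'   field
#' @param duration trace duration in seconds
#' @param center time of the field center in seconds
#' @param input_gain amplitude of the pulse. In the network a category
#'   cell's drive at a field crossing pools several coactive stripe
#'   afferents (multiple phases and directions), so the single-cell
#'   equivalent is a few times one cell's peak activity; 4 lets even the
#'   slowest response rate summate to threshold within the pulse
#' @return a tibble with columns `circuit`, `beta`, `time`, `input`, `V`,
#'   `z`, `gfz` (gated feedback signal), `f` (output)
#' @export
simulate_case1 <- function(betas = c(1, 0.5, 0.2, 0.1), eps = 0.05,
                           params = som_params(), speed = 10,
                           lambda = 20, sigma_frac = 0.0884,
                           duration = 8, center = 1, input_gain = 4) {
  p <- params
  n <- floor(duration / p$dt) + 1L
  tt <- seq(0, by = p$dt, length.out = n)
  sigma_t <- sigma_frac * lambda / speed       # field sd in seconds
  inp <- input_gain * exp(-(tt - center)^2 / (2 * sigma_t^2))
  circuits <- c("no_feedback", "ungated", "gated")
  out <- list()
  for (ci in seq_along(circuits)) {
    circ <- circuits[ci]
    for (b in betas) {
      tr <- inject_current_cpp(inp, b, eps, p$A, p$B,
                               if (circ == "no_feedback") 0 else p$gamma,
                               p$Gamma, p$mu, 0, p$dt,
                               circ != "ungated")
      out[[length(out) + 1L]] <- tibble::tibble(
        circuit = circ, beta = b, time = tt, input = inp,
        V = tr$V, z = tr$z,
        gfz = p$gamma * pmax(tr$V - p$Gamma, 0) * tr$z,
        f = pmax(tr$V - p$Gamma, 0))
    }
  }
  dplyr::bind_rows(out)
}
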