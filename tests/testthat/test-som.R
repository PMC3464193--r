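test_that("output signal is threshold-linear", {
  expect_equal(output_signal(0.1, 0.1), 0)
  expect_equal(output_signal(0.5, 0.1), 0.4)
  expect_equal(output_signal(-0.3, 0.1), 0)
  expect_equal(output_signal(c(-1, 0.2, 2), 0.1), c(0, 0.1, 1.9))
})

test_that("quiescence is a fixed point of the noise-free dynamics", {
  set.seed(1)
  p <- som_params()
  pop <- som_population(5, 8)
  for (i in 1:200) pop <- step_population(pop, rep(0, 8), p)
  expect_equal(pop$V, rep(0, 5))
  expect_equal(pop$z, rep(1, 5))
})

test_that("noise-free potentials respect the shunting bounds", {
  p <- som_params()
  set.seed(42)
  for (rep in 1:5) {
    pop <- som_population(6, 10)
    pop$V <- runif(6, -p$C, p$B)          # arbitrary admissible start
    for (i in 1:500) {
      S <- runif(10, 0, 2) * rbinom(10, 1, 0.5)
      pop <- step_population(pop, S, p,
                             variant = sample(c("base", "v1", "v2"), 1))
      expect_true(all(pop$V >= -p$C - 1e-12 & pop$V <= p$B + 1e-12))
      expect_true(all(pop$z > 0 & pop$z <= 1 + 1e-12))
    }
  }
})

test_that("transmitter gate converges to the habituation equilibrium", {
  # with the gated signal G held fixed, dz/dt = eps[(1-z) - mu z G^2]
  # has equilibrium 1 / (1 + mu G^2)
  p <- som_params()
  pop <- som_population(1, 1)
  pop$V <- 0.6                            # f = 0.5, G = gamma * f
  G <- p$gamma * output_signal(pop$V, p$Gamma)
  z <- 1
  for (i in 1:50000) {
    z <- z + p$dt * 0.5 * ((1 - z) - p$mu * z * G^2)
  }
  expect_equal(z, 1 / (1 + p$mu * G^2), tolerance = 1e-6)
})

test_that("weights freeze when the learning gate is closed", {
  W <- matrix(runif(12), 4, 3)
  W2 <- update_weights(W, runif(4), rep(0, 3))
  expect_identical(W, W2)
})

test_that("instar learning converges to the normalized input pattern", {
  S <- c(2, 1, 1)
  W <- matrix(runif(3, 0, 0.5), 3, 1)
  for (i in 1:30000) W <- update_weights(W, S, 1, lambda_w = 0.025, dt = 0.01)
  expect_equal(as.numeric(W), S / sum(S), tolerance = 1e-3)
})

test_that("column weight sums stay within the learned bound", {
  # from inside the simplex, the base law keeps each column total <= 1
  set.seed(3)
  K <- 10
  W <- matrix(runif(K * 4, 0, 1 / K), K, 4)
  for (i in 1:2000) {
    S <- runif(K, 0, 2)
    f <- runif(4, 0, 0.9)
    W <- update_weights(W, S, f, lambda_w = 0.5, dt = 0.01)
    expect_true(all(colSums(W) <= 1 + 1e-6))
    expect_true(all(W >= -1e-12))
  }
  # from above, the total decays monotonically toward 1
  W <- matrix(runif(K, 0.2, 0.4), K, 1)   # colsum ~ 3
  prev <- colSums(W)
  for (i in 1:500) {
    W <- update_weights(W, runif(K, 0.5, 1.5), 0.5, lambda_w = 0.5, dt = 0.01)
    cs <- colSums(W)
    expect_lte(cs, prev + 1e-9)
    prev <- cs
  }
})

test_that("variation-1 weights compete for a total available weight of 2", {
  S <- c(2, 1, 1)
  W <- matrix(runif(3, 0, 0.2), 3, 1)
  for (i in 1:30000) W <- update_weights(W, S, 1, lambda_w = 0.025,
                                         dt = 0.01, variant = "v1")
  expect_lte(sum(W), 2 + 1e-6)
  # equilibrium of dW = S(2 - colsum) - W(Stot - S)
  cs <- sum(W)
  expect_equal(as.numeric(W), S * (2 - cs) / (sum(S) - S),
               tolerance = 1e-3)
})

test_that("a full Euler step matches two half steps to second order", {
  p1 <- som_params(dt = 0.002)
  p2 <- som_params(dt = 0.001)
  set.seed(5)
  S <- runif(8, 0, 1.5)
  pop <- som_population(4, 8)
  pop$V <- runif(4, -0.2, 0.8); pop$z <- runif(4, 0.3, 1)
  full <- step_population(pop, S, p1)
  half <- step_population(step_population(pop, S, p2), S, p2)
  # difference between the schemes is O(dt^2), far below the step change
  expect_lt(max(abs(full$V - half$V)), 2e-3)
  expect_lt(max(abs(full$z - half$z)), 2e-3)
  step_size <- max(abs(full$V - pop$V))
  expect_lt(max(abs(full$V - half$V)), 0.05 * step_size)
})

test_that("compiled trial loop matches the R reference stepper", {
  set.seed(9)
  bank <- make_stripe_bank(c(20, 35))
  n <- 300
  traj <- straight_trajectory(speed = 20, duration = (n - 1) * 0.002)
  p <- som_params()
  pop <- som_population(4, n_stripe_cells(bank))
  res <- run_trial(list(pop), bank, traj, p, learn = TRUE)
  # replay in R: same displacement, stripe, dynamics and learning order
  rpop <- pop
  D <- rep(0, 9)
  for (t in seq_len(n)) {
    S <- stripe_activities(bank, D)
    f_old <- output_signal(rpop$V, p$Gamma)
    W_old <- rpop$W
    rpop <- step_population(rpop, S, p)       # V, z step uses old weights
    rpop$W <- update_weights(W_old, S, f_old, p$lambda_w, p$dt)
    D <- D + directional_velocity(traj$speed[t], traj$heading[t],
                                  bank$directions_deg * pi / 180) * p$dt
  }
  expect_equal(res$model[[1]]$V, rpop$V, tolerance = 1e-10)
  expect_equal(res$model[[1]]$z, rpop$z, tolerance = 1e-10)
  expect_equal(res$model[[1]]$W, rpop$W, tolerance = 1e-8)
})

test_that("run_trial is deterministic without noise and logs outputs", {
  set.seed(2)
  bank <- make_stripe_bank(20)
  traj <- synthesize_trajectory(5, seed = 3)
  pop <- som_population(3, n_stripe_cells(bank))
  a <- run_trial(list(pop), bank, traj, learn = FALSE)
  b <- run_trial(list(pop), bank, traj, learn = FALSE)
  expect_identical(a$log, b$log)
  expect_equal(dim(a$log), c(length(traj$times), 3))
  expect_identical(a$model[[1]]$W, pop$W)   # no learning, weights frozen
})

test_that("single-cell dynamics reproduce the rate-gradient signatures", {
  tr <- simulate_case1(betas = c(1, 0.5, 0.2, 0.1))
  by_beta <- function(circ, fn) {
    sub <- tr[tr$circuit == circ, ]
    vapply(split(sub, sub$beta), fn, 0)[c("1", "0.5", "0.2", "0.1")]
  }
  # gated feedback: peak falls, response broadens and is delayed as the
  # response rate decreases
  peaks <- by_beta("gated", function(d) max(d$f))
  expect_true(all(diff(peaks) < 0))
  fwhm <- by_beta("gated", function(d) sum(d$f > max(d$f) / 2) * 0.002)
  expect_true(all(diff(fwhm) > 0))
  tpk <- by_beta("gated", function(d) d$time[which.max(d$f)])
  expect_true(all(diff(tpk) > 0))
  # the gate collapses during the gated response
  zmin <- by_beta("gated", function(d) min(d$z))
  expect_true(all(zmin < 0.6))
  # ungated feedback perseverates after the input ends
  sub <- tr[tr$circuit == "ungated" & tr$beta == 1, ]
  expect_gt(sub$f[nrow(sub)], 0.5 * max(sub$f))
  # without feedback the response decays after input offset with the
  # passive time constant ~ 1/(beta * A)
  nf <- tr[tr$circuit == "no_feedback" & tr$beta == 1, ]
  expect_lt(nf$f[nrow(nf)], 0.05 * max(nf$f))
  t_off <- 1 + 4 * (0.0884 * 20 / 10)
  after <- nf[nf$time > t_off & nf$V > 0.01 * max(nf$V), ]
  fit <- stats::coef(stats::lm(log(V) ~ time, after))
  expect_equal(unname(fit[2]), -1 * 3, tolerance = 0.35)
})
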