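#' Declarative specification of a simulation case
#'
#' Cases 1-13 cover the model's published simulation settings: Case 1 is
#' the single-cell dynamics paradigm; Cases 2-10 learn grid cells along a
#' response-rate gradient under model/input variations (novel trajectories,
#' three stripe scales, noise, model variations 1 and 2, and the stripe
#' normalization ablations); Case 11 uses a habituation-rate gradient at
#' fixed response rate; Cases 12-13 are the current-injection MPO sweeps.
#'
#' `scale = "desk"` gives reduced presets (3 ladder points, 10 cells per
#' population, 10 trials, synthetic 10-minute trajectory); `scale = "full"`
#' restores the published settings (full ladders, 25 cells, 40 trials).
#'
#' @param case_id integer 1-13
#' @param scale `"desk"` or `"full"`
#' @param seed master seed; all child seeds derive from it
#' @param ... overrides for any spec field (e.g. `ladder`, `n_cells`,
#'   `n_trials`, `eps`, `scales`, `stripe_mode`, `variant`, `noise`,
#'   `trajectory_policy`, `duration`, `metrics_trials`, `trajectory`)
#' @return a `case_spec` list
#' @export
case_spec <- function(case_id, scale = c("desk", "full"), seed = 1, ...) {
  scale <- match.arg(scale)
  if (!case_id %in% 1:13) stop("case_id must be in 1..13")
  desk <- scale == "desk"
  beta_ladder <- if (desk) c(1, 0.6, 0.2) else seq(1, 0.1, by = -0.1)
  eps_ladder_full <- c(0.5, 0.2, 0.1, 0.05, 0.02, 0.01, 0.005, 0.002, 0.001)
  eps_ladder <- if (desk) c(0.5, 0.02, 0.001) else eps_ladder_full
  spec <- list(
    case_id = case_id, scale = scale, seed = as.integer(seed),
    gradient = "response_rate", ladder = beta_ladder,
    beta = 1, eps = 0.05,
    n_cells = if (desk) 10L else 25L,
    n_trials = if (desk) 10L else 40L,
    scales = c(20, 35), stripe_mode = "normalized", stripe_omega0 = NULL,
    variant = "base", noise = FALSE,
    trajectory_policy = "fixed",
    duration = 600, arena_size = 100, dt = 0.002,
    amplitudes = c(0.5, 1, 1.5), reps = 5, mpo_duration = 50,
    metrics_trials = "last", trajectory = NULL)
  mod <- switch(as.character(case_id),
    "1" = list(ladder = c(1, 0.5, 0.2, 0.1)),
    "2" = list(),
    "3" = list(trajectory_policy = "novel_per_trial"),
    "4" = list(scales = c(20, 35, 50)),
    "5" = list(noise = TRUE),
    "6" = list(variant = "v1"),
    "7" = list(variant = "v2"),
    "8" = list(stripe_mode = "equal_peak"),
    "9" = list(stripe_mode = "equal_width"),
    "10" = list(stripe_mode = "equal_both"),
    "11" = list(gradient = "habituation_rate", ladder = eps_ladder),
    "12" = list(noise = TRUE,
                amplitudes = if (desk) c(0.5, 1, 1.5) else c(0.5, 1, 1.5, 2, 2.5)),
    "13" = list(gradient = "habituation_rate", ladder = eps_ladder,
                noise = TRUE))
  spec[names(mod)] <- mod
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown)) stop("unknown case_spec field(s): ",
                            paste(unknown, collapse = ", "))
  spec[names(dots)] <- dots
  if (spec$n_cells < 1) stop("n_cells must be at least 1")
  if (is.unsorted(rev(spec$ladder), strictly = TRUE) &&
      is.unsorted(spec$ladder, strictly = TRUE))
    stop("ladder must be strictly monotone")
  structure(spec, class = "case_spec")
}

#' @export
print.case_spec <- function(x, ...) {
  cat(sprintf("<case_spec> case %d (%s), %s ladder: %s\n", x$case_id,
              x$scale, x$gradient, paste(x$ladder, collapse = ", ")))
  invisible(x)
}

child_seed <- function(seed, a, b = 0L) {
  (as.integer(seed) + 7919L * as.integer(a) + 104729L * as.integer(b)) %%
    2147483647L
}

#' Run a simulation case
#'
#' Dispatches on the case type: learning cases (2-11) run the full SOM
#' model along the specified rate gradient, compute per-cell grid metrics,
#' and aggregate trend tables; Case 1 returns the single-cell dynamics
#' traces; Cases 12-13 return the MPO frequency sweep.
#'
#' For learning cases the returned list has:
#' \describe{
#'   \item{metrics}{per-cell tibble (population gradient value, cell,
#'     trial, gridness, spacing_cm, orientation_deg, field_width_cm,
#'     peak_rate, mean_rate, stability)}
#'   \item{trends}{[trend_table()] aggregate over the gradient}
#'   \item{model}{final populations (weights, state)}
#'   \item{maps}{final-trial smoothed rate maps per population}
#'   \item{manifest}{config, seeds, package version (reproducibility)}
#' }
#'
#' @param spec a [case_spec()]
#' @param params a [som_params()]
#' @param progress print per-trial progress to stderr
#' @return see Details
#' @export
run_case <- function(spec, params = som_params(), progress = FALSE) {
  stopifnot(inherits(spec, "case_spec"))
  if (spec$case_id == 1) {
    return(simulate_case1(betas = spec$ladder, eps = spec$eps,
                          params = params))
  }
  if (spec$case_id %in% c(12, 13)) {
    tab <- if (spec$gradient == "response_rate") {
      sweep_mpo(beta_values = spec$ladder, eps_values = spec$eps,
                amplitudes = spec$amplitudes, reps = spec$reps,
                seed = spec$seed, params = params,
                duration = spec$mpo_duration, noise = spec$noise)
    } else {
      sweep_mpo(beta_values = spec$beta, eps_values = spec$ladder,
                amplitudes = spec$amplitudes, reps = spec$reps,
                seed = spec$seed, params = params,
                duration = spec$mpo_duration, noise = spec$noise)
    }
    return(tab)
  }
  run_learning_case(spec, params, progress)
}

run_learning_case <- function(spec, params, progress = FALSE) {
  set.seed(spec$seed)
  traj <- spec$trajectory
  if (is.null(traj)) {
    traj <- synthesize_trajectory(spec$duration, spec$arena_size,
                                  dt = spec$dt,
                                  seed = child_seed(spec$seed, 1L))
  } else if (is.na(traj$dt) || abs(traj$dt - spec$dt) > 1e-9) {
    traj <- resample_trajectory(traj, spec$dt)
  }
  bank <- if (is.null(spec$stripe_omega0)) {
    make_stripe_bank(scales = spec$scales, mode = spec$stripe_mode)
  } else {
    make_stripe_bank(scales = spec$scales, mode = spec$stripe_mode,
                     omega0 = spec$stripe_omega0)
  }
  ns <- n_stripe_cells(bank)
  grad_beta <- spec$gradient == "response_rate"
  model <- lapply(seq_along(spec$ladder), function(pidx) {
    set.seed(child_seed(spec$seed, 2L, pidx))
    som_population(spec$n_cells, ns,
                   beta = if (grad_beta) spec$ladder[pidx] else spec$beta,
                   eps = if (grad_beta) spec$eps else spec$ladder[pidx])
  })
  metric_trials <- if (identical(spec$metrics_trials, "all"))
    seq_len(spec$n_trials) else spec$n_trials
  prev_maps <- NULL
  metrics <- list()
  maps_last <- NULL
  for (trial in seq_len(spec$n_trials)) {
    ttraj <- traj
    if (spec$trajectory_policy == "novel_per_trial" && trial > 1) {
      set.seed(child_seed(spec$seed, 3L, trial))
      ttraj <- rotate_and_prefix(traj, stats::runif(1, 0, 2 * pi))
    }
    set.seed(child_seed(spec$seed, 4L, trial))
    res <- run_trial(model, bank, ttraj, params, variant = spec$variant,
                     learn = TRUE, noise = spec$noise)
    model <- res$model
    rmaps <- accumulate_maps(ttraj, res$log)
    if (inherits(rmaps, "rate_map")) rmaps <- list(rmaps)
    smoothed <- lapply(rmaps, smooth_and_rate)
    if (trial %in% metric_trials) {
      metrics[[length(metrics) + 1L]] <-
        collect_metrics(spec, smoothed, prev_maps, trial)
    }
    prev_maps <- smoothed
    if (trial == spec$n_trials) maps_last <- smoothed
    if (progress)
      message(sprintf("case %d trial %d/%d done", spec$case_id, trial,
                      spec$n_trials))
  }
  metrics <- dplyr::bind_rows(metrics)
  list(metrics = metrics, trends = trend_table(metrics),
       model = model, maps = maps_last,
       manifest = list(spec = unclass(spec),
                       params = unclass(params),
                       package_version = as.character(utils::packageVersion("gridsom"))))
}

collect_metrics <- function(spec, smoothed, prev_maps, trial) {
  n_cells <- spec$n_cells
  rows <- lapply(seq_along(smoothed), function(ci) {
    pidx <- (ci - 1L) %/% n_cells + 1L
    # silent cells give constant maps whose autocorrelations are undefined;
    # their grid measures are reported as NA
    gm <- suppressWarnings(
      grid_metrics(autocorrelogram(smoothed[[ci]]), smoothed[[ci]]))
    stab <- if (is.null(prev_maps)) NA_real_ else
      inter_trial_stability(smoothed[[ci]], prev_maps[[ci]])
    tibble::tibble(
      population = spec$ladder[pidx],
      cell = (ci - 1L) %% n_cells + 1L,
      trial = trial,
      gridness = gm$gridness, spacing_cm = gm$spacing_cm,
      orientation_deg = gm$orientation_deg,
      field_width_cm = gm$field_width_cm,
      peak_rate = gm$peak_rate, mean_rate = gm$mean_rate,
      stability = stab)
  })
  dplyr::bind_rows(rows)
}

circular_mean_60 <- function(deg) {
  deg <- deg[!is.na(deg)]
  if (!length(deg)) return(NA_real_)
  a <- deg * 6 * pi / 180                 # map [0, 60) onto the circle
  (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi / 6) %% 60
}

#' Aggregate per-cell grid metrics into gradient trends
#'
#' For each gradient value, metrics are averaged (mean and SEM) over cells
#' classified as grid cells, for both the gridness > 0 and the stricter
#' gridness > 0.3 subsets, along with the percentage of grid cells.
#' Orientation uses the circular mean over \[0, 60).
#'
#' @param metrics a per-cell metrics tibble (as from [run_case()]); when
#'   several trials are present only the last is aggregated
#' @return a tibble with one row per (gradient value, gridness threshold)
#' @export
trend_table <- function(metrics) {
  if (!nrow(metrics)) return(tibble::tibble())
  metrics <- dplyr::filter(metrics, .data$trial == max(.data$trial))
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  }
  agg_one <- function(df, thr) {
    grid <- dplyr::filter(df, !is.na(.data$gridness), .data$gridness > thr)
    tibble::tibble(
      gridness_threshold = thr,
      n_cells = nrow(df), n_grid = nrow(grid),
      pct_grid = 100 * nrow(grid) / nrow(df),
      spacing_mean = mean(grid$spacing_cm, na.rm = TRUE),
      spacing_sem = sem(grid$spacing_cm),
      field_width_mean = mean(grid$field_width_cm, na.rm = TRUE),
      field_width_sem = sem(grid$field_width_cm),
      gridness_mean = mean(grid$gridness, na.rm = TRUE),
      gridness_sem = sem(grid$gridness),
      peak_rate_mean = mean(grid$peak_rate, na.rm = TRUE),
      peak_rate_sem = sem(grid$peak_rate),
      mean_rate_mean = mean(grid$mean_rate, na.rm = TRUE),
      mean_rate_sem = sem(grid$mean_rate),
      stability_mean = mean(grid$stability, na.rm = TRUE),
      stability_sem = sem(grid$stability),
      orientation_circ_mean = circular_mean_60(grid$orientation_deg))
  }
  out <- metrics |>
    dplyr::group_by(population = .data$population) |>
    dplyr::group_modify(function(df, key)
      dplyr::bind_rows(agg_one(df, 0), agg_one(df, 0.3))) |>
    dplyr::ungroup()
  out
}

#' Run several case specifications side by side
#'
#' All specs must share the same gradient ladder; their trend tables are
#' joined with a `case_id` column, ready for cross-case comparisons such as
#' the normalization-ablation reversal (equal-peak stripe inputs let the
#' large scale win even at fast response rates).
#'
#' @param specs a list of [case_spec()]s with identical ladders
#' @param params a [som_params()]
#' @return a tibble of joined trend tables
#' @export
compare_variants <- function(specs, params = som_params()) {
  stopifnot(length(specs) >= 1)
  ladders <- lapply(specs, `[[`, "ladder")
  if (!all(vapply(ladders, function(l) identical(l, ladders[[1]]), TRUE)))
    stop("all specs must share the same gradient ladder")
  dplyr::bind_rows(lapply(specs, function(sp) {
    res <- run_case(sp, params)
    dplyr::mutate(res$trends, case_id = sp$case_id, .before = 1)
  }))
}
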