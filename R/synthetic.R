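# Synthetic weight histories with the statistical structure the analysis
# assumes: a slow upward weight trend from decaying calorie expenditure, a
# noisy month-to-month drive whose integrated effect is a stationary
# weight fluctuation, and dietary periods during which the drive is
# reduced -- the reduction starting before and ending before the formal
# period boundaries (anticipation/relapse) -- followed by a compensating
# rebound that regains the lost weight (yoyo cycling).

#' Specify a synthetic weight-history scenario
#'
#' @param n_months Number of monthly observations.
#' @param baseline_drive Regular (non-cycle) drive level, cal/day.
#' @param drive_noise_sd Marginal SD of the month-to-month drive noise,
#'   cal/day. The noise is generated as the first difference of a
#'   stationary Gaussian weight-fluctuation process (so each month's
#'   noise is Gaussian with this SD, anti-correlated at lag 1, and the
#'   weight record fluctuates stationarily instead of random-walking).
#' @param diet_periods Diet schedule tibble (`start_month`, `end_month`,
#'   half-open).
#' @param diet_depth Drive reduction during dieting, cal/day.
#' @param anticipation_lead Months by which the drive reduction starts
#'   before the formal period start (>= 0).
#' @param relapse_lead Months by which the reduction ends before the
#'   formal period end (>= 0).
#' @param params [model_params()] providing `Q0`, `epsilon` (schedule),
#'   `delta`, `eta`, `gamma`, `rho` (and derived `alpha`, `beta`).
#' @param obs_noise_sd SD of the Gaussian observation noise on weight, lb.
#' @param rebound If `TRUE` (default) each reduction window is followed
#'   by a calorie-balanced rebound window of equal length during which
#'   the drive is raised, so the weight lost while dieting is regained
#'   (the yoyo pattern seen in long-term records). Without it every diet
#'   permanently removes `diet_depth * window` calories and a multi-year
#'   record with several diets drifts far below any realistic weight.
#' @param seed Integer seed; all randomness in the generated scenario
#'   flows from it (drive noise first, observation noise second, in one
#'   seeded stream).
#' @return An object of class `scenario_spec`.
#' @seealso [scenario_preset()] for ready-made subject-like scenarios.
#' @export
scenario_spec <- function(n_months, baseline_drive, drive_noise_sd,
                          diet_periods, diet_depth, anticipation_lead = 1,
                          relapse_lead = 1, params, obs_noise_sd = 1,
                          rebound = TRUE, seed = 1) {
  validate_schedule(diet_periods)
  if (n_months < 2) stop_domain("n_months must be at least 2")
  if (drive_noise_sd < 0 || obs_noise_sd < 0) {
    stop_domain("noise SDs must be non-negative")
  }
  if (diet_depth < 0) stop_domain("diet_depth must be non-negative")
  if (anticipation_lead < 0 || relapse_lead < 0) {
    stop_domain("leads must be non-negative")
  }
  check_positive(baseline_drive, "baseline_drive")
  if (!inherits(params, "model_params")) {
    stop_domain("params must be a model_params object")
  }
  for (nm in c("Q0", "epsilon", "delta", "eta", "rho")) {
    if (is.null(params[[nm]])) stop_domain("params$", nm, " must be set")
  }
  if (params$eta <= max(params$epsilon)) {
    stop_domain("params must satisfy eta > epsilon")
  }
  structure(list(n_months = as.integer(n_months),
                 baseline_drive = baseline_drive,
                 drive_noise_sd = drive_noise_sd,
                 diet_periods = diet_periods, diet_depth = diet_depth,
                 anticipation_lead = anticipation_lead,
                 relapse_lead = relapse_lead, params = params,
                 obs_noise_sd = obs_noise_sd,
                 rebound = isTRUE(rebound), seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$n_months, "months, baseline drive",
      round(x$baseline_drive), "cal/day,", nrow(x$diet_periods),
      "dietary periods (depth", x$diet_depth, "cal/day)\n")
  invisible(x)
}

# months during which the drive is actually reduced: each period shifted
# earlier at its start by the anticipation lead and truncated earlier at
# its end by the relapse lead
reduced_schedule <- function(spec) {
  s <- pmax(spec$diet_periods$start_month - spec$anticipation_lead, 0)
  e <- pmax(spec$diet_periods$end_month - spec$relapse_lead, s)
  keep <- e > s
  tibble::tibble(start_month = s[keep], end_month = e[keep])
}

# deterministic (noise-free) part of the drive profile on months 0..n-1
drive_deterministic <- function(spec) {
  months <- seq(0, spec$n_months - 1L)
  red <- reduced_schedule(spec)
  reduced <- months_in_schedule(months, red)
  D <- rep(spec$baseline_drive, length(months)) -
    spec$diet_depth * reduced
  rebound <- rep(FALSE, length(months))
  if (spec$rebound && nrow(red) > 0 && spec$diet_depth > 0) {
    for (i in seq_len(nrow(red))) {
      len <- red$end_month[i] - red$start_month[i]
      w_end <- min(red$end_month[i] + len, spec$n_months)
      win <- months >= red$end_month[i] & months < w_end
      if (any(win)) {
        # spread the calories withheld during the reduction evenly over
        # the rebound window (full regain when the window fits)
        D[win] <- D[win] + spec$diet_depth * len / sum(win)
        rebound[win] <- TRUE
      }
    }
  }
  tibble::tibble(month = months, drive_cal_day = D, reduced = reduced,
                 rebound = rebound)
}

drive_profile_impl <- function(spec, days_per_month = DAYS_PER_MONTH) {
  det <- drive_deterministic(spec)
  n <- spec$n_months
  p <- spec$params
  # drive noise as the first difference of a stationary Gaussian weight
  # fluctuation f (lb): e(tau) = rho*delta*(f(tau+1)-f(tau))/dt, scaled so
  # sd(e) = drive_noise_sd
  sigma_f <- spec$drive_noise_sd * days_per_month /
    (p$rho * p$delta * sqrt(2))
  f <- sigma_f * stats::rnorm(n + 1L)
  e <- p$rho * p$delta * diff(f) / days_per_month
  D <- det$drive_cal_day + e
  if (any(D < 0)) {
    warning("negative generated drive clipped at 0", call. = FALSE)
    D <- pmax(D, 0)
  }
  tibble::tibble(month = det$month, drive_cal_day = D,
                 reduced = det$reduced, rebound = det$rebound)
}

#' Generate a monthly drive profile
#'
#' The drive is the baseline plus stationary-difference Gaussian noise,
#' reduced by `diet_depth` during the dietary periods shifted earlier by
#' the anticipation lead and truncated earlier by the relapse lead, and
#' (by default) raised during a balanced rebound window after each
#' reduction.
#'
#' @param spec A [scenario_spec()].
#' @param days_per_month Days per month.
#' @return A tibble with columns `month`, `drive_cal_day`, `reduced` and
#'   `rebound` (logical indicators of the reduction and rebound windows).
#'   Reproducible for a given `spec$seed`.
#' @export
make_drive_profile <- function(spec, days_per_month = DAYS_PER_MONTH) {
  if (!inherits(spec, "scenario_spec")) {
    stop_domain("spec must be a scenario_spec")
  }
  withr::with_seed(spec$seed, drive_profile_impl(spec, days_per_month))
}

#' Generate a synthetic weight history
#'
#' Integrates the quasi-steady-state calorie equation driven by the
#' generated monthly drive (held piecewise constant within each month),
#' samples the weight at the monthly time stamps and adds Gaussian
#' observation noise. The initial calorie store is the closed-form
#' quasi-steady value for the baseline drive, so the record starts on the
#' slow manifold.
#'
#' @param spec A [scenario_spec()].
#' @param days_per_month Days per month.
#' @return A list of class `synthetic_series` with `weights` (tibble
#'   `month`, `weight_lb`), `weights_true` (noise-free weights), `drive`
#'   (the true generated drive), `params`, `schedule` and `spec`.
#' @export
make_weight_series <- function(spec, days_per_month = DAYS_PER_MONTH) {
  if (!inherits(spec, "scenario_spec")) {
    stop_domain("spec must be a scenario_spec")
  }
  p <- spec$params
  out <- withr::with_seed(spec$seed, {
    drive <- drive_profile_impl(spec, days_per_month)
    obs_noise <- stats::rnorm(spec$n_months, 0, spec$obs_noise_sd)
    list(drive = drive, obs_noise = obs_noise)
  })
  drive <- out$drive
  W_true <- integrate_drive_months(drive$drive_cal_day, spec,
                                   days_per_month)
  weights <- tibble::tibble(month = drive$month,
                            weight_lb = W_true + out$obs_noise)
  if (any(weights$weight_lb <= 0)) {
    stop_domain("scenario produced non-positive observed weights")
  }
  structure(list(weights = weights,
                 weights_true = tibble::tibble(month = drive$month,
                                               weight_lb = W_true),
                 drive = drive[, c("month", "drive_cal_day")],
                 params = p, schedule = spec$diet_periods, spec = spec),
            class = "synthetic_series")
}

# QSS integration of a monthly piecewise-constant drive; returns the
# noise-free weights at the month grid
integrate_drive_months <- function(D, spec, days_per_month) {
  p <- spec$params
  months <- seq(0, spec$n_months - 1L)
  knots <- months * days_per_month
  drive_fn <- stats::approxfun(knots, D, method = "constant", f = 0,
                               rule = 2)
  C0 <- spec$baseline_drive / p$eta - p$Q0 / (p$eta - p$epsilon[1])
  if (C0 <= 0) stop_domain("scenario implies a non-positive calorie store")
  traj <- integrate_qss(p, drive_fn, C0, t_grid = knots)
  traj$W_lb
}

#' @export
print.synthetic_series <- function(x, ...) {
  cat("<synthetic_series>", nrow(x$weights), "monthly observations,",
      nrow(x$schedule), "dietary periods\n")
  invisible(x)
}

# Baseline drive such that the *deterministic* generated record (diet
# cycles included) has the target mean weight over the given months:
# secant iteration on two noise-free integrations.
calibrate_baseline <- function(spec, target_mean_lb, months,
                               days_per_month = DAYS_PER_MONTH) {
  mean_at <- function(b) {
    s <- spec; s$baseline_drive <- b
    class(s) <- "scenario_spec"
    D <- drive_deterministic(s)$drive_cal_day
    mean(integrate_drive_months(D, s, days_per_month)[months + 1L])
  }
  b0 <- spec$baseline_drive
  m0 <- mean_at(b0)
  b1 <- b0 + 10
  m1 <- mean_at(b1)
  for (i in 1:3) {
    b2 <- b1 + (target_mean_lb - m1) * (b1 - b0) / (m1 - m0)
    b0 <- b1; m0 <- m1
    b1 <- b2; m1 <- mean_at(b2)
    if (abs(m1 - target_mean_lb) < 1e-8) break
  }
  b1
}

#' Ready-made subject-like synthetic scenarios
#'
#' Two presets emulate the structure of multi-year weight records of two
#' adult women: a slow upward trend from decaying calorie expenditure,
#' stationary month-to-month weight fluctuations, and recurring dietary
#' periods with anticipation (the drive falls before the formal period
#' start), relapse (it recovers before the formal end) and post-diet
#' regain.
#'
#' `"subject_A_like"`: 80 months, single expenditure decay rate, 8
#' dietary periods; drive noise SD 131 cal/day, dieting depth 267
#' cal/day; baseline drive calibrated so the noise-free mean weight is
#' 157.0 lb.
#'
#' `"subject_B_like"`: 80 months, two-rate expenditure schedule with the
#' transition at month 40, 5 dietary periods; drive noise SD 183 cal/day,
#' dieting depth 160 cal/day; baseline drive calibrated so the noise-free
#' mean weight of the pre-transition section is 127.4 lb.
#'
#' @param name `"subject_A_like"` or `"subject_B_like"`.
#' @param seed Integer seed stored in the returned spec.
#' @return A [scenario_spec()].
#' @export
#' @examples
#' spec <- scenario_preset("subject_A_like", seed = 7)
#' series <- make_weight_series(spec)
scenario_preset <- function(name = c("subject_A_like", "subject_B_like"),
                            seed = 1) {
  name <- match.arg(name)
  gamma <- 40.1; rho <- 3500; L_ref <- 20.3
  if (name == "subject_A_like") {
    delta <- 0.405; eta <- 2.78e-5; Q0 <- 2571
    epsilon <- 1e-7; t_transition <- numeric(0)
    W_ref <- 157.0; n_months <- 80L
    months_target <- 0:79
    schedule <- tibble::tibble(
      start_month = c(6, 15, 24, 33, 42, 52, 61, 70),
      end_month   = c(9, 18, 27, 36, 45, 55, 64, 73)
    )
    drive_noise_sd <- 131; diet_depth <- 267
  } else {
    delta <- 0.316; eta <- 1.17e-4; Q0 <- 2100
    epsilon <- c(2.06e-6, 8.30e-7)
    t_transition <- 40 * DAYS_PER_MONTH
    W_ref <- 127.4; n_months <- 80L
    months_target <- 0:39   # parameters anchor to the pre-transition section
    schedule <- tibble::tibble(
      start_month = c(8, 22, 35, 52, 66),
      end_month   = c(11, 25, 38, 55, 69)
    )
    drive_noise_sd <- 183; diet_depth <- 160
  }
  beta <- beta_from_reference(L_ref, gamma, rho, delta, W_ref)
  alpha <- alpha_from_eta(eta, gamma, beta)
  params <- model_params(alpha = alpha, beta = beta, gamma = gamma,
                         delta = delta, eta = eta, Q0 = Q0,
                         epsilon = epsilon, t_transition = t_transition,
                         rho = rho, L_ref = L_ref, W_ref = W_ref)
  # analytic starting point: baseline matching the target mean without
  # diet cycles, refined by the deterministic calibration below
  t0 <- months_target * DAYS_PER_MONTH
  Q <- expenditure(t0, Q0, epsilon, t_transition)
  sec <- findInterval(t0, t_transition) + 1L
  b_init <- eta * (W_ref * rho * delta + mean(Q / (eta - epsilon[sec])))
  spec <- scenario_spec(n_months = n_months, baseline_drive = b_init,
                        drive_noise_sd = drive_noise_sd,
                        diet_periods = schedule, diet_depth = diet_depth,
                        anticipation_lead = 1, relapse_lead = 1,
                        params = params, obs_noise_sd = 1, seed = seed)
  spec$baseline_drive <- calibrate_baseline(spec, W_ref, months_target)
  spec
}
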