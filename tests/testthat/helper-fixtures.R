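# Shared fixtures: printed parameter sets for the two reference subjects,
# the printed per-period deficit means, and small scenario builders.

subject_A_printed <- list(
  Q0 = 2571, beta = 3.68e-3, delta = 0.405, eta = 2.78e-5, alpha = 0.303,
  D = 2586, eps1 = 1.00e-7, W_mean = 157.0
)

subject_B_printed <- list(
  Q0 = 2100, beta = 5.78e-3, delta = 0.316, eta = 1.17e-4, alpha = 0.816,
  D = 2152, eps1 = 2.06e-6, eps2 = 8.30e-7, W_mean_section1 = 127.4
)

period_means_A <- c(263, 346, 323, 120, 181, 342, 369, 193)
period_means_B <- c(77, 66, 228, 151, 274)

subject_A_params <- function() {
  s <- subject_A_printed
  model_params(D = s$D, Q0 = s$Q0, delta = s$delta, eta = s$eta,
               epsilon = s$eps1, gamma = 40.1, W_ref = s$W_mean)
}

# fully specified (alpha/beta consistent with eta) subject-A-like set
subject_A_full_params <- function() {
  s <- subject_A_printed
  beta <- beta_from_reference(20.3, 40.1, 3500, s$delta, s$W_mean)
  alpha <- alpha_from_eta(s$eta, 40.1, beta)
  model_params(D = s$D, alpha = alpha, beta = beta, gamma = 40.1,
               delta = s$delta, eta = s$eta, Q0 = s$Q0,
               epsilon = s$eps1, W_ref = s$W_mean)
}

subject_B_params <- function(transition_month = 40) {
  s <- subject_B_printed
  model_params(D = s$D, Q0 = s$Q0, delta = s$delta, eta = s$eta,
               epsilon = c(s$eps1, s$eps2),
               t_transition = transition_month * DAYS_PER_MONTH,
               gamma = 40.1, W_ref = s$W_mean_section1)
}

# small well-separated-diet scenario without rebound, used for the
# anticipation cross-correlation property (positive in-period deficit
# loading guaranteed)
anticipation_scenario <- function(seed, lead) {
  beta <- beta_from_reference(20.3, 40.1, 3500, 0.405, 150)
  p <- model_params(alpha = alpha_from_eta(2.78e-5, 40.1, beta),
                    beta = beta, gamma = 40.1, delta = 0.405,
                    eta = 2.78e-5, Q0 = 2204, epsilon = 0, W_ref = 150)
  scenario_spec(
    n_months = 60, baseline_drive = 2210, drive_noise_sd = 131,
    diet_periods = tibble::tibble(start_month = c(10, 25, 40),
                                  end_month = c(13, 28, 43)),
    diet_depth = 250, anticipation_lead = lead, relapse_lead = lead,
    params = p, obs_noise_sd = 1, rebound = FALSE, seed = seed
  )
}

# centred 3-month moving average, NA at the ends
smooth3 <- function(x) as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))

# location of the smoothed cross-correlation peak for a generated record
xcorr_peak <- function(spec, shifts = -8:8) {
  ser <- make_weight_series(spec)
  rec <- reconstruct_drive(ser$weights, ser$params)
  E <- drive_deficit(rec, ser$schedule)
  xc <- cross_correlation(E, ser$schedule, shifts = shifts)
  sm <- smooth3(xc$xcorr)
  ok <- !is.na(sm)
  xc$shift[ok][which.max(sm[ok])]
}

# independent period-membership helper for oracles
months_in_schedule_toy <- function(months, schedule) {
  vapply(months, function(m) {
    any(m >= schedule$start_month & m < schedule$end_month)
  }, logical(1))
}

# brute-force double-loop cross-correlation oracle (kept deliberately
# independent of the vectorised implementation)
xcorr_bruteforce <- function(months, E, schedule, shifts) {
  in_period <- function(m) {
    any(m >= schedule$start_month & m < schedule$end_month)
  }
  val <- function(s) {
    total <- 0
    for (i in seq_along(months)) {
      lag <- months[i] - s
      if (lag >= min(months) && lag <= max(months) && in_period(lag)) {
        total <- total + E[i]
      }
    }
    total
  }
  num <- vapply(shifts, val, numeric(1))
  num / val(0)
}

# noise-free weight series from a closed-form parameter set
closed_form_series <- function(params, months = 0:79) {
  tibble::tibble(month = months,
                 weight_lb = weight_closed_form(months * DAYS_PER_MONTH,
                                                params))
}
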