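# Month-by-month reconstruction of the latent eating drive from an
# observed weight history and a (fitted) parameter set.
#
# Discretising the reduced calorie equation dC/dt = D - eta*C - Q with a
# forward difference on the monthly grid, and writing eta*C as alpha*L via
# the quasi-steady state, gives per month tau
#
#   D(tau) = rho*delta*(W(tau+1) - W(tau)) / dt  +  alpha*L(tau)  +  Q(tau)
#
# with dt the month length in days and L(tau) = beta*rho*delta*W(tau)/gamma.

#' Reconstruct the drive from a weight record
#'
#' Inverts the reduced calorie-balance equation month by month: the
#' observed weight change fixes the net calorie balance, the
#' quasi-steady-state leptin level (from the observed weight) fixes the
#' leptin damping term, and the expenditure schedule fixes `Q`; their sum
#' is the drive. The forward difference `W(tau+1) - W(tau)` is assigned to
#' month `tau`, and leptin is evaluated at the left endpoint.
#'
#' @param data Weight series: data frame with columns `month` and
#'   `weight_lb`, at least 2 rows, months strictly increasing.
#' @param params A [model_params()] with `alpha`, `beta`, `gamma`,
#'   `delta`, `Q0`, `epsilon` (e.g. from [fit_weight_model()]).
#' @param days_per_month Days per month (default 365.25/12).
#' @return A tibble with one row per consecutive observation pair:
#'   `month` (left endpoint), `drive_cal_day`, `leptin_ng_ml`.
#' @export
#' @examples
#' p <- model_params(D = 2586, alpha = 0.303, beta = 3.68e-3, gamma = 40.1,
#'                   delta = 0.405, eta = 2.78e-5, Q0 = 2571,
#'                   epsilon = 1e-7, W_ref = 157)
#' w <- tibble::tibble(month = 0:3, weight_lb = c(157, 158, 157.5, 158))
#' reconstruct_drive(w, p)
reconstruct_drive <- function(data, params, days_per_month = DAYS_PER_MONTH) {
  validate_weight_series(data, min_points = 2L)
  if (days_per_month <= 0) stop_domain("days_per_month must be positive")
  p <- params
  for (nm in c("alpha", "beta", "gamma", "delta", "Q0", "rho")) {
    if (is.null(p[[nm]])) {
      stop_domain("params$", nm, " must be set to reconstruct the drive")
    }
  }
  if (is.null(p$epsilon)) stop_domain("params$epsilon must be set")
  n <- nrow(data)
  m <- data$month
  W <- data$weight_lb
  dW <- diff(W)
  dtau <- diff(m)
  left <- seq_len(n - 1L)
  L <- qss_leptin(weight_to_calories(W[left], p$rho, p$delta),
                  p$beta, p$gamma)
  Q <- expenditure(m[left] * days_per_month, p$Q0, p$epsilon, p$t_transition)
  D <- p$rho * p$delta * dW / (dtau * days_per_month) + p$alpha * L + Q
  tibble::tibble(month = m[left], drive_cal_day = D, leptin_ng_ml = L)
}

#' Mean and spread of the drive outside dietary periods
#'
#' @param drive A drive series: data frame with columns `month` and
#'   `drive_cal_day` (from [reconstruct_drive()] or
#'   [make_drive_profile()]).
#' @param schedule A diet schedule: data frame with columns `start_month`,
#'   `end_month` (half-open intervals `[start, end)`).
#' @return A one-row tibble with `mean_drive`, `sd_drive` (population,
#'   n-divisor) and `n_outside`, computed over the months outside all
#'   dietary periods.
#' @export
drive_summary <- function(drive, schedule) {
  validate_drive_series(drive)
  validate_schedule(schedule)
  outside <- !months_in_schedule(drive$month, schedule)
  if (!any(outside)) {
    stop_domain("no months outside the dietary periods: cannot form the ",
                "baseline drive")
  }
  d <- drive$drive_cal_day[outside]
  tibble::tibble(mean_drive = mean(d),
                 sd_drive = sqrt(mean((d - mean(d))^2)),
                 n_outside = length(d))
}

validate_drive_series <- function(drive) {
  if (!is.data.frame(drive) ||
      !all(c("month", "drive_cal_day") %in% names(drive))) {
    stop_domain("drive series needs columns 'month' and 'drive_cal_day'")
  }
  if (nrow(drive) == 0) stop_domain("drive series is empty")
  if (any(diff(drive$month) <= 0)) {
    stop_domain("drive series months must be strictly increasing")
  }
  if (any(!is.finite(drive$drive_cal_day))) {
    stop_domain("drive values must be finite")
  }
  invisible(drive)
}

months_in_schedule <- function(months, schedule) {
  if (nrow(schedule) == 0) return(rep(FALSE, length(months)))
  purrr::reduce(
    purrr::map2(schedule$start_month, schedule$end_month,
                function(s, e) months >= s & months < e),
    `|`
  )
}

#' Plot a drive series with its dietary periods
#'
#' @param drive Drive series tibble (`month`, `drive_cal_day`).
#' @param schedule Diet schedule tibble (`start_month`, `end_month`),
#'   drawn as shaded bands.
#' @return A ggplot object.
#' @export
plot_drive <- function(drive, schedule = NULL) {
  gg <- ggplot2::ggplot(drive,
                        ggplot2::aes(x = .data$month,
                                     y = .data$drive_cal_day))
  if (!is.null(schedule) && nrow(schedule) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = schedule, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_month, xmax = .data$end_month,
                   ymin = -Inf, ymax = Inf),
      fill = "grey80", alpha = 0.6
    )
  }
  gg + ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "month", y = "drive [cal/day]") +
    ggplot2::theme_minimal()
}
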