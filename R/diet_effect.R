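# Quantifying the effect of dieting (and leptin) on the eating drive:
# drive deficit relative to the non-dieting baseline, per-period means,
# a one-sample t-test, percentage effects, and the cross-correlation of
# the deficit with the dietary block function.

validate_schedule <- function(schedule) {
  if (!is.data.frame(schedule) ||
      !all(c("start_month", "end_month") %in% names(schedule))) {
    stop_domain("schedule needs columns 'start_month' and 'end_month'")
  }
  if (nrow(schedule) == 0) return(invisible(schedule))
  s <- schedule$start_month; e <- schedule$end_month
  if (anyNA(s) || anyNA(e) || !is.numeric(s) || !is.numeric(e)) {
    stop_domain("schedule months must be numeric without missing values")
  }
  if (any(e <= s)) stop_domain("each period must have start_month < end_month")
  o <- order(s)
  if (any(s[o][-1] < e[o][-length(e)])) {
    stop_domain("dietary periods must not overlap")
  }
  invisible(schedule)
}

#' Drive deficit relative to the non-dieting baseline
#'
#' The deficit is `E(tau) = Dbar - D(tau)` for every month, where `Dbar`
#' is the mean drive over the months outside all dietary periods (see
#' [drive_summary()]). Positive values mean the drive is suppressed below
#' its regular level.
#'
#' @inheritParams drive_summary
#' @return A tibble with columns `month`, `deficit_cal_day` and `in_diet`
#'   (logical indicator of the dietary periods).
#' @export
drive_deficit <- function(drive, schedule) {
  base <- drive_summary(drive, schedule)
  tibble::tibble(
    month = drive$month,
    deficit_cal_day = base$mean_drive - drive$drive_cal_day,
    in_diet = months_in_schedule(drive$month, schedule)
  )
}

#' Per-period deficit means and their summary
#'
#' Averages the drive deficit over each dietary period, then summarises
#' the period means by their mean and population (n-divisor) standard
#' deviation. Periods containing no months of the deficit series are
#' excluded with a warning.
#'
#' @param deficit A deficit series from [drive_deficit()] (columns
#'   `month`, `deficit_cal_day`).
#' @param schedule Diet schedule (`start_month`, `end_month`).
#' @return A list with `periods` (tibble: `period`, `start_month`,
#'   `end_month`, `n_months`, `mean_deficit`), `overall_mean`,
#'   `overall_sd` (population SD of the period means) and `n_periods`.
#' @export
period_statistics <- function(deficit, schedule) {
  validate_schedule(schedule)
  if (nrow(schedule) == 0) stop_domain("schedule has no dietary periods")
  if (!is.data.frame(deficit) ||
      !all(c("month", "deficit_cal_day") %in% names(deficit))) {
    stop_domain("deficit series needs columns 'month' and 'deficit_cal_day'")
  }
  per <- purrr::map_dfr(seq_len(nrow(schedule)), function(i) {
    s <- schedule$start_month[i]; e <- schedule$end_month[i]
    inside <- deficit$month >= s & deficit$month < e
    tibble::tibble(period = i, start_month = s, end_month = e,
                   n_months = sum(inside),
                   mean_deficit = if (any(inside)) {
                     mean(deficit$deficit_cal_day[inside])
                   } else NA_real_)
  })
  if (anyNA(per$mean_deficit)) {
    warning("excluding ", sum(is.na(per$mean_deficit)),
            " dietary period(s) with no drive data", call. = FALSE)
    per <- per[!is.na(per$mean_deficit), , drop = FALSE]
  }
  if (nrow(per) == 0) stop_domain("no dietary period overlaps the series")
  m <- per$mean_deficit
  list(periods = per,
       overall_mean = mean(m),
       overall_sd = sqrt(mean((m - mean(m))^2)),
       n_periods = nrow(per))
}

#' One-sample t-test for a positive dieting effect
#'
#' Tests whether the per-period mean deficits are positive on average:
#' a one-sample t-test against zero with the one-sided alternative
#' `mean > 0` and the usual sample (n-1) variance.
#'
#' @param period_means Numeric vector of per-period mean deficits
#'   (cal/day), length at least 2.
#' @return A one-row tibble: `estimate` (mean), `t_stat`, `df`, `p_value`.
#' @export
#' @examples
#' diet_ttest(c(77, 66, 228, 151, 274)) # p = 0.009
diet_ttest <- function(period_means) {
  if (length(period_means) < 2) {
    stop_domain("need at least 2 period means for a t-test")
  }
  ht <- stats::t.test(period_means, mu = 0, alternative = "greater")
  tibble::tibble(estimate = unname(ht$estimate),
                 t_stat = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Dieting and leptin effects as percentages of the baseline drive
#'
#' Expresses the mean dieting deficit and the leptin damping term
#' `alpha * L_ref` as percentages of the mean drive outside the dietary
#' periods. Unrounded values are returned together with printed-style
#' roundings (integer for the dieting effect; one decimal below 1%,
#' integer above, for the leptin effect).
#'
#' @param overall_mean_E Mean per-period deficit, cal/day.
#' @param mean_drive_outside Mean drive outside dietary periods, cal/day
#'   (must be positive).
#' @param alpha Leptin damping coefficient, cal/day per ng/ml.
#' @param L_ref Reference plasma leptin, ng/ml.
#' @return A one-row tibble: `pct_dieting`, `pct_leptin` (unrounded) and
#'   `pct_dieting_printed`, `pct_leptin_printed`.
#' @export
#' @examples
#' effect_percentages(267, 2210, 0.303, 20.3) # 12% and 0.3%
effect_percentages <- function(overall_mean_E, mean_drive_outside, alpha,
                               L_ref) {
  check_positive(mean_drive_outside, "mean_drive_outside")
  check_positive(alpha, "alpha"); check_positive(L_ref, "L_ref")
  pd <- 100 * overall_mean_E / mean_drive_outside
  pl <- 100 * alpha * L_ref / mean_drive_outside
  tibble::tibble(
    pct_dieting = pd,
    pct_leptin = pl,
    pct_dieting_printed = round(pd),
    # integer rounding, falling back to one decimal when it vanishes
    pct_leptin_printed = if (round(pl) == 0) round(pl, 1) else round(pl)
  )
}

#' Dietary block indicator on a month grid
#'
#' `B(tau) = 1` during dietary periods (half-open `[start, end)`) and 0
#' outside.
#'
#' @param schedule Diet schedule (`start_month`, `end_month`).
#' @param months_grid Sorted numeric vector of months.
#' @return A tibble with columns `month` and `block` (0/1 integer).
#' @export
block_function <- function(schedule, months_grid) {
  validate_schedule(schedule)
  if (is.unsorted(months_grid)) stop_domain("months_grid must be sorted")
  tibble::tibble(month = months_grid,
                 block = as.integer(months_in_schedule(months_grid,
                                                       schedule)))
}

#' Cross-correlation of the drive deficit with the dietary block
#'
#' Measures how the deficit aligns with the dietary periods when the
#' block function is shifted in time (backwards for negative shifts):
#' `X(s) = sum_tau E(tau) * B(tau - s) / sum_tau E(tau) * B(tau)`.
#' The normalisation makes `X(0) = 1` exactly. The shifted block is
#' truncated at the record boundaries (months for which `tau - s` falls
#' outside the record do not contribute); there is no wrap-around.
#'
#' A deficit that anticipates the dietary periods (suppression starting
#' before the formal start and relapsing before the formal end) shows up
#' as `X(s)` skewed toward negative shifts.
#'
#' @param deficit Deficit series from [drive_deficit()] on an equally
#'   spaced month grid.
#' @param schedule Diet schedule (`start_month`, `end_month`).
#' @param shifts Integer shifts (months) at which to evaluate `X`; must
#'   include 0.
#' @return A tibble with columns `shift` and `xcorr`.
#' @export
cross_correlation <- function(deficit, schedule, shifts = -12:12) {
  validate_schedule(schedule)
  if (!0 %in% shifts) stop_domain("shifts must include 0")
  tau <- deficit$month
  E <- deficit$deficit_cal_day
  lo <- min(tau); hi <- max(tau)
  num <- vapply(shifts, function(s) {
    lagged <- tau - s
    ok <- lagged >= lo & lagged <= hi
    if (!any(ok)) return(0)
    sum(E[ok] * months_in_schedule(lagged[ok], schedule))
  }, numeric(1))
  den <- num[shifts == 0][1]
  if (den == 0) {
    stop_domain("zero cross-correlation at shift 0: the deficit does not ",
                "load on the dietary periods, X(s) is undefined")
  }
  tibble::tibble(shift = as.numeric(shifts), xcorr = num / den)
}

#' Full dieting-effect report for a drive series
#'
#' Runs the whole dieting analysis: baseline drive outside the dietary
#' periods, deficit series, per-period means with their summary, the
#' one-sided t-test, percentage effects of dieting and leptin, and the
#' cross-correlation of the deficit with the block function.
#'
#' @inheritParams drive_summary
#' @param params Optional [model_params()] supplying `alpha` (and
#'   `L_ref`) for the leptin percentage; if `NULL` the percentage row is
#'   omitted.
#' @param shifts Integer shifts for [cross_correlation()].
#' @return An object of class `diet_effect_report`: a list with
#'   `baseline`, `deficit`, `period_stats`, `t_test`, `percentages`
#'   (or `NULL`), `xcorr`, `schedule`. Supports `tidy()`, `glance()` and
#'   `autoplot()`.
#' @export
diet_effect_report <- function(drive, schedule, params = NULL,
                               shifts = -12:12) {
  base <- drive_summary(drive, schedule)
  E <- drive_deficit(drive, schedule)
  ps <- period_statistics(E, schedule)
  tt <- diet_ttest(ps$periods$mean_deficit)
  pct <- if (!is.null(params) && !is.null(params$alpha) &&
             !is.null(params$L_ref)) {
    effect_percentages(ps$overall_mean, base$mean_drive, params$alpha,
                       params$L_ref)
  }
  xc <- cross_correlation(E, schedule, shifts)
  structure(list(baseline = base, deficit = E, period_stats = ps,
                 t_test = tt, percentages = pct, xcorr = xc,
                 schedule = schedule),
            class = "diet_effect_report")
}

#' @export
print.diet_effect_report <- function(x, ...) {
  cat("<diet_effect_report>\n")
  cat(sprintf("  baseline drive outside diets: %.0f (sd %.0f) cal/day over %d months\n",
              x$baseline$mean_drive, x$baseline$sd_drive,
              x$baseline$n_outside))
  cat(sprintf("  %d dietary periods, mean deficit %.0f (sd %.0f) cal/day\n",
              x$period_stats$n_periods, x$period_stats$overall_mean,
              x$period_stats$overall_sd))
  cat(sprintf("  one-sided t-test (deficit > 0): t = %.2f, p = %.4g\n",
              x$t_test$t_stat, x$t_test$p_value))
  if (!is.null(x$percentages)) {
    cat(sprintf("  effect on the drive: dieting %.1f%%, leptin %.2f%%\n",
                x$percentages$pct_dieting, x$percentages$pct_leptin))
  }
  invisible(x)
}

#' @rdname diet_effect_report
#' @param x A `diet_effect_report`.
#' @param ... Unused.
#' @export
tidy.diet_effect_report <- function(x, ...) x$period_stats$periods

#' @rdname diet_effect_report
#' @export
glance.diet_effect_report <- function(x, ...) {
  out <- tibble::tibble(
    mean_drive_outside = x$baseline$mean_drive,
    sd_drive_outside = x$baseline$sd_drive,
    n_periods = x$period_stats$n_periods,
    mean_deficit = x$period_stats$overall_mean,
    sd_deficit = x$period_stats$overall_sd,
    t_stat = x$t_test$t_stat,
    p_value = x$t_test$p_value
  )
  if (!is.null(x$percentages)) {
    out$pct_dieting <- x$percentages$pct_dieting
    out$pct_leptin <- x$percentages$pct_leptin
  }
  out
}

#' @rdname diet_effect_report
#' @param object A `diet_effect_report`.
#' @export
autoplot.diet_effect_report <- function(object, ...) {
  ggplot2::ggplot(object$xcorr,
                  ggplot2::aes(x = .data$shift, y = .data$xcorr)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70",
                        linetype = "dashed") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue", size = 1) +
    ggplot2::labs(x = "shift s [month]", y = "X(s)",
                  title = "Cross-correlation of drive deficit with dietary periods") +
    ggplot2::theme_minimal()
}
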