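# Parameter container and literature-anchored parameter derivations for the
# leptin-regulated energy-balance model
#
#   dC/dt = I - Q,   I = D - alpha * L,   dL/dt = beta * C - gamma * L
#
# with C stored calories [cal], L plasma leptin [ng/ml], D the eating drive
# [cal/day], Q = Q0 * exp(-eps * t) calorie expenditure [cal/day].

#' Mean length of a month in days (365.25 / 12)
#'
#' Used to convert the monthly time stamps of weight records to the model's
#' internal time unit of days. All rate parameters are per day.
#' @export
DAYS_PER_MONTH <- 365.25 / 12

stop_domain <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.null(x) && (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))) {
    stop_domain(name, " must be strictly positive and finite")
  }
  invisible(x)
}

#' Energy-balance model parameters
#'
#' Bundles all rate constants and scale parameters of the model for one
#' subject. Any subset may be supplied; consistency is checked for the
#' fields that are present.
#'
#' @param D Eating drive, cal/day.
#' @param alpha Leptin damping of intake, cal/day per (ng/ml).
#' @param beta Leptin production coefficient, (ng/ml)/cal/day.
#' @param gamma Leptin clearance rate, 1/day (40.1 for a 24.9-minute
#'   half-life; see [gamma_from_halflife()]).
#' @param delta Body-fat fraction of total weight, in (0, 1).
#' @param eta Composite relaxation rate `alpha * beta / gamma`, 1/day.
#' @param Q0 Calorie expenditure at the start of the record, cal/day.
#' @param epsilon Expenditure decay rate(s), 1/day. A vector of length
#'   `k` gives a piecewise schedule with `k - 1` transition times.
#' @param t_transition Transition times of the expenditure schedule, in
#'   days from the record start; length `length(epsilon) - 1`, strictly
#'   increasing.
#' @param rho Caloric density of body fat, cal/lb (default 3500).
#' @param L_ref Reference mean plasma leptin, ng/ml (default 20.3, the
#'   population mean for women used to calibrate `beta`).
#' @param W_ref Reference mean weight for the `beta` calibration, lb.
#'
#' @return An object of class `model_params` (a named list).
#' @details Invariants enforced: all rates and scales strictly positive;
#'   `delta` in (0, 1); `eta > max(epsilon)` (required for the validity of
#'   the closed-form trajectory with zero integration constant); when
#'   `alpha`, `beta`, `gamma` and `eta` are all set,
#'   `eta == alpha * beta / gamma` to relative tolerance 1e-9.
#' @seealso [beta_from_reference()], [alpha_from_eta()],
#'   [weight_closed_form()]
#' @export
#' @examples
#' model_params(D = 2586, Q0 = 2571, delta = 0.405, eta = 2.78e-5,
#'              epsilon = 1e-7, gamma = 40.1, W_ref = 157)
model_params <- function(D = NULL, alpha = NULL, beta = NULL, gamma = NULL,
                         delta = NULL, eta = NULL, Q0 = NULL,
                         epsilon = NULL, t_transition = numeric(0),
                         rho = 3500, L_ref = 20.3, W_ref = NULL) {
  p <- list(D = D, alpha = alpha, beta = beta, gamma = gamma, delta = delta,
            eta = eta, Q0 = Q0, epsilon = epsilon,
            t_transition = as.numeric(t_transition),
            rho = rho, L_ref = L_ref, W_ref = W_ref)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  for (nm in c("D", "alpha", "beta", "gamma", "eta", "Q0", "rho", "L_ref",
               "W_ref")) {
    check_positive(p[[nm]], nm)
  }
  if (!is.null(p$delta) &&
      (!is.numeric(p$delta) || p$delta <= 0 || p$delta >= 1)) {
    stop_domain("delta must lie strictly inside (0, 1)")
  }
  if (!is.null(p$epsilon)) {
    if (any(!is.finite(p$epsilon)) || any(p$epsilon < 0)) {
      stop_domain("epsilon rates must be finite and non-negative")
    }
    if (length(p$t_transition) != length(p$epsilon) - 1L) {
      stop_domain("need exactly one transition time between consecutive ",
                  "epsilon rates")
    }
    if (length(p$t_transition) &&
        (any(diff(p$t_transition) <= 0) || any(p$t_transition <= 0))) {
      stop_domain("t_transition must be positive and strictly increasing")
    }
    if (!is.null(p$eta) && p$eta <= max(p$epsilon)) {
      stop_domain("eta must exceed every expenditure decay rate epsilon ",
                  "(closed-form validity)")
    }
  }
  if (!is.null(p$alpha) && !is.null(p$beta) && !is.null(p$gamma) &&
      !is.null(p$eta)) {
    eta_implied <- p$alpha * p$beta / p$gamma
    if (abs(eta_implied - p$eta) > 1e-9 * p$eta) {
      stop_domain("inconsistent parameters: eta must equal ",
                  "alpha * beta / gamma (relative tolerance 1e-9)")
    }
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  fmt <- function(v) if (is.null(v)) "." else paste(signif(v, 4), collapse = ", ")
  cat(sprintf("  drive D        : %s cal/day\n", fmt(x$D)))
  cat(sprintf("  expenditure Q0 : %s cal/day, decay eps = %s /day\n",
              fmt(x$Q0), fmt(x$epsilon)))
  if (length(x$t_transition)) {
    cat(sprintf("  eps transition : %s day\n", fmt(x$t_transition)))
  }
  cat(sprintf("  delta (fat fr.): %s   eta : %s /day\n",
              fmt(x$delta), fmt(x$eta)))
  cat(sprintf("  leptin: alpha = %s, beta = %s, gamma = %s /day\n",
              fmt(x$alpha), fmt(x$beta), fmt(x$gamma)))
  cat(sprintf("  scales: rho = %s cal/lb, L_ref = %s ng/ml, W_ref = %s lb\n",
              fmt(x$rho), fmt(x$L_ref), fmt(x$W_ref)))
  invisible(x)
}

#' Leptin clearance rate from a plasma half-life
#'
#' Renal clearance of leptin is fast (half-life on the order of tens of
#' minutes); the corresponding first-order rate in the model's unit of
#' 1/day is `ln(2) / halflife` with the half-life converted to days.
#'
#' @param halflife_min Plasma half-life in minutes (must be positive).
#' @return Clearance rate gamma, 1/day.
#' @export
#' @examples
#' gamma_from_halflife(24.9) # 40.1 per day
gamma_from_halflife <- function(halflife_min) {
  check_positive(halflife_min, "halflife_min")
  log(2) / (halflife_min / 1440)
}

#' Leptin production coefficient from a reference calibration
#'
#' In the quasi-steady state the plasma leptin level is `L = beta * C /
#' gamma` with `C = rho * delta * W` the calories stored in body fat.
#' Solving for `beta` at a reference leptin level and reference weight
#' gives `beta = gamma * L_ref / (rho * delta * W_ref)`.
#'
#' @param L_ref Reference mean plasma leptin, ng/ml.
#' @param gamma Leptin clearance rate, 1/day.
#' @param rho Caloric density of body fat, cal/lb.
#' @param delta Body-fat fraction, in (0, 1).
#' @param W_ref Reference mean weight, lb.
#' @return beta, (ng/ml)/cal/day.
#' @export
#' @examples
#' beta_from_reference(20.3, 40.1, 3500, 0.316, 127.4) # 5.78e-3
beta_from_reference <- function(L_ref, gamma, rho, delta, W_ref) {
  check_positive(L_ref, "L_ref"); check_positive(gamma, "gamma")
  check_positive(rho, "rho"); check_positive(W_ref, "W_ref")
  if (!is.numeric(delta) || delta <= 0 || delta >= 1) {
    stop_domain("delta must lie strictly inside (0, 1)")
  }
  gamma * L_ref / (rho * delta * W_ref)
}

#' Intake-damping coefficient from the composite decay rate
#'
#' The quasi-steady-state reduction collapses the leptin feedback into the
#' single composite rate `eta = alpha * beta / gamma`; given `eta`, `gamma`
#' and `beta` this inverts to `alpha = eta * gamma / beta`.
#'
#' @param eta Composite decay rate, 1/day.
#' @param gamma Leptin clearance rate, 1/day.
#' @param beta Leptin production coefficient, (ng/ml)/cal/day.
#' @return alpha, cal/day per (ng/ml).
#' @export
#' @examples
#' alpha_from_eta(2.78e-5, 40.1, 3.68e-3) # 0.303
alpha_from_eta <- function(eta, gamma, beta) {
  check_positive(eta, "eta"); check_positive(gamma, "gamma")
  check_positive(beta, "beta")
  eta * gamma / beta
}

#' Quasi-steady-state leptin level
#'
#' The leptin equation relaxes on a time scale of minutes, far faster than
#' the calorie store changes, so plasma leptin tracks `L = beta * C / gamma`.
#'
#' @param C Stored calories, cal (non-negative).
#' @param beta Leptin production coefficient.
#' @param gamma Leptin clearance rate, 1/day.
#' @return Leptin concentration, ng/ml.
#' @export
qss_leptin <- function(C, beta, gamma) {
  if (any(C < 0)) stop_domain("stored calories C must be non-negative")
  check_positive(beta, "beta"); check_positive(gamma, "gamma")
  beta * C / gamma
}

#' Convert stored fat calories to body weight and back
#'
#' Stored calories and weight are proportional: `C = rho * delta * W`,
#' with `rho` the caloric density of body fat (3500 cal/lb) and `delta`
#' the body-fat fraction.
#'
#' @param C Stored calories, cal.
#' @param W Body weight, lb.
#' @param rho Caloric density of body fat, cal/lb.
#' @param delta Body-fat fraction, in (0, 1).
#' @return Weight in lb (`calories_to_weight`) or calories
#'   (`weight_to_calories`).
#' @export
calories_to_weight <- function(C, rho, delta) {
  check_positive(rho, "rho"); check_positive(delta, "delta")
  C / (rho * delta)
}

#' @rdname calories_to_weight
#' @export
weight_to_calories <- function(W, rho, delta) {
  check_positive(rho, "rho"); check_positive(delta, "delta")
  W * rho * delta
}

#' Piecewise-exponential calorie expenditure
#'
#' Expenditure decays at a constant relative rate, `Q(t) = Q0 *
#' exp(-eps1 * t)`, optionally switching to further rates at given
#' transition times with Q continuous at each transition.
#'
#' @param t_day Time(s) in days from the record start (non-negative).
#' @param Q0 Expenditure at `t = 0`, cal/day.
#' @param epsilon Decay rate(s), 1/day; one rate per section.
#' @param t_transition Strictly increasing transition times (days);
#'   length `length(epsilon) - 1`.
#' @return Expenditure Q at `t_day`, cal/day (vectorised over `t_day`).
#' @export
#' @examples
#' expenditure(0, 2571, 1e-7)           # 2571
#' expenditure(c(0, 100), 2000, 0)      # constant
expenditure <- function(t_day, Q0, epsilon, t_transition = numeric(0)) {
  check_positive(Q0, "Q0")
  if (any(!is.finite(epsilon)) || any(epsilon < 0)) {
    stop_domain("epsilon rates must be finite and non-negative")
  }
  if (length(t_transition) != length(epsilon) - 1L) {
    stop_domain("need exactly one transition time between consecutive ",
                "epsilon rates")
  }
  if (length(t_transition) && any(diff(t_transition) <= 0)) {
    stop_domain("t_transition must be strictly increasing")
  }
  if (any(t_day < 0)) stop_domain("t_day must be non-negative")
  starts <- c(0, t_transition)
  # expenditure at the start of each section, imposing continuity of Q
  Q_start <- numeric(length(starts))
  Q_start[1] <- Q0
  if (length(starts) > 1) {
    for (i in seq_len(length(starts) - 1L)) {
      Q_start[i + 1] <- Q_start[i] *
        exp(-epsilon[i] * (starts[i + 1] - starts[i]))
    }
  }
  sec <- findInterval(t_day, t_transition) + 1L
  Q_start[sec] * exp(-epsilon[sec] * (t_day - starts[sec]))
}

#' Closed-form weight trajectory
#'
#' Under the quasi-steady-state reduction with constant drive the calorie
#' store obeys `dC/dt = D - eta*C - Q(t)`; with `Q(t) = Q0*exp(-eps*t)`
#' and the integration constant set to zero (valid when `eta >> eps`) the
#' solution is `C(t) = D/eta - Q(t)/(eta - eps)`, evaluated section by
#' section for a piecewise expenditure schedule (Q continuous across
#' transitions; the weight slope may jump). Weight is `W = C/(rho*delta)`.
#'
#' @param t_day Time(s) in days from the record start.
#' @param params A [model_params()] object with at least `D`, `Q0`,
#'   `delta`, `eta`, `epsilon` (and `rho`).
#' @return Weight in lb, vectorised over `t_day`.
#' @export
weight_closed_form <- function(t_day, params) {
  p <- params
  for (nm in c("D", "Q0", "delta", "eta", "rho")) {
    if (is.null(p[[nm]])) stop_domain("params$", nm, " must be set")
  }
  if (is.null(p$epsilon)) stop_domain("params$epsilon must be set")
  if (p$eta <= max(p$epsilon)) {
    stop_domain("closed form requires eta > every epsilon")
  }
  Q <- expenditure(t_day, p$Q0, p$epsilon, p$t_transition)
  sec <- findInterval(t_day, p$t_transition) + 1L
  C <- p$D / p$eta - Q / (p$eta - p$epsilon[sec])
  calories_to_weight(C, p$rho, p$delta)
}

#' Right-hand side of the full two-state system
#'
#' Calorie balance `dC/dt = (D(t) - alpha*L) - Q(t)` (intake is the drive
#' damped by leptin) and leptin kinetics `dL/dt = beta*C - gamma*L`.
#'
#' @param state Numeric vector `c(C, L)`.
#' @param t_day Time in days.
#' @param params A [model_params()] with `alpha`, `beta`, `gamma`, `Q0`,
#'   `epsilon`.
#' @param drive_fn Function mapping time (days) to the drive D (cal/day).
#' @return Numeric vector `c(dC, dL)` of time derivatives.
#' @export
ode_rhs <- function(state, t_day, params, drive_fn) {
  C <- state[[1]]; L <- state[[2]]
  D <- drive_fn(t_day)
  if (any(D < 0)) stop_domain("drive_fn must return non-negative values")
  Q <- expenditure(t_day, params$Q0, params$epsilon, params$t_transition)
  c((D - params$alpha * L) - Q,
    params$beta * C - params$gamma * L)
}

#' Read and write model parameters as a flat key-value file
#'
#' Parameters serialise to plain text, one `key = value` per line, with
#' keys named after the model symbols (`D`, `alpha`, `beta`, `gamma`,
#' `delta`, `eta`, `Q0`, `epsilon1`, `epsilon2`, ..., `t_transition1`,
#' ..., `rho`, `L_ref`, `W_ref`).
#'
#' @param params A [model_params()] object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns
#'   a [model_params()] object.
#' @export
write_params <- function(params, path) {
  p <- unclass(params)
  lines <- character(0)
  add <- function(key, val) {
    if (!is.null(val) && length(val)) {
      c(lines, sprintf("%s = %.17g", key, val))
    } else lines
  }
  for (nm in c("D", "alpha", "beta", "gamma", "delta", "eta", "Q0")) {
    lines <- add(nm, p[[nm]])
  }
  if (!is.null(p$epsilon)) {
    for (i in seq_along(p$epsilon)) {
      lines <- add(paste0("epsilon", i), p$epsilon[i])
    }
  }
  for (i in seq_along(p$t_transition)) {
    lines <- add(paste0("t_transition", i), p$t_transition[i])
  }
  for (nm in c("rho", "L_ref", "W_ref")) lines <- add(nm, p[[nm]])
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop_domain("malformed parameter line: ", lines[which(bad)[1]])
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (any(is.na(vals))) {
    stop_domain("non-numeric parameter value for key: ", keys[is.na(vals)][1])
  }
  named <- stats::setNames(as.list(vals), keys)
  pick <- function(nm) if (nm %in% keys) named[[nm]] else NULL
  eps_keys <- sort(keys[grepl("^epsilon[0-9]+$", keys)])
  tr_keys <- sort(keys[grepl("^t_transition[0-9]+$", keys)])
  model_params(
    D = pick("D"), alpha = pick("alpha"), beta = pick("beta"),
    gamma = pick("gamma"), delta = pick("delta"), eta = pick("eta"),
    Q0 = pick("Q0"),
    epsilon = if (length(eps_keys)) unname(unlist(named[eps_keys])) else NULL,
    t_transition = if (length(tr_keys)) {
      unname(unlist(named[tr_keys]))
    } else numeric(0),
    rho = pick("rho") %||% 3500,
    L_ref = pick("L_ref") %||% 20.3,
    W_ref = pick("W_ref")
  )
}
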