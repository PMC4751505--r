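state_names <- c("A", "V", "B_I", "B_R", "S", "R", "Ag",
                 "D_L", "Dr_L", "C_L", "G_L", "I_L", "C_P", "G_P", "I_P")

#' Regimen-determined initial state
#'
#' Androgen starts at 1 in every regimen; the three treatment variables
#' (vaccine stimulus, anti-IL-2 antibody, anti-Treg antibody) start at 1
#' when the corresponding treatment is given and 0 otherwise; all
#' biological states (tumor populations, antigen, dendritic cells, T
#' cells, IL-2 in both compartments) start at 1, matching the relative
#' scale of the measurements.
#'
#' @param regimen A regimen object or label.
#' @return Named numeric vector of length 15.
#' @export
initial_state <- function(regimen = "SX") {
  rg <- as_regimen(regimen)
  setNames(c(1, as.numeric(rg$v), as.numeric(rg$ai), as.numeric(rg$ar),
             rep(1, 11)), state_names)
}

#' Model right-hand side (reference implementation)
#'
#' The 15 coupled time-derivatives of the tumor-immune system, written in
#' plain R. Simulation uses the compiled equivalent by default; this
#' function is the readable reference, used directly in tests and
#' available as a pluggable alternative right-hand side.
#'
#' @param state Named numeric state vector (see [initial_state()]).
#' @param t Time in weeks (the system is autonomous; `t` is accepted for
#'   solver compatibility).
#' @param params A parameter tibble (see [parameter_table()]).
#' @param regimen A regimen object or label; only the castration flag
#'   enters the right-hand side (the other treatments act through their
#'   initial values).
#' @return Named numeric vector of 15 derivatives.
#' @export
tumor_immune_rhs <- function(state, t = 0, params, regimen = "SX") {
  if (length(state) != length(state_names)) {
    abort(sprintf("`state` must have %d components.", length(state_names)))
  }
  if (any(!is.finite(state))) {
    bad <- state_names[!is.finite(state)]
    abort(paste0("Non-finite state component(s): ", paste(bad, collapse = ", ")))
  }
  p <- as.list(param_vector(params))
  rg <- as_regimen(regimen)
  s <- setNames(as.numeric(state), state_names)
  with(c(p, as.list(s)), {
    chi_cx <- as.numeric(rg$cx)
    h <- A / (theta_A + A)
    cap <- 1 - (S + R) / kappa
    stim <- Ag + omega_V * V
    c(
      A    = -delta_A * chi_cx * A,
      V    = -delta_V * V,
      B_I  = -delta_BI * B_I,
      B_R  = -delta_BR * B_R,
      S    = rho_S * h * S * cap - delta_S * S - lambda * (1 - h) * S - eta_S * C_P * S,
      R    = rho_R * R * cap - delta_R * R + lambda * (1 - h) * S - eta_R * C_P * R,
      Ag   = sigma_Ag * (delta_S * S + delta_R * R + eta_S * C_P * S + eta_R * C_P * R) - delta_Ag * Ag,
      D_L  = alpha_D * stim - delta_D * D_L,
      Dr_L = alpha_Dr * stim * G_L - delta_Dr * Dr_L,
      C_L  = alpha_C * D_L * (1 + beta_I * I_L) - xi_C * G_L * C_L - mu_C * C_L - tau_C * C_L,
      G_L  = alpha_G * I_L * G_L + zeta * Dr_L - mu_G * G_L - tau_G * G_L - kappa_AR * B_R * G_L,
      I_L  = sigma_I * C_L - delta_I * I_L - kappa_AI * B_I * I_L,
      C_P  = tau_C * C_L - xi_C * G_P * C_P - mu_C * C_P,
      G_P  = tau_G * G_L + alpha_G * I_P * G_P - mu_G * G_P - kappa_AR * B_R * G_P,
      I_P  = sigma_I * C_P - delta_I * I_P - kappa_AI * B_I * I_P
    )
  })
}

#' Simulate the tumor-immune model
#'
#' Integrates the 15-state system from the regimen-determined initial
#' condition with a stiff-capable solver (`deSolve::lsoda`). States are
#' floored at zero after solving (the dynamics keep exact solutions
#' non-negative; the floor removes solver-level excursions).
#'
#' @param params A parameter tibble.
#' @param regimen A regimen object or label.
#' @param horizon Final time, weeks (default 5; must be >= 5 for outcome
#'   computation).
#' @param step Output grid spacing in weeks (default 0.05). Ignored if
#'   `times` is given.
#' @param times Explicit output time vector (must start at 0).
#' @param compiled Use the compiled right-hand side (default) or the R
#'   reference implementation.
#' @param rtol,atol Solver relative / absolute tolerances.
#' @return A `prostimm_trajectory`: a tibble with a `time` column and the
#'   15 state columns, with the regimen and validity recorded as
#'   attributes. A solver failure or state blow-up marks the trajectory
#'   invalid rather than erroring (objective functions treat invalid
#'   trajectories as infinite error).
#' @examples
#' tr <- simulate_model(default_truth(), "CX")
#' head(observe(tr))
#' @export
simulate_model <- function(params, regimen = "SX", horizon = 5, step = 0.05,
                           times = NULL, compiled = TRUE,
                           rtol = 1e-6, atol = 1e-8) {
  rg <- as_regimen(regimen)
  check_parameter_table(params)
  if (is.null(times)) {
    times <- seq(0, horizon, by = step)
    if (horizon >= 5 && !all(c(2.5, 5) %in% times)) {
      times <- sort(unique(c(times, 2.5, 5)))
    }
  }
  if (times[1] != 0) abort("`times` must start at 0.")
  y0 <- initial_state(rg)
  pv <- c(param_vector(params), chi_cx = as.numeric(rg$cx))
  sol <- if (compiled) {
    try(suppressWarnings(
      deSolve::lsoda(y0, times, func = "prostimm_derivs", parms = pv,
                     dllname = "prostimm", initfunc = "prostimm_initmod",
                     rtol = rtol, atol = atol, maxsteps = 10000)), silent = TRUE)
  } else {
    try(suppressWarnings(
      deSolve::lsoda(y0, times,
                     func = function(t, y, p) list(unname(tumor_immune_rhs(y, t, params, rg))),
                     parms = NULL, rtol = rtol, atol = atol, maxsteps = 10000)),
        silent = TRUE)
  }
  valid <- !inherits(sol, "try-error") &&
    nrow(sol) == length(times) &&
    all(is.finite(sol)) && max(abs(sol)) < 1e8
  if (valid) {
    m <- as.data.frame(sol)
    m[m < 0] <- 0  # floor tiny negative solver excursions
    colnames(m) <- c("time", state_names)
    out <- as_tibble(m)
  } else {
    out <- as_tibble(setNames(as.data.frame(
      matrix(NA_real_, nrow = 0, ncol = 16)), c("time", state_names)))
  }
  structure(out, regimen = rg, valid = valid, params = params,
            class = c("prostimm_trajectory", class(out)))
}

is_valid_trajectory <- function(traj) isTRUE(attr(traj, "valid"))

check_trajectory <- function(traj) {
  if (!inherits(traj, "prostimm_trajectory")) {
    abort("Expected a trajectory from `simulate_model()`.")
  }
  if (!is_valid_trajectory(traj)) {
    abort(paste0("Invalid trajectory (solver failure or blow-up) for regimen ",
                 attr(traj, "regimen")$label, "."))
  }
  invisible(traj)
}

observable_names <- c("Tumor", "CTL-P", "Treg-P", "CTL-L", "Treg-L")

#' Measurable observables of a trajectory
#'
#' The five quantities measured in the experiments: relative tumor size
#' (the sum of the two tumor populations normalized to its initial
#' value), and the CTL and Treg populations in the prostate and lymphoid
#' compartments. All five equal 1 at time 0.
#'
#' @param traj A valid trajectory.
#' @return A long tibble: `time`, `observable`, `value`.
#' @export
observe <- function(traj) {
  check_trajectory(traj)
  tum0 <- traj$S[1] + traj$R[1]
  tibble(
    time = rep(traj$time, 5),
    observable = rep(observable_names, each = nrow(traj)),
    value = c((traj$S + traj$R) / tum0, traj$C_P, traj$G_P, traj$C_L, traj$G_L)
  )
}

tumor_series <- function(traj) {
  check_trajectory(traj)
  (traj$S + traj$R) / (traj$S[1] + traj$R[1])
}

#' Treatment outcomes from a trajectory
#'
#' Two tumor-size outcomes are used throughout: the type I outcome is the
#' instantaneous relative tumor size 5 weeks after treatment; the type II
#' outcome is the average relative tumor size over weeks 0-5 (composite
#' trapezoid on the solution grid).
#'
#' @param traj A valid trajectory with horizon >= 5 weeks.
#' @return `outcome_instantaneous()` and `outcome_average()` return single
#'   numbers; `outcomes()` returns a one-row tibble with `type_I` and
#'   `type_II`.
#' @export
outcome_instantaneous <- function(traj) {
  check_trajectory(traj)
  if (max(traj$time) < 5) abort("Trajectory horizon must reach 5 weeks.")
  tum <- tumor_series(traj)
  tum[match(5, traj$time)]
}

#' @rdname outcome_instantaneous
#' @export
outcome_average <- function(traj) {
  check_trajectory(traj)
  if (max(traj$time) < 5) abort("Trajectory horizon must reach 5 weeks.")
  keep <- traj$time <= 5
  tt <- traj$time[keep]
  tum <- tumor_series(traj)[keep]
  sum(diff(tt) * (tum[-length(tum)] + tum[-1]) / 2) / (max(tt) - min(tt))
}

#' @rdname outcome_instantaneous
#' @export
outcomes <- function(traj) {
  tibble(type_I = outcome_instantaneous(traj), type_II = outcome_average(traj))
}

#' Percent tumor-growth inhibition
#'
#' Treatment effect expressed as the percentage reduction of a tumor-size
#' outcome relative to the untreated control: `100 * (1 - x / control)`.
#' Negative values mean the treatment worsened the outcome.
#'
#' @param x Outcome value(s) under treatment.
#' @param control Outcome value under the untreated control (must be
#'   positive).
#' @return Percentage inhibition (vectorized over `x`).
#' @export
percent_inhibition <- function(x, control) {
  if (!is.finite(control) || control <= 0) {
    abort("`control` outcome must be a positive finite number.")
  }
  100 * (1 - x / control)
}
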