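#' Mean-field model derivatives
#'
#' Right-hand side of the deterministic ordinary differential equations:
#' target cells are infected at rate `gamma*beta*T*V/s`, cells cascade
#' through `n_E` eclipse and `n_I` infectious compartments at per-stage rates
#' `n_E/tau_E` and `n_I/tau_I`, and virions obey
#' `dV/dt = p*sum(I) - c*V - beta*T*V/s` — note the entry-loss term removes
#' every entering virion regardless of post-entry success.
#'
#' The state vector ordering is `[T, E_1..E_nE, I_1..I_nI, V]`.
#'
#' @param state Numeric state vector of length `2 + n_E + n_I`.
#' @param params An [infection_params] object.
#' @return Numeric derivative vector of the same length.
#' @export
mfm_derivatives <- function(state, params) {
  nE <- params$n_E; nI <- params$n_I
  stopifnot(length(state) == 2 + nE + nI)
  T <- state[1]
  E <- state[1 + seq_len(nE)]
  I <- state[1 + nE + seq_len(nI)]
  V <- state[2 + nE + nI]
  kE <- nE / params$tau_E
  kI <- nI / params$tau_I
  infect <- params$gamma * params$beta * T * V / params$s
  dT <- -infect
  dE <- kE * c(0, E[-nE][seq_len(nE - 1)]) - kE * E
  dE[1] <- dE[1] + infect
  dI <- kI * c(0, I[-nI][seq_len(nI - 1)]) - kI * I
  dI[1] <- dI[1] + kE * E[nE]
  dV <- params$p * sum(I) - params$c * V - params$beta * T * V / params$s
  c(dT, dE, dI, dV)
}

#' Solve the mean-field model
#'
#' Integrates the deterministic model with `deSolve::lsoda` from the
#' inoculum stored in `params` (`T(0) = N_cells`, `V(0) = V0`,
#' `I_1(0) = I0`). When `t_end` is `NULL` the horizon is extended in chunks
#' until the infection has burnt out (`V < 1e-6` and total infected cell
#' mass `< 1e-6`), so that `T(t_end)` approximates the final size `T(Inf)`.
#'
#' @param params An [infection_params] object.
#' @param t_end Integration horizon in hours, or `NULL` to integrate to
#'   burn-out (capped at `max_t`).
#' @param dt_out Output grid spacing, hours.
#' @param rtol,atol Solver tolerances.
#' @param max_t Cap on the automatic horizon.
#' @return Object of class `mfm_trajectory`: a data frame with columns `t`,
#'   `T`, `E1..`, `I1..`, `V` and `R_t` (the running reproduction number
#'   `gamma*p*tau_I * T / (c*s/beta + T)`), with attribute `params`.
#' @examples
#' traj <- solve_mfm(sars2_baseline_params())
#' 1 - tail(traj$T, 1) / 4e4  # fraction of cells consumed
#' @export
solve_mfm <- function(params, t_end = NULL, dt_out = 1,
                      rtol = 1e-8, atol = 1e-10, max_t = 2e5) {
  stopifnot(inherits(params, "infection_params"))
  y0 <- c(params$N_cells, numeric(params$n_E),
          c(params$I0, numeric(params$n_I - 1)), params$V0)
  rhs <- function(t, y, parms) list(mfm_derivatives(y, params))
  burnt_out <- function(y) {
    nE <- params$n_E; nI <- params$n_I
    infected <- sum(y[1 + seq_len(nE)]) + sum(y[1 + nE + seq_len(nI)])
    y[2 + nE + nI] < 1e-6 && infected < 1e-6
  }
  if (!is.null(t_end)) {
    stopifnot(t_end > 0)
    times <- seq(0, t_end, by = dt_out)
    sol <- deSolve::lsoda(y0, times, rhs, NULL, rtol = rtol, atol = atol)
  } else {
    chunk <- 2000
    sol <- deSolve::lsoda(y0, seq(0, chunk, by = dt_out), rhs, NULL,
                          rtol = rtol, atol = atol)
    while (!burnt_out(sol[nrow(sol), -1]) && sol[nrow(sol), 1] < max_t) {
      t0 <- sol[nrow(sol), 1]
      nxt <- deSolve::lsoda(sol[nrow(sol), -1], seq(t0, t0 + chunk, dt_out),
                            rhs, NULL, rtol = rtol, atol = atol)
      sol <- rbind(sol, nxt[-1, , drop = FALSE])
    }
  }
  df <- as.data.frame(sol)
  names(df) <- c("t", "T", paste0("E", seq_len(params$n_E)),
                 paste0("I", seq_len(params$n_I)), "V")
  df$R_t <- params$gamma * params$p * params$tau_I * df$T /
    (params$c * params$s / params$beta + df$T)
  attr(df, "params") <- params
  class(df) <- c("mfm_trajectory", "data.frame")
  df
}

#' One expected-value step of the stochastic model
#'
#' Advances a real-valued state by one tau-leaping step with every random
#' variable replaced by its expectation: binomial exits by `n * p`, Poisson
#' production by its mean, the trinomial split by `V*dt*c` and
#' `V*dt*beta*T/s`, successful entries by `V_enter * gamma`, and the
#' distinct-cell count by [expected_unique_infections()] (0 when `T < 1`).
#' Iterated, this defines a deterministic map whose trajectory tracks the
#' mean-field differential equations closely at small `P_events`.
#'
#' @param state State list as from [initial_state()] (real-valued fields).
#' @param params An [infection_params] object.
#' @param dt Time step (defaults to [compute_time_step()] at the current
#'   state).
#' @return The advanced state.
#' @export
expected_value_step <- function(state, params,
                                dt = compute_time_step(state, params)) {
  pE <- dt * params$n_E / params$tau_E
  pI <- dt * params$n_I / params$tau_I
  E_out <- state$E * pE
  I_out <- state$I * pI
  V_prod <- dt * params$p * sum(state$I)
  V_decay <- state$V * dt * params$c
  V_enter <- state$V * dt * params$beta * state$T / params$s
  V_suc <- V_enter * params$gamma
  N_inf <- if (state$T < 1) 0 else expected_unique_infections(state$T, V_suc)
  nE <- params$n_E; nI <- params$n_I
  E <- state$E; I <- state$I
  E[1] <- E[1] + N_inf - E_out[1]
  if (nE > 1) for (i in 2:nE) E[i] <- E[i] + E_out[i - 1] - E_out[i]
  I[1] <- I[1] + E_out[nE] - I_out[1]
  if (nI > 1) for (j in 2:nI) I[j] <- I[j] + I_out[j - 1] - I_out[j]
  list(t = state$t + dt, T = state$T - N_inf, E = E, I = I,
       V = state$V + V_prod - V_decay - V_enter,
       cumulative_infected = state$cumulative_infected + N_inf,
       cumulative_virions_produced =
         state$cumulative_virions_produced + V_prod)
}

#' Solve the expected-value stochastic model
#'
#' Iterates [expected_value_step()] from the inoculum until burn-out
#' (`V < 1e-6` and infected mass `< 1e-6`) or `t_end`. Serves as a
#' cross-validation bridge between the stochastic update rules and the
#' mean-field differential equations.
#'
#' @param params An [infection_params] object.
#' @param t_end Horizon in hours, or `NULL` for burn-out (capped at `max_t`).
#' @param config A [simulator_config] object (sets `P_events`).
#' @param max_t Cap on the automatic horizon.
#' @return Data frame with columns `t`, `T`, `Etot`, `Itot`, `V`, one row per
#'   step.
#' @export
solve_expected_value <- function(params, t_end = NULL,
                                 config = simulator_config(), max_t = 2e5) {
  state <- initial_state(params)
  state$T <- as.double(state$T); state$E <- as.double(state$E)
  state$I <- as.double(state$I); state$V <- as.double(state$V)
  horizon <- if (is.null(t_end)) max_t else t_end
  n_guess <- 4096
  out <- matrix(NA_real_, n_guess, 5)
  k <- 0
  repeat {
    k <- k + 1
    if (k > nrow(out)) out <- rbind(out, matrix(NA_real_, nrow(out), 5))
    out[k, ] <- c(state$t, state$T, sum(state$E), sum(state$I), state$V)
    done <- state$V < 1e-6 && sum(state$E) + sum(state$I) < 1e-6
    if ((is.null(t_end) && done) || state$t >= horizon) break
    state <- expected_value_step(state, params,
                                 compute_time_step(state, params, config))
  }
  df <- as.data.frame(out[seq_len(k), , drop = FALSE])
  names(df) <- c("t", "T", "Etot", "Itot", "V")
  df
}
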