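#' Simulator configuration
#'
#' Settings of the adaptive-time-step (tau-leaping) stochastic simulator.
#' `P_events` is the per-step probability of the most likely single event;
#' the time step is chosen each iteration as `P_events` divided by the
#' largest per-capita rate, so every per-individual event probability stays
#' at or below `P_events`. The default 0.05 keeps the discretization error
#' of key ensemble statistics around 1e-4.
#'
#' @param P_events Maximum per-step event probability, in (0, 0.1].
#' @param max_time Safety horizon in hours; runs still active at `max_time`
#'   are flagged censored.
#' @param record_trajectory Record the full state at every step boundary?
#' @return Object of class `simulator_config`.
#' @export
simulator_config <- function(P_events = 0.05, max_time = 1e4,
                             record_trajectory = FALSE) {
  stopifnot(is.numeric(P_events), length(P_events) == 1L,
            P_events > 0, P_events <= 0.1,
            is.numeric(max_time), max_time > 0)
  structure(list(P_events = P_events, max_time = max_time,
                 record_trajectory = isTRUE(record_trajectory)),
            class = "simulator_config")
}

#' Initial simulation state
#'
#' Integer compartment occupancies at time zero: all cells susceptible, the
#' inoculum's `I0` cells placed in the first infectious compartment and `V0`
#' virions free.
#'
#' @param params An [infection_params] object.
#' @return List with `t`, `T`, `E`, `I`, `V`, `cumulative_infected`,
#'   `cumulative_virions_produced`.
#' @export
initial_state <- function(params) {
  I <- integer(params$n_I)
  I[1] <- params$I0
  list(t = 0, T = params$N_cells, E = integer(params$n_E), I = I,
       V = params$V0, cumulative_infected = 0,
       cumulative_virions_produced = 0)
}

#' Adaptive time step
#'
#' `dt = P_events / max(beta*T/s, c, n_E/tau_E, n_I/tau_I)`, recomputed every
#' step since the entry rate depends on the current number of susceptible
#' cells.
#'
#' @param state Simulation state (see [initial_state()]).
#' @param params An [infection_params] object.
#' @param config A [simulator_config] object.
#' @return Time step in hours.
#' @export
compute_time_step <- function(state, params, config = simulator_config()) {
  rmax <- max(params$beta * state$T / params$s, params$c,
              params$n_E / params$tau_E, params$n_I / params$tau_I)
  config$P_events / rmax
}

#' Count distinct cells hit by successful virions
#'
#' Places `V_suc` successful virions uniformly at random (with replacement)
#' among `T` target cells and counts the distinct cells hit — two successful
#' virions landing in the same cell produce a single infection. Uses the
#' session RNG.
#'
#' @param T Number of target cells (non-negative integer).
#' @param V_suc Number of successful virions (non-negative integer).
#' @return Integer count of newly infected cells, `<= min(T, V_suc)`.
#' @export
count_unique_infections <- function(T, V_suc) {
  stopifnot(T >= 0, V_suc >= 0)
  if (T == 0 || V_suc == 0) return(0L)
  if (T == 1) return(1L)
  length(unique(floor(stats::runif(V_suc) * T)))
}

#' Draw the random event counts of one step
#'
#' One set of tau-leaping draws: binomial exits from each eclipse and
#' infectious compartment, Poisson virion production, a trinomial split of
#' free virions into decayed / entered / persisting (realized exactly as two
#' nested binomials), binomial thinning of entries into successful entries
#' with probability `gamma`, and the distinct-cell count `N_inf`.
#'
#' @param state Simulation state.
#' @param params An [infection_params] object.
#' @param dt Time step from [compute_time_step()].
#' @return List with `E_out`, `I_out`, `V_prod`, `V_decay`, `V_enter`,
#'   `V_suc`, `N_inf`.
#' @export
draw_step_events <- function(state, params, dt) {
  pE <- dt * params$n_E / params$tau_E
  pI <- dt * params$n_I / params$tau_I
  p1 <- dt * params$c
  p2 <- dt * params$beta * state$T / params$s
  stopifnot(pE <= 1, pI <= 1, p1 + p2 <= 1)
  E_out <- vapply(state$E, function(n) stats::rbinom(1L, n, pE), numeric(1))
  I_out <- vapply(state$I, function(n) stats::rbinom(1L, n, pI), numeric(1))
  V_prod <- stats::rpois(1L, dt * params$p * sum(state$I))
  V_decay <- stats::rbinom(1L, state$V, p1)
  V_enter <- stats::rbinom(1L, state$V - V_decay, p2 / (1 - p1))
  V_suc <- stats::rbinom(1L, V_enter, params$gamma)
  N_inf <- count_unique_infections(state$T, V_suc)
  list(E_out = E_out, I_out = I_out, V_prod = V_prod,
       V_decay = V_decay, V_enter = V_enter, V_suc = V_suc, N_inf = N_inf)
}

#' Advance the stochastic state by one step
#'
#' Applies one set of step draws to every compartment: susceptible cells
#' decrease by `N_inf` and feed the first eclipse compartment, compartment
#' exits cascade down the eclipse and infectious chains, and the virion pool
#' gains `V_prod` and loses `V_decay + V_enter`. Cell conservation
#' (`T + sum(E) + sum(I) + dead = N_cells`) holds by construction; a breach
#' indicates an implementation bug and raises an error.
#'
#' @param state Simulation state.
#' @param params An [infection_params] object.
#' @param config A [simulator_config] object.
#' @return The advanced state.
#' @export
advance <- function(state, params, config = simulator_config()) {
  dt <- compute_time_step(state, params, config)
  d <- draw_step_events(state, params, dt)
  nE <- params$n_E; nI <- params$n_I
  E <- state$E; I <- state$I
  Tnew <- state$T - d$N_inf
  E[1] <- E[1] + d$N_inf - d$E_out[1]
  if (nE > 1) for (i in 2:nE) E[i] <- E[i] + d$E_out[i - 1] - d$E_out[i]
  I[1] <- I[1] + d$E_out[nE] - d$I_out[1]
  if (nI > 1) for (j in 2:nI) I[j] <- I[j] + d$I_out[j - 1] - d$I_out[j]
  Vnew <- state$V + d$V_prod - d$V_decay - d$V_enter
  if (Tnew < 0 || Vnew < 0 || any(E < 0) || any(I < 0)) {
    stop("negative compartment occupancy: invariant breach", call. = FALSE)
  }
  list(t = state$t + dt, T = Tnew, E = E, I = I, V = Vnew,
       cumulative_infected = state$cumulative_infected + d$N_inf,
       cumulative_virions_produced =
         state$cumulative_virions_produced + d$V_prod)
}

#' Simulate one stochastic infection
#'
#' Runs the tau-leaping stochastic model from the inoculum in `params` until
#' no further event can fire (`V = 0` and all eclipse and infectious
#' compartments empty) or until `config$max_time`, in which case the run is
#' flagged censored. The default engine is the compiled kernel; the pure-R
#' engine executes the identical sequence of RNG draws and therefore gives
#' bit-identical results from the same seed.
#'
#' @param params An [infection_params] object.
#' @param config A [simulator_config] object.
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation built on [advance()]).
#' @return Object of class `simulation_result`: list with final `state`,
#'   `cells_consumed`, `censored`, `steps`, and when requested a `trajectory`
#'   data frame with columns `t`, `T`, `E1..`, `I1..`, `V` recorded at step
#'   boundaries.
#' @examples
#' par <- sars2_baseline_params()
#' set.seed(1)
#' simulate_infection(par)$cells_consumed
#' @export
simulate_infection <- function(params, config = simulator_config(),
                               engine = c("cpp", "R")) {
  stopifnot(inherits(params, "infection_params"),
            inherits(config, "simulator_config"))
  engine <- match.arg(engine)
  if (engine == "cpp") {
    raw <- cpp_sm_run(params$beta, params$p, params$c, params$gamma,
                      params$n_E, params$n_I, params$tau_E, params$tau_I,
                      params$N_cells, params$s, params$V0, params$I0,
                      config$P_events, config$max_time,
                      config$record_trajectory)
    state <- list(t = raw$t, T = raw$T, E = raw$E, I = raw$I, V = raw$V,
                  cumulative_infected = raw$cumulative_infected,
                  cumulative_virions_produced =
                    raw$cumulative_virions_produced)
    res <- list(state = state, cells_consumed = raw$cells_consumed,
                censored = raw$censored, steps = raw$steps)
    if (config$record_trajectory) {
      res$trajectory <- as_trajectory_df(raw$trajectory,
                                         params$n_E, params$n_I)
    }
  } else {
    state <- initial_state(params)
    traj <- if (config$record_trajectory) list(state) else NULL
    steps <- 0
    censored <- FALSE
    repeat {
      if (state$V == 0 && sum(state$E) == 0 && sum(state$I) == 0) break
      if (state$t >= config$max_time) { censored <- TRUE; break }
      state <- advance(state, params, config)
      steps <- steps + 1
      if (config$record_trajectory) traj[[steps + 1]] <- state
    }
    res <- list(state = state,
                cells_consumed = params$N_cells - state$T,
                censored = censored, steps = steps)
    if (config$record_trajectory) {
      m <- t(vapply(traj, function(s) c(s$t, s$T, s$E, s$I, s$V),
                    numeric(3 + params$n_E + params$n_I)))
      res$trajectory <- as_trajectory_df(m, params$n_E, params$n_I)
    }
  }
  class(res) <- "simulation_result"
  res
}

as_trajectory_df <- function(m, n_E, n_I) {
  df <- as.data.frame(m)
  names(df) <- c("t", "T", paste0("E", seq_len(n_E)),
                 paste0("I", seq_len(n_I)), "V")
  df
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Stochastic infection run: %s cells consumed in %.1f h (%d steps)%s\n",
    format(x$cells_consumed, big.mark = ","), x$state$t, x$steps,
    if (x$censored) " [censored at max_time]" else ""))
  invisible(x)
}

# Deterministic per-run child seed spawned from the master seed. LCG-style
# mixing keeps results reproducible and independent of run order; all values
# stay below 2^31 - 1.
spawn_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 1664525) %%
               2147483647)
}

#' Simulate an ensemble of stochastic infections
#'
#' Independent runs of [simulate_infection()], each seeded with a child seed
#' derived deterministically from `seed` and the run index, so the ensemble
#' is reproducible and each run's result does not depend on execution order.
#'
#' @param params An [infection_params] object.
#' @param n_runs Number of runs.
#' @param seed Master seed (integer).
#' @param config A [simulator_config] object.
#' @param engine Simulation engine, see [simulate_infection()].
#' @return Object of class `simulation_ensemble`: a list of
#'   `simulation_result` objects with attributes `params`, `seed`.
#' @examples
#' par <- sars2_baseline_params()
#' runs <- simulate_ensemble(par, n_runs = 20, seed = 1)
#' summarize_ensemble(runs, par)
#' @export
simulate_ensemble <- function(params, n_runs, seed,
                              config = simulator_config(),
                              engine = c("cpp", "R")) {
  stopifnot(n_runs >= 1)
  engine <- match.arg(engine)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(spawn_seed(seed, i))
    runs[[i]] <- simulate_infection(params, config, engine)
    runs[[i]]$seed <- spawn_seed(seed, i)
  }
  structure(runs, params = params, seed = seed,
            class = "simulation_ensemble")
}

#' @export
print.simulation_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d stochastic infection runs (master seed %d)\n",
              length(x), attr(x, "seed")))
  invisible(x)
}

#' Simulate method for infection parameter sets
#'
#' `simulate()` on an [infection_params] object runs a stochastic ensemble;
#' equivalent to [simulate_ensemble()].
#'
#' @param object An [infection_params] object.
#' @param nsim Number of runs.
#' @param seed Master seed.
#' @param ... Passed to [simulate_ensemble()] (`config`, `engine`).
#' @return A `simulation_ensemble`.
#' @export
simulate.infection_params <- function(object, nsim = 1, seed = 1, ...) {
  simulate_ensemble(object, n_runs = nsim, seed = seed, ...)
}

#' Sample burst sizes of single infectious cells
#'
#' Simulates cells one at a time through the `n_I` infectious compartments
#' with the stochastic model's step rules (no virion entry or decay) and
#' returns the total number of virions each produced. The time step is the
#' one the full simulator would use in a fully susceptible population, so
#' the empirical distribution matches [burst_size_pmf()] up to the
#' finite-step discretization of the simulator.
#'
#' @param params An [infection_params] object.
#' @param n Number of cells to sample.
#' @param config A [simulator_config] object (only `P_events` is used).
#' @return Integer vector of burst sizes. Uses the session RNG.
#' @export
sample_burst_size <- function(params, n = 1, config = simulator_config()) {
  stopifnot(inherits(params, "infection_params"), n >= 1)
  dt <- compute_time_step(initial_state(params), params, config)
  cpp_sample_bursts(as.integer(n), params$p, params$n_I, params$tau_I, dt)
}

#' Sample the fate of single virions
#'
#' Tracks virions one at a time in a fully susceptible population (target
#' cells held at `N_cells`) with the stochastic model's per-step trinomial
#' rule until each decays or enters a cell; entries succeed with probability
#' `gamma`. The empirical success frequency estimates the per-virion
#' infection probability [prob_virion_infects()].
#'
#' @param params An [infection_params] object.
#' @param n Number of virions.
#' @param config A [simulator_config] object (only `P_events` is used).
#' @return Logical vector: `TRUE` for virions causing a productive infection.
#' @export
sample_virion_success <- function(params, n = 1,
                                  config = simulator_config()) {
  stopifnot(inherits(params, "infection_params"), n >= 1)
  cpp_virion_success(as.integer(n), params$beta, params$c, params$gamma,
                     params$N_cells, params$s,
                     params$n_E / params$tau_E, params$n_I / params$tau_I,
                     config$P_events) > 0
}
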