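test_that("the adaptive time step is set by the fastest per-capita rate", {
  par <- baseline()
  st <- initial_state(par)
  # at the baseline c = 10/24 /h dominates beta*N/s, n_E/tau_E, n_I/tau_I
  expect_equal(compute_time_step(st, par), 0.05 * 24 / 10, tolerance = 1e-12)
  # with all four rates equal to r, dt = P_events / r
  pe <- infection_params(p = 1, c = 0.25, tau_E = 4, tau_I = 4,
                         N_cells = 1000, beta = 0.25 / 1000, s = 1)
  expect_equal(compute_time_step(initial_state(pe), pe), 0.05 / 0.25,
               tolerance = 1e-12)
  # T = 0 removes the entry rate from the maximum
  st0 <- st; st0$T <- 0
  expect_equal(compute_time_step(st0, par),
               0.05 / max(par$c, 1 / par$tau_E, 1 / par$tau_I),
               tolerance = 1e-12)
})

test_that("step draws respect their structural bounds", {
  par <- baseline(n_I = 3L, V0 = 500L, I0 = 20L)
  st <- initial_state(par)
  st$E <- c(40L, 0L, 10L)[seq_len(par$n_E)]
  set.seed(99)
  for (i in 1:200) {
    dt <- compute_time_step(st, par)
    d <- draw_step_events(st, par, dt)
    expect_true(all(d$E_out <= st$E))
    expect_true(all(d$I_out <= st$I))
    expect_lte(d$V_decay + d$V_enter, st$V)
    expect_lte(d$V_suc, d$V_enter)
    expect_lte(d$N_inf, min(d$V_suc, st$T))
  }
  # degenerate states produce no events
  st0 <- initial_state(baseline(V0 = 0L))
  set.seed(1)
  d0 <- draw_step_events(st0, par, 0.1)
  expect_equal(d0$V_decay + d0$V_enter + d0$V_suc + d0$V_prod, 0)
})

test_that("virion production draws have the prescribed mean", {
  par <- baseline(I0 = 50L)
  st <- initial_state(par)
  dt <- compute_time_step(st, par)
  set.seed(7)
  vp <- replicate(2e4, draw_step_events(st, par, dt)$V_prod)
  lam <- dt * par$p * 50
  expect_lt(abs(mean(vp) - lam), 4 * sqrt(lam / 2e4))
})

test_that("unique-infection counting matches its enumerated expectation", {
  set.seed(31)
  expect_equal(count_unique_infections(5, 0), 0L)
  expect_equal(count_unique_infections(0, 5), 0L)
  expect_equal(count_unique_infections(1, 5), 1L)
  n <- 5e4
  draws <- replicate(n, count_unique_infections(2, 2))
  se <- stats::sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - 1.5), 4 * se)
})

test_that("advance preserves cell conservation and bookkeeping identities", {
  par <- baseline(n_E = 2L, n_I = 3L, V0 = 30L, I0 = 5L, N_cells = 500L)
  cfg <- simulator_config()
  set.seed(11)
  st <- initial_state(par)
  dead <- 0
  for (i in 1:2000) {
    if (st$V == 0 && sum(st$E) == 0 && sum(st$I) == 0) break
    prev <- st
    st <- advance(st, par, cfg)
    dead <- dead + (prev$T + sum(prev$E) + sum(prev$I)) -
      (st$T + sum(st$E) + sum(st$I))
    # the inoculated infectious cells are on top of the susceptible pool
    expect_equal(st$T + sum(st$E) + sum(st$I) + dead,
                 par$N_cells + par$I0)
    expect_lte(st$T, prev$T)
    expect_true(all(c(st$T, st$E, st$I, st$V) >= 0))
  }
  # finished run: every infected cell passed through E1, so the cumulative
  # infection count equals the cells lost from the susceptible pool
  expect_equal(st$cumulative_infected, par$N_cells - st$T)
  # an all-virus-free state only advances the clock
  quiet <- list(t = 0, T = 100L, E = integer(1), I = integer(1), V = 0L,
                cumulative_infected = 0, cumulative_virions_produced = 0)
  par1 <- baseline(N_cells = 100L)
  out <- advance(quiet, par1, cfg)
  expect_equal(out[c("T", "E", "I", "V")], quiet[c("T", "E", "I", "V")])
  expect_gt(out$t, 0)
})

test_that("the compiled and pure-R engines are bit-identical run for run", {
  par <- apply_antiviral(baseline(V0 = 3L), "reduce_p", 0.7)
  for (seed in c(5, 17, 91)) {
    set.seed(seed)
    a <- simulate_infection(par, engine = "cpp")
    set.seed(seed)
    b <- simulate_infection(par, engine = "R")
    expect_equal(as.double(a$cells_consumed), as.double(b$cells_consumed))
    expect_equal(a$state$t, b$state$t, tolerance = 1e-12)
    expect_equal(as.double(a$state$V), as.double(b$state$V))
    expect_equal(as.double(a$steps), as.double(b$steps))
  }
})

test_that("degenerate parameter limits give the exact deterministic outcome", {
  # no inoculum: nothing happens
  par0 <- baseline(V0 = 0L, I0 = 0L)
  set.seed(1)
  r0 <- simulate_infection(par0)
  expect_equal(r0$cells_consumed, 0)
  expect_equal(r0$steps, 0)
  # one virion, no production, no decay, certain entry success:
  # exactly one cell is consumed in every run
  par1 <- baseline(V0 = 1L)
  par1$p <- 1e-12; par1$c <- 1e-9; par1$gamma <- 1
  set.seed(2)
  for (i in 1:20) {
    expect_equal(simulate_infection(par1)$cells_consumed, 1)
  }
})

test_that("ensembles are reproducible and order-stable", {
  par <- tstar_setting(0.5)
  e1 <- simulate_ensemble(par, 5, seed = 42)
  e2 <- simulate_ensemble(par, 5, seed = 42)
  expect_identical(vapply(e1, `[[`, 0, "cells_consumed"),
                   vapply(e2, `[[`, 0, "cells_consumed"))
  # a single run equals simulate_infection under the derived child seed
  single <- simulate_ensemble(par, 1, seed = 42)
  set.seed(single[[1]]$seed)
  direct <- simulate_infection(par)
  expect_identical(single[[1]]$cells_consumed, direct$cells_consumed)
  # the simulate() S3 method is a synonym
  e3 <- simulate(par, nsim = 5, seed = 42)
  expect_identical(vapply(e3, `[[`, 0, "cells_consumed"),
                   vapply(e1, `[[`, 0, "cells_consumed"))
})

test_that("trajectories record conserved, non-increasing target cells", {
  par <- baseline(N_cells = 2000L, V0 = 20L)
  set.seed(3)
  r <- simulate_infection(par, simulator_config(record_trajectory = TRUE))
  tr <- r$trajectory
  expect_true(all(diff(tr$T) <= 0))
  expect_equal(tr$T[1], 2000)
  expect_equal(tr$V[1], 20)
  expect_equal(tr$T[nrow(tr)], 2000 - r$cells_consumed)
})

test_that("sampled burst sizes match the negative binomial law", {
  par <- baseline()
  d <- derive_quantities(par)
  set.seed(12)
  b <- sample_burst_size(par, 2e4)
  expect_lt(abs(mean(b) - d$B), 4 * stats::sd(b) / sqrt(2e4))
  p5 <- mean(b <= 5)
  th5 <- sum(burst_size_pmf(0:5, par))
  expect_lt(abs(p5 - th5), 3 * sqrt(th5 * (1 - th5) / 2e4))
  # production off: no virions ever
  parp <- baseline(); parp$p <- 1e-300
  set.seed(13)
  expect_true(all(sample_burst_size(parp, 100) == 0))
})

test_that("single-virion success frequency matches the entry-race probability", {
  par <- baseline()
  set.seed(14)
  s <- sample_virion_success(par, 2e4)
  th <- prob_virion_infects(par)
  expect_lt(abs(mean(s) - th), 3 * sqrt(th * (1 - th) / 2e4))
})
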