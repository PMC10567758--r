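test_that("critical efficacies match the published thresholds", {
  par <- baseline()
  expect_equal(critical_efficacy(par, "reduce_p"), 0.87, tolerance = 0.005)
  expect_equal(critical_efficacy(par, "reduce_gamma"), 0.87, tolerance = 0.005)
  expect_equal(critical_efficacy(par, "reduce_beta"), 0.92, tolerance = 0.005)
  # at each critical efficacy the reproduction number is exactly 1
  for (mode in c("reduce_p", "reduce_gamma", "reduce_beta")) {
    eps <- critical_efficacy(par, mode)
    expect_equal(derive_quantities(apply_antiviral(par, mode, eps))$R0, 1,
                 tolerance = 1e-8)
  }
  # subcritical baseline: efficacy 0 with a warning
  sub <- apply_antiviral(par, "reduce_p", 0.95)
  expect_warning(e0 <- critical_efficacy(sub, "reduce_p"))
  expect_equal(as.numeric(e0), 0)
})

test_that("eps50 halves the establishment probability and matches the table", {
  par <- baseline()
  # the published whole-percent values for a single-virion inoculum, nI = 1
  expect_equal(round(100 * epsilon_50(par, "reduce_p", V0 = 1)), 77,
               tolerance = 1)
  expect_equal(round(100 * epsilon_50(par, "reduce_beta", V0 = 1)), 57,
               tolerance = 1)
  expect_equal(round(100 * epsilon_50(par, "reduce_gamma", V0 = 1)), 43,
               tolerance = 1)
  # defining property, checked at an asymmetric setting
  p60 <- baseline(n_I = 60L)
  eps <- epsilon_50(p60, "reduce_beta", V0 = 10)
  est0 <- extinction_prob_inoculum(p60, V0 = 10)$establishment
  est <- extinction_prob_inoculum(apply_antiviral(p60, "reduce_beta", eps),
                                  V0 = 10)$establishment
  expect_equal(est, est0 / 2, tolerance = 1e-6)
})

test_that("eps50 table reproduces published whole-percent entries", {
  tab <- epsilon50_table(baseline())
  pick <- function(mode, n_I, V0) {
    round(tab$eps50_percent[tab$mode == mode & tab$n_I == n_I &
                              tab$V0 == V0])
  }
  published <- list( # mode, n_I, V0, percent
    list("reduce_gamma", 1, 1, 43), list("reduce_beta", 1, 1, 57),
    list("reduce_p", 1, 1, 77),
    list("reduce_gamma", 60, 1, 49), list("reduce_beta", 60, 1, 62),
    list("reduce_p", 60, 1, 82),
    list("reduce_gamma", 1, 10, 71), list("reduce_p", 1, 10, 85),
    # (the entry-rate V0=10, nI=1 cell is quoted from earlier work and
    #  differs ~0.5 pt from direct evaluation; not asserted)
    list("reduce_gamma", 60, 10, 77), list("reduce_beta", 60, 10, 85),
    list("reduce_p", 60, 10, 86)
  )
  for (cell in published) {
    expect_equal(pick(cell[[1]], cell[[2]], cell[[3]]), cell[[4]],
                 tolerance = 1, label = paste(unlist(cell), collapse = "/"))
  }
})

test_that("efficacy sweeps are monotone and flag subcritical points", {
  par <- baseline()
  grid <- seq(0, 0.95, length.out = 40)
  for (mode in c("reduce_p", "reduce_beta", "reduce_gamma")) {
    sw <- efficacy_sweep(par, mode, grid, V0 = 1, I0 = 0)
    expect_true(all(diff(sw$establishment) <= 1e-12))
    fc <- sw$fraction_consumed[sw$supercritical]
    expect_true(all(diff(fc) <= 1e-12))
    expect_true(all(sw$establishment[!sw$supercritical] == 0))
    expect_true(all(is.na(sw$fraction_consumed[!sw$supercritical])))
  }
  # eps = 0 reproduces the baseline quantities
  sw0 <- efficacy_sweep(par, "reduce_p", 0)
  expect_equal(sw0$establishment,
               extinction_prob_inoculum(par)$establishment, tolerance = 1e-12)
  # production-rate and post-entry modes consume identically at every eps:
  # exact in T*/N; the consumed fraction itself differs only through the
  # O(1e-5) single-virion inoculum term gamma*beta*V0/(s*c)
  swp <- efficacy_sweep(par, "reduce_p", grid)
  swg <- efficacy_sweep(par, "reduce_gamma", grid)
  expect_equal(swp$Tstar_frac, swg$Tstar_frac, tolerance = 1e-12)
  expect_lt(max(abs(swp$fraction_consumed - swg$fraction_consumed),
                na.rm = TRUE), 1e-4)
  # and their establishment curves are related by the factor (1 - eps)
  sup <- swp$supercritical
  expect_equal(swg$establishment[sup],
               (1 - grid[sup]) * swp$establishment[sup], tolerance = 1e-10)
})

test_that("post-entry mode dominates on a randomized parameter grid", {
  set.seed(20240915)
  for (rep in 1:25) {
    par <- infection_params(
      p = exp(stats::runif(1, log(0.05), log(5))),
      c = exp(stats::runif(1, log(0.05), log(5))),
      tau_E = stats::runif(1, 2, 30),
      tau_I = stats::runif(1, 5, 80),
      N_cells = sample(c(4e3, 4e4, 4e5), 1),
      beta = exp(stats::runif(1, log(1e-8), log(1e-4))),
      gamma = stats::runif(1, 0.2, 1),
      n_I = sample(c(1L, 2L, 7L, 60L), 1)
    )
    eps <- stats::runif(1, 0, 0.95)
    est <- vapply(c("reduce_gamma", "reduce_p", "reduce_beta"), function(m) {
      extinction_prob_inoculum(apply_antiviral(par, m, eps),
                               V0 = 1, I0 = 0)$establishment
    }, numeric(1))
    expect_lte(est[["reduce_gamma"]], est[["reduce_p"]] + 1e-12)
    expect_lte(est[["reduce_gamma"]], est[["reduce_beta"]] + 1e-12)
    modes_def <- vapply(c("reduce_gamma", "reduce_p", "reduce_beta"),
      function(m) {
        pe <- apply_antiviral(par, m, eps)
        pe$gamma * pe$p * pe$tau_I > 1
      }, logical(1))
    if (all(modes_def)) {
      fr <- vapply(c("reduce_gamma", "reduce_p", "reduce_beta"), function(m) {
        fraction_consumed(apply_antiviral(par, m, eps), V0 = 1, I0 = 0)
      }, numeric(1))
      expect_lte(fr[["reduce_gamma"]], fr[["reduce_p"]] + 1e-12)
      expect_lte(fr[["reduce_gamma"]], fr[["reduce_beta"]] + 1e-12)
    }
  }
})

test_that("for cell-initiated infections gamma and p modes are equivalent", {
  p2 <- baseline(V0 = 0L, I0 = 1L, n_I = 3L)
  for (eps in c(0.1, 0.45, 0.8)) {
    eg <- extinction_prob_inoculum(apply_antiviral(p2, "reduce_gamma", eps),
                                   V0 = 0, I0 = 1)$establishment
    ep <- extinction_prob_inoculum(apply_antiviral(p2, "reduce_p", eps),
                                   V0 = 0, I0 = 1)$establishment
    eb <- extinction_prob_inoculum(apply_antiviral(p2, "reduce_beta", eps),
                                   V0 = 0, I0 = 1)$establishment
    expect_equal(eg, ep, tolerance = 1e-10)
    expect_lte(eg, eb + 1e-12)
  }
})

test_that("establishment is non-decreasingly suppressed by efficacy in every mode", {
  par <- baseline(n_I = 7L)
  grid <- seq(0, 0.9, by = 0.05)
  for (mode in c("reduce_p", "reduce_beta", "reduce_gamma")) {
    pext <- vapply(grid, function(eps) {
      extinction_prob_single_virion(apply_antiviral(par, mode, eps))
    }, numeric(1))
    expect_true(all(diff(pext) >= -1e-12))
  }
})
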