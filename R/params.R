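#' Infection parameter set
#'
#' Construct and validate the full parameterization of the within-host
#' infection model shared by the analytic, stochastic and mean-field layers.
#' Target cells are lost to productive infection at rate `gamma * beta * T *
#' V / s`; infected cells traverse an Erlang-staged eclipse phase (shape
#' `n_E`, mean `tau_E`) and infectious phase (shape `n_I`, mean `tau_I`)
#' during which they produce infectious virions at rate `p`; virions are lost
#' to infectivity decay at rate `c` and to irreversible cell entry at rate
#' `beta * T / s`.
#'
#' Instead of `beta`, the basic reproduction number `R0` may be supplied, in
#' which case the entry-rate coefficient is recovered from
#' `beta = (c * R0 / tau_I) / (N_cells * (p - R0 / tau_I))`,
#' the parameterization under which published SARS-CoV-2 within-host values
#' are usually quoted (Czuppon et al. 2021, PLOS Comput Biol 17:e1008752).
#'
#' Units are fixed: hours for rates and durations, mL for the volume `s`,
#' counts for cells and virions.
#'
#' @param p Virion production rate, infectious virions (IV) per cell per hour.
#' @param c Rate of virion infectivity loss, per hour.
#' @param tau_E,tau_I Mean eclipse / infectious phase durations, hours.
#' @param N_cells Initial number of susceptible target cells (integer >= 1).
#' @param beta Entry-rate coefficient, mL per cell per hour (the per-virion
#'   entry rate is `beta * T / s`). Exactly one of `beta`, `R0` must be given.
#' @param R0 Basic reproduction number used to derive `beta` (see Details).
#' @param gamma Probability in (0, 1] that a virion entry yields a productive
#'   cell infection.
#' @param n_E,n_I Erlang shape parameters (integers >= 1) of the eclipse and
#'   infectious phase duration distributions.
#' @param s System volume, mL.
#' @param V0,I0 Initial numbers of infectious virions and infectious cells
#'   (non-negative integers).
#'
#' @return An object of class `infection_params`: a named list with fields
#'   `beta`, `p`, `c`, `gamma`, `tau_E`, `tau_I`, `n_E`, `n_I`, `N_cells`,
#'   `s`, `V0`, `I0`.
#'
#' @examples
#' par <- infection_params(
#'   p = 11.2 / 24, c = 10 / 24, tau_E = 24 / 5, tau_I = 24 / 0.595,
#'   N_cells = 4e4, R0 = 7.69
#' )
#' summary(par)
#' @seealso [derive_quantities()], [apply_antiviral()], [simulate_infection()]
#' @export
infection_params <- function(p, c, tau_E, tau_I, N_cells,
                             beta = NULL, R0 = NULL, gamma = 1,
                             n_E = 1L, n_I = 1L, s = 1, V0 = 1L, I0 = 0L) {
  if (is.null(beta) == is.null(R0)) {
    stop("exactly one of `beta` or `R0` must be supplied", call. = FALSE)
  }
  check_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("`%s` must be a single finite positive number", nm),
           call. = FALSE)
    }
  }
  check_count <- function(x, nm, min = 0L) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x != round(x) || x < min) {
      stop(sprintf("`%s` must be an integer >= %d", nm, min), call. = FALSE)
    }
  }
  check_pos(p, "p"); check_pos(c, "c")
  check_pos(tau_E, "tau_E"); check_pos(tau_I, "tau_I"); check_pos(s, "s")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0 || gamma > 1) {
    stop("`gamma` must lie in (0, 1]", call. = FALSE)
  }
  check_count(n_E, "n_E", 1L); check_count(n_I, "n_I", 1L)
  check_count(N_cells, "N_cells", 1L)
  check_count(V0, "V0"); check_count(I0, "I0")

  if (is.null(beta)) {
    check_pos(R0, "R0")
    if (p - R0 / tau_I <= 0) {
      stop("`R0` too large for these `p`, `tau_I`: requires p > R0/tau_I",
           call. = FALSE)
    }
    beta <- (c * R0 / tau_I) / (N_cells * (p - R0 / tau_I))
  }
  check_pos(beta, "beta")

  structure(
    list(beta = beta, p = p, c = c, gamma = gamma,
         tau_E = tau_E, tau_I = tau_I,
         n_E = as.integer(n_E), n_I = as.integer(n_I),
         N_cells = as.integer(N_cells), s = s,
         V0 = as.integer(V0), I0 = as.integer(I0)),
    class = "infection_params"
  )
}

#' @export
print.infection_params <- function(x, digits = 4, ...) {
  cat("Within-host infection parameters\n")
  cat(sprintf("  entry rate coeff   beta = %.*g mL/cell/h\n", digits, x$beta))
  cat(sprintf("  production rate    p    = %.*g IV/cell/h\n", digits, x$p))
  cat(sprintf("  infectivity loss   c    = %.*g /h\n", digits, x$c))
  cat(sprintf("  post-entry success gamma= %.*g cell/IV\n", digits, x$gamma))
  cat(sprintf("  eclipse phase      tau_E= %.*g h (Erlang shape n_E = %d)\n",
              digits, x$tau_E, x$n_E))
  cat(sprintf("  infectious phase   tau_I= %.*g h (Erlang shape n_I = %d)\n",
              digits, x$tau_I, x$n_I))
  cat(sprintf("  cells / volume     N_cells = %d, s = %.*g mL\n",
              x$N_cells, digits, x$s))
  cat(sprintf("  inoculum           V0 = %d IV, I0 = %d cells\n", x$V0, x$I0))
  invisible(x)
}

#' Derived infection quantities
#'
#' Quantities derived from an [infection_params] set: the mean burst size
#' `B = p * tau_I`; the loss-to-entry ratio `ratio = c / (beta * N_cells /
#' s)`; the probability `P_VI = gamma / (1 + ratio)` that a single virion in a
#' fully susceptible population causes a productive cell infection; the basic
#' reproduction number `R0 = B * P_VI`; and the critical uninfected fraction
#' `Tstar_frac = ratio / (gamma * p * tau_I - 1)`, the fraction of cells still
#' uninfected at which the running reproduction number crosses 1.
#' `Tstar_frac` only exists when `gamma * p * tau_I > 1`; otherwise it is
#' returned as `NA` with `Tstar_defined = FALSE`.
#'
#' @param params An [infection_params] object.
#' @return An object of class `infection_derived`: list with `B`, `ratio`,
#'   `P_VI`, `R0`, `Tstar_frac`, `Tstar_defined`.
#' @examples
#' par <- sars2_baseline_params()
#' derive_quantities(par)$R0  # 7.69
#' @export
derive_quantities <- function(params) {
  stopifnot(inherits(params, "infection_params"))
  B <- params$p * params$tau_I
  ratio <- params$c / (params$beta * params$N_cells / params$s)
  P_VI <- params$gamma / (1 + ratio)
  R0 <- B * P_VI
  gpt <- params$gamma * params$p * params$tau_I
  defined <- gpt > 1
  Tstar <- if (defined) ratio / (gpt - 1) else NA_real_
  structure(
    list(B = B, ratio = ratio, P_VI = P_VI, R0 = R0,
         Tstar_frac = Tstar, Tstar_defined = defined),
    class = "infection_derived"
  )
}

#' @export
print.infection_derived <- function(x, digits = 6, ...) {
  cat("Derived infection quantities\n")
  cat(sprintf("  burst size            B       = %.*g IV/cell\n", digits, x$B))
  cat(sprintf("  loss-to-entry ratio   c/(bN/s)= %.*g\n", digits, x$ratio))
  cat(sprintf("  P(virion -> infection) P_VI   = %.*g\n", digits, x$P_VI))
  cat(sprintf("  basic reproduction    R0      = %.*g\n", digits, x$R0))
  if (x$Tstar_defined) {
    cat(sprintf("  critical fraction     T*/N    = %.*g\n", digits,
                x$Tstar_frac))
  } else {
    cat("  critical fraction     T*/N    = undefined (gamma*p*tau_I <= 1)\n")
  }
  invisible(x)
}

#' @export
summary.infection_params <- function(object, ...) derive_quantities(object)

#' Antiviral intervention
#'
#' A prophylactic antiviral mode of action and efficacy. The three modes
#' multiply one parameter by `(1 - efficacy)`: `"reduce_beta"` lowers the
#' virus entry rate (e.g. entry/attachment inhibitors), `"reduce_p"` lowers
#' the virion production rate (e.g. protease inhibitors), and
#' `"reduce_gamma"` lowers the probability of productive infection after
#' entry (e.g. endosomal fusion inhibitors, reverse transcriptase
#' inhibitors).
#'
#' @param mode One of `"reduce_beta"`, `"reduce_p"`, `"reduce_gamma"`.
#' @param efficacy Efficacy in `[0, 1)`; 1 is rejected since it would zero a
#'   rate.
#' @return Object of class `antiviral`.
#' @examples
#' apply_antiviral(sars2_baseline_params(), antiviral("reduce_p", 0.5))
#' @export
antiviral <- function(mode = c("reduce_beta", "reduce_p", "reduce_gamma"),
                      efficacy) {
  mode <- match.arg(mode)
  if (!is.numeric(efficacy) || length(efficacy) != 1L ||
      !is.finite(efficacy) || efficacy < 0 || efficacy >= 1) {
    stop("`efficacy` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(mode = mode, efficacy = efficacy), class = "antiviral")
}

#' @export
print.antiviral <- function(x, ...) {
  cat(sprintf("Antiviral: %s at efficacy %.4g\n", x$mode, x$efficacy))
  invisible(x)
}

#' Apply an antiviral to a parameter set
#'
#' Returns a copy of `params` with exactly one of `beta`, `p` or `gamma`
#' multiplied by `(1 - efficacy)` according to the intervention's mode; all
#' other fields are untouched. Two successive applications of the same mode
#' compose into a single application with combined efficacy
#' `1 - (1 - e1) * (1 - e2)`.
#'
#' @param params An [infection_params] object.
#' @param iv An [antiviral] object, or a mode string combined with `efficacy`.
#' @param efficacy Efficacy, used when `iv` is given as a mode string.
#' @return A modified `infection_params` object.
#' @export
apply_antiviral <- function(params, iv, efficacy = NULL) {
  stopifnot(inherits(params, "infection_params"))
  if (is.character(iv)) iv <- antiviral(iv, efficacy)
  stopifnot(inherits(iv, "antiviral"))
  f <- 1 - iv$efficacy
  out <- params
  switch(iv$mode,
    reduce_beta  = { out$beta  <- params$beta  * f },
    reduce_p     = { out$p     <- params$p     * f },
    reduce_gamma = { out$gamma <- params$gamma * f }
  )
  out
}

#' Efficacy achieving a target critical uninfected fraction
#'
#' Solve for the antiviral efficacy at which the critical uninfected fraction
#' `T*/N_cells = ratio / (gamma * p * tau_I - 1)` equals `target`. For modes
#' acting on `p` or `gamma` the solution is closed-form,
#' `(1 - eps) * gamma * p * tau_I = ratio / target + 1`; for the entry-rate
#' mode, `(1 - eps) = ratio / (target * (gamma * p * tau_I - 1))`. Published
#' whole-percent efficacies are rounded versions of these exact conditions;
#' use this helper when a figure-exact condition such as `T*/N = 0.5` is
#' required.
#'
#' @param params An [infection_params] object with `gamma * p * tau_I > 1`.
#' @param mode Antiviral mode of action (see [antiviral()]).
#' @param target Target value of `T*/N_cells`, > current value.
#' @return The efficacy (scalar in `[0, 1)`).
#' @examples
#' efficacy_for_critical_fraction(sars2_baseline_params(), "reduce_p", 0.5)
#' @export
efficacy_for_critical_fraction <- function(params, mode, target) {
  stopifnot(inherits(params, "infection_params"),
            is.numeric(target), length(target) == 1L,
            target > 0, target < Inf)
  d <- derive_quantities(params)
  if (!d$Tstar_defined) {
    stop("T*/N_cells undefined at these parameters (gamma*p*tau_I <= 1)",
         call. = FALSE)
  }
  mode <- match.arg(mode, c("reduce_beta", "reduce_p", "reduce_gamma"))
  gpt <- params$gamma * params$p * params$tau_I
  one_minus_eps <- if (mode == "reduce_beta") {
    d$ratio / (target * (gpt - 1))
  } else {
    (d$ratio / target + 1) / gpt
  }
  if (one_minus_eps <= 0 || one_minus_eps > 1) {
    stop("target critical fraction not reachable with this mode", call. = FALSE)
  }
  1 - one_minus_eps
}
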