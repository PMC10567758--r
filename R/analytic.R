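#' Probability that a single virion causes a productive cell infection
#'
#' In a fully susceptible cell population a virion is lost either to
#' infectivity decay (rate `c`) or to irreversible cell entry (rate
#' `beta * N_cells / s`); an entry is productive with probability `gamma`.
#' Racing the two loss routes gives
#' `P_VI = gamma / (1 + c / (beta * N_cells / s))`.
#'
#' @param params An [infection_params] object.
#' @return Probability in (0, 1].
#' @examples
#' prob_virion_infects(sars2_baseline_params())  # 0.409
#' @export
prob_virion_infects <- function(params) {
  derive_quantities(params)$P_VI
}

#' Burst size probability mass function
#'
#' The total number of infectious virions produced by one infectious cell
#' over its lifespan. Poisson production at rate `p` over an
#' Erlang(`n_I`, mean `tau_I`) lifespan marginalizes to a negative binomial
#' law `NB(m | r = n_I, prob of success B/(n_I + B))` with mean burst size
#' `B = p * tau_I`. For `n_I = 1` this is geometric; as `n_I` grows it tends
#' to Poisson(`B`).
#'
#' @param m Vector of non-negative integer burst sizes.
#' @param params An [infection_params] object; alternatively supply `B` and
#'   `n_I` directly and leave `params` missing.
#' @param B Mean burst size (used when `params` is missing).
#' @param n_I Erlang shape of the infectious phase (used when `params` is
#'   missing).
#' @return Vector of probabilities.
#' @examples
#' burst_size_pmf(0:5, B = 11.2 / 0.595, n_I = 1)
#' @export
burst_size_pmf <- function(m, params, B = NULL, n_I = NULL) {
  if (!missing(params)) {
    stopifnot(inherits(params, "infection_params"))
    B <- params$p * params$tau_I
    n_I <- params$n_I
  }
  stopifnot(is.numeric(B), B > 0, is.numeric(n_I), n_I >= 1)
  if (any(m < 0) || any(m != round(m))) {
    stop("`m` must contain non-negative integers", call. = FALSE)
  }
  # NB with size = n_I failures and success probability B/(n_I + B);
  # stats::dnbinom's `prob` is the failure probability n_I/(n_I + B)
  stats::dnbinom(m, size = n_I, prob = n_I / (n_I + B))
}

# Root function for the single-virion extinction probability P:
#   0 = 1 - (1 - P)/P_VI - [B(1 - P)/n_I + 1]^(-n_I)
ext_root_fn <- function(P, P_VI, B, n_I) {
  1 - (1 - P) / P_VI - (B * (1 - P) / n_I + 1)^(-n_I)
}

ext_root_dfn <- function(P, P_VI, B, n_I) {
  1 / P_VI - B * (B * (1 - P) / n_I + 1)^(-n_I - 1)
}

#' Extinction probability of an infection seeded by one virion
#'
#' The probability that an infection initiated with a single infectious
#' virion in a fully susceptible population dies out. It is the smallest
#' root in \[0, 1) of the branching-process fixed point
#' `P = (1 - P_VI) + P_VI * [B (1 - P)/n_I + 1]^(-n_I)`,
#' found by a bracketed root search (the trivial root at exactly 1 is
#' excluded by bracketing on `[0, 1 - 1e-9]`) and polished by Newton steps to
#' residual below 1e-13. When `R0 <= 1` extinction is certain and 1 is
#' returned without solving. For `n_I = 1` the root has the closed form
#' `1 - (R0 - 1)/B`.
#'
#' @param params An [infection_params] object.
#' @return Probability in (0, 1].
#' @export
extinction_prob_single_virion <- function(params) {
  d <- derive_quantities(params)
  if (d$R0 <= 1) return(1)
  f <- function(P) ext_root_fn(P, d$P_VI, d$B, params$n_I)
  upper <- 1 - 1e-9
  if (f(upper) <= 0) {
    # R0 barely above 1: root is within 1e-9 of 1, indistinguishable from it
    return(1)
  }
  root <- stats::uniroot(f, c(0, upper), tol = 1e-12)$root
  for (i in 1:4) { # Newton polish to near machine precision
    step <- f(root) / ext_root_dfn(root, d$P_VI, d$B, params$n_I)
    root <- root - step
  }
  if (abs(f(root)) > 1e-10) {
    stop(sprintf(
      "extinction root search failed to converge (residual %.3e at P = %.8f)",
      f(root), root), call. = FALSE)
  }
  root
}

#' Extinction probability of an infection seeded by one infectious cell
#'
#' Given the single-virion extinction probability `P_v`, the probability
#' generating function of the negative binomial burst law evaluated at `P_v`
#' gives `[B (1 - P_v)/n_I + 1]^(-n_I)`.
#'
#' @param params An [infection_params] object.
#' @return Probability in (0, 1].
#' @export
extinction_prob_single_cell <- function(params) {
  d <- derive_quantities(params)
  Pv <- extinction_prob_single_virion(params)
  (d$B * (1 - Pv) / params$n_I + 1)^(-params$n_I)
}

#' Extinction and establishment probability for a given inoculum
#'
#' Each of the `V0` initial virions and `I0` initial infectious cells founds
#' an independent lineage, so the inoculum extinction probability is the
#' product `p_ext_virion^V0 * p_ext_cell^I0` and establishment is its
#' complement.
#'
#' @param params An [infection_params] object.
#' @param V0,I0 Inoculum sizes; default to the values stored in `params`.
#' @return List of class `extinction_result` with `p_ext_virion`,
#'   `p_ext_cell`, `p_ext_inoculum`, `establishment`.
#' @examples
#' extinction_prob_inoculum(sars2_baseline_params(), V0 = 1, I0 = 0)
#' @export
extinction_prob_inoculum <- function(params, V0 = params$V0, I0 = params$I0) {
  stopifnot(V0 >= 0, I0 >= 0, V0 == round(V0), I0 == round(I0))
  pv <- extinction_prob_single_virion(params)
  pc <- extinction_prob_single_cell(params)
  pe <- pv^V0 * pc^I0
  structure(
    list(p_ext_virion = pv, p_ext_cell = pc,
         p_ext_inoculum = pe, establishment = 1 - pe),
    class = "extinction_result"
  )
}

#' @export
print.extinction_result <- function(x, digits = 6, ...) {
  cat(sprintf("P(extinction | one virion) = %.*g\n", digits, x$p_ext_virion))
  cat(sprintf("P(extinction | one cell)   = %.*g\n", digits, x$p_ext_cell))
  cat(sprintf("P(extinction | inoculum)   = %.*g\n", digits, x$p_ext_inoculum))
  cat(sprintf("P(establishment)           = %.*g\n", digits, x$establishment))
  invisible(x)
}

#' Critical fraction of cells remaining uninfected
#'
#' The uninfected fraction `T*/N_cells = ratio / (gamma * p * tau_I - 1)` at
#' which the running reproduction number `R(t)` crosses 1: past this point
#' the infectious cell population peaks and declines. It controls the final
#' size of established infections. Requires `gamma * p * tau_I > 1`;
#' otherwise there is no interior critical point and an error is raised.
#'
#' @param params An [infection_params] object.
#' @return The fraction (scalar in (0, Inf); meaningful final-size behaviour
#'   requires values below 1).
#' @export
critical_fraction_uninfected <- function(params) {
  d <- derive_quantities(params)
  if (!d$Tstar_defined) {
    stop("no interior critical point: gamma * p * tau_I <= 1", call. = FALSE)
  }
  d$Tstar_frac
}

#' Principal branch of the Lambert W function
#'
#' Solves `w * exp(w) = x` for `w >= -1`, defined for `x >= -1/e`. Thin
#' validated wrapper with a residual guarantee of 1e-12.
#'
#' @param x Numeric vector with all elements `>= -1/e`.
#' @return `w` such that `w * exp(w) = x`.
#' @examples
#' lambert_w0(c(0, exp(1)))  # 0, 1
#' @export
lambert_w0 <- function(x) {
  if (any(!is.finite(x)) || any(x < -exp(-1))) {
    stop("lambert_w0 requires finite x >= -1/e", call. = FALSE)
  }
  w <- vapply(x, pracma::lambertWp, numeric(1))
  bad <- abs(w * exp(w) - x) > 1e-12
  if (any(bad)) { # one Halley step as a safety polish near the branch point
    for (i in which(bad)) {
      wi <- w[i]
      ew <- exp(wi)
      f <- wi * ew - x[i]
      wi <- wi - f / (ew * (wi + 1) - (wi + 2) * f / (2 * wi + 2))
      w[i] <- wi
    }
  }
  w
}

#' Fraction of cells consumed by an established infection
#'
#' Closed-form final size of the mean-field model, which approximates the
#' median consumed fraction among established stochastic runs. With
#' `Tf = T*/N_cells`,
#' `1 - T(Inf)/N = 1 + Tf * W0( -exp(-1/Tf)/Tf * exp(-gamma*(beta/s)*(V0 + p*tau_I*I0)/c) )`.
#' An inoculum of infectious cells enters through the substitution
#' `V0 -> V0 + p * tau_I * I0`. In the limit of a vanishing inoculum the
#' expression depends on `Tf` alone, and for `Tf << 1` it approaches
#' `1 - exp(-1/Tf)`.
#'
#' @param params An [infection_params] object with `gamma * p * tau_I > 1`.
#' @param V0,I0 Inoculum; defaults taken from `params`.
#' @return Fraction of `N_cells` consumed, in (0, 1).
#' @export
fraction_consumed <- function(params, V0 = params$V0, I0 = params$I0) {
  Tf <- critical_fraction_uninfected(params)
  inoc <- params$gamma * (params$beta / params$s) *
    (V0 + params$p * params$tau_I * I0) / params$c
  arg <- -exp(-1 / Tf) / Tf * exp(-inoc)
  if (arg < -exp(-1)) {
    stop("Lambert W argument below -1/e; invalid parameter combination",
         call. = FALSE)
  }
  1 + Tf * lambert_w0(arg)
}

#' Reproduction number along the infection course
#'
#' The running reproduction number as a function of the uninfected fraction
#' `T(t)/N_cells`, written purely in terms of `R0` and the critical fraction
#' `Tstar_frac`:
#' `R = R0 * Tf_t * (1 - Tstar) / (Tstar * (R0 - 1) + Tf_t * (1 - R0 * Tstar))`
#' with `Tf_t = T(t)/N_cells`. It equals `R0` at `Tf_t = 1`, crosses 1 at
#' `Tf_t = Tstar_frac`, and is strictly increasing in `Tf_t`.
#'
#' @param T_frac Uninfected fraction(s) in (0, 1].
#' @param R0 Basic reproduction number, > 1.
#' @param Tstar_frac Critical uninfected fraction in (0, 1).
#' @return Reproduction number(s).
#' @export
reproductive_number_at <- function(T_frac, R0, Tstar_frac) {
  if (any(T_frac <= 0) || any(T_frac > 1)) {
    stop("`T_frac` must lie in (0, 1]", call. = FALSE)
  }
  if (length(R0) != 1L || R0 < 1) stop("`R0` must be >= 1", call. = FALSE)
  if (length(Tstar_frac) != 1L || Tstar_frac <= 0 || Tstar_frac >= 1) {
    stop("`Tstar_frac` must lie in (0, 1)", call. = FALSE)
  }
  R0 * T_frac * (1 - Tstar_frac) /
    (Tstar_frac * (R0 - 1) + T_frac * (1 - R0 * Tstar_frac))
}

#' Expected number of distinct cells infected by successful virions
#'
#' Expected number of distinct cells receiving at least one of `V_suc`
#' successful virions placed uniformly at random (with replacement) among `T`
#' cells: `T * (1 - ((T - 1)/T)^V_suc)`, 0 when `T = 0`. For `V_suc << T`
#' this is approximately `V_suc`.
#'
#' @param T Number of available target cells (non-negative integer; may be
#'   real-valued >= 1 in mean-field use).
#' @param V_suc Number of successful virions (non-negative).
#' @return Expected number of newly infected cells.
#' @examples
#' expected_unique_infections(2, 2)  # 1.5
#' @export
expected_unique_infections <- function(T, V_suc) {
  stopifnot(all(T >= 0), all(V_suc >= 0))
  ifelse(T < 1, 0, T * (1 - ((T - 1) / T)^V_suc))
}
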