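#' Critical antiviral efficacy
#'
#' The efficacy at which the basic reproduction number under the antiviral
#' reaches 1, so the establishment probability reaches zero. Modes acting on
#' `p` or `gamma` scale `R0` linearly, giving the closed form
#' `1 - 1/R0`; the entry-rate mode affects numerator and denominator of
#' `P_VI` and is solved numerically.
#'
#' @param params An [infection_params] object.
#' @param mode Antiviral mode of action (see [antiviral()]).
#' @return The critical efficacy in `[0, 1)`. If `R0 <= 1` already, returns 0
#'   with a warning.
#' @examples
#' critical_efficacy(sars2_baseline_params(), "reduce_p")    # ~0.87
#' critical_efficacy(sars2_baseline_params(), "reduce_beta") # ~0.92
#' @export
critical_efficacy <- function(params, mode) {
  mode <- match.arg(mode, c("reduce_beta", "reduce_p", "reduce_gamma"))
  R0 <- derive_quantities(params)$R0
  if (R0 <= 1) {
    warning("R0 <= 1 without antiviral; critical efficacy is 0")
    return(structure(0, subcritical = TRUE))
  }
  if (mode != "reduce_beta") return(1 - 1 / R0)
  g <- function(eps) {
    derive_quantities(apply_antiviral(params, mode, eps))$R0 - 1
  }
  stats::uniroot(g, c(0, 1 - 1e-12), tol = 1e-12)$root
}

#' Efficacy halving the establishment probability
#'
#' The efficacy `eps50` at which the establishment probability of an
#' infection seeded by `V0` virions is 50% of its value without antivirals,
#' located by bisection (to `|delta eps| <= 1e-8`) between 0 and the critical
#' efficacy.
#'
#' @param params An [infection_params] object with positive establishment
#'   probability at `eps = 0`.
#' @param mode Antiviral mode of action.
#' @param V0 Inoculum size in virions (infections seeded by virions only).
#' @param I0 Inoculum size in infectious cells (default 0).
#' @return The efficacy in (0, 1).
#' @examples
#' round(100 * epsilon_50(sars2_baseline_params(), "reduce_p", V0 = 1))  # 77
#' @export
epsilon_50 <- function(params, mode, V0 = 1, I0 = 0) {
  mode <- match.arg(mode, c("reduce_beta", "reduce_p", "reduce_gamma"))
  est0 <- extinction_prob_inoculum(params, V0 = V0, I0 = I0)$establishment
  if (est0 <= 0) {
    stop("establishment probability is zero without antivirals", call. = FALSE)
  }
  target <- est0 / 2
  est_at <- function(eps) {
    extinction_prob_inoculum(apply_antiviral(params, mode, eps),
                             V0 = V0, I0 = I0)$establishment
  }
  lo <- 0
  hi <- critical_efficacy(params, mode)
  if (est_at(hi) > target) {
    stop("eps50 not bracketed below the critical efficacy", call. = FALSE)
  }
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (est_at(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Efficacy sweep of establishment and consumed fraction
#'
#' Evaluates, on a grid of efficacies for one antiviral mode, the
#' establishment probability of an inoculum (`V0` virions, `I0` infectious
#' cells), the critical uninfected fraction `T*/N_cells`, and the mean-field
#' fraction of cells consumed by established infections. Grid points at
#' which the antiviral drives `R0 <= 1` are flagged `supercritical = FALSE`;
#' there establishment is 0 and the consumed fraction undefined (`NA`).
#'
#' @param params An [infection_params] object.
#' @param mode Antiviral mode of action.
#' @param eps_grid Efficacy grid in `[0, 1)`; default 512 uniform points on
#'   `[0, 0.999]`.
#' @param V0,I0 Inoculum; defaults taken from `params`.
#' @return Data frame of class `efficacy_sweep` with columns `efficacy`,
#'   `establishment`, `Tstar_frac`, `fraction_consumed`, `supercritical`,
#'   plus attributes `mode`, `V0`, `I0`.
#' @export
efficacy_sweep <- function(params, mode,
                           eps_grid = seq(0, 0.999, length.out = 512),
                           V0 = params$V0, I0 = params$I0) {
  mode <- match.arg(mode, c("reduce_beta", "reduce_p", "reduce_gamma"))
  stopifnot(all(eps_grid >= 0), all(eps_grid < 1))
  rows <- lapply(eps_grid, function(eps) {
    pe <- apply_antiviral(params, mode, eps)
    d <- derive_quantities(pe)
    sup <- d$R0 > 1
    est <- if (sup) {
      extinction_prob_inoculum(pe, V0 = V0, I0 = I0)$establishment
    } else 0
    frac <- if (sup && d$Tstar_defined) {
      fraction_consumed(pe, V0 = V0, I0 = I0)
    } else NA_real_
    data.frame(efficacy = eps, establishment = est,
               Tstar_frac = if (d$Tstar_defined) d$Tstar_frac else NA_real_,
               fraction_consumed = frac, supercritical = sup)
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  attr(out, "V0") <- V0
  attr(out, "I0") <- I0
  class(out) <- c("efficacy_sweep", "data.frame")
  out
}

#' Table of eps50 values across modes, inoculum sizes and burst shapes
#'
#' Recomputes the efficacy at which establishment probability is halved, for
#' the three antiviral modes, inoculum sizes `V0`, and infectious-phase
#' shapes `n_I`. Values are reported in percent; the column
#' `relative_to_gamma` gives the excess over the `reduce_gamma` mode at the
#' same `n_I` and `V0`.
#'
#' @param params An [infection_params] object (its `n_I`, `V0` are ignored).
#' @param n_I_values Integer vector of infectious-phase shapes.
#' @param V0_values Integer vector of virion inoculum sizes.
#' @return Data frame with columns `mode`, `n_I`, `V0`, `eps50_percent`,
#'   `relative_to_gamma`.
#' @export
epsilon50_table <- function(params, n_I_values = c(1L, 60L),
                            V0_values = c(1L, 10L)) {
  modes <- c("reduce_gamma", "reduce_beta", "reduce_p")
  grid <- expand.grid(mode = modes, n_I = n_I_values, V0 = V0_values,
                      stringsAsFactors = FALSE)
  grid$eps50_percent <- mapply(function(mode, n_I, V0) {
    pars <- params
    pars$n_I <- as.integer(n_I)
    100 * epsilon_50(pars, mode, V0 = V0)
  }, grid$mode, grid$n_I, grid$V0)
  ref <- grid[grid$mode == "reduce_gamma", ]
  key <- paste(grid$n_I, grid$V0)
  grid$relative_to_gamma <-
    grid$eps50_percent - ref$eps50_percent[match(key, paste(ref$n_I, ref$V0))]
  grid
}
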