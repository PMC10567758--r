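#' Classify a run as extinct or established
#'
#' A finished run is `"established"` iff its consumed-cell count exceeds
#' `threshold_frac * N_cells` (strict inequality), `"extinct"` otherwise.
#' The default threshold of 0.01% of cells cleanly separates the two
#' outcome clusters whenever they are statistically distinct. Runs stopped
#' by the simulator's safety horizon are labelled `"censored"`.
#'
#' @param result A `simulation_result` (or anything with `cells_consumed`
#'   and `censored` fields), or a plain numeric count of consumed cells.
#' @param params An [infection_params] object (supplies `N_cells`).
#' @param threshold_frac Classification threshold as a fraction of
#'   `N_cells`.
#' @return `"extinct"`, `"established"` or `"censored"`.
#' @examples
#' par <- sars2_baseline_params()
#' classify_outcome(4, par)  # "extinct"   (4 <= 0.01% of 40,000)
#' classify_outcome(5, par)  # "established"
#' @export
classify_outcome <- function(result, params, threshold_frac = 1e-4) {
  if (is.numeric(result)) {
    consumed <- result
    censored <- FALSE
  } else {
    consumed <- result$cells_consumed
    censored <- isTRUE(result$censored)
  }
  if (censored) return("censored")
  if (consumed > threshold_frac * params$N_cells) "established" else "extinct"
}

pct_linear <- function(x, probs) {
  # linear interpolation between order statistics (stats::quantile type 7)
  unname(stats::quantile(x, probs, type = 7, names = FALSE))
}

#' Summarize an ensemble of stochastic runs
#'
#' Classifies each run (see [classify_outcome()]) and reports the extinction
#' frequency with its binomial standard error, an integer-binned histogram
#' of consumed cells, and the median with 2.5th/97.5th percentiles (linear
#' interpolation) of the consumed fraction among established and among
#' extinct runs. Censored runs are excluded from all frequencies with a
#' warning. When no run falls in a class its statistics are omitted
#' (`NULL`), not propagated as `NaN`.
#'
#' @param runs A `simulation_ensemble`, a list of `simulation_result`
#'   objects, or a numeric vector of consumed-cell counts.
#' @param params An [infection_params] object; defaults to the ensemble's
#'   attached parameters.
#' @param threshold_frac Classification threshold, see [classify_outcome()].
#' @param se_p Probability used for the binomial standard error
#'   `sqrt(p(1-p)/n)`. Default `"empirical"` uses the observed frequency;
#'   supply the analytic extinction probability to use the theoretical value.
#' @return Object of class `ensemble_summary`.
#' @export
summarize_ensemble <- function(runs, params = attr(runs, "params"),
                               threshold_frac = 1e-4, se_p = "empirical") {
  if (is.numeric(runs)) {
    consumed <- runs
    censored <- rep(FALSE, length(runs))
  } else {
    consumed <- vapply(runs, function(r) as.double(r$cells_consumed),
                       numeric(1))
    censored <- vapply(runs, function(r) isTRUE(r$censored), logical(1))
  }
  stopifnot(inherits(params, "infection_params"))
  if (any(censored)) {
    warning(sprintf("%d censored run(s) excluded from outcome frequencies",
                    sum(censored)))
    consumed <- consumed[!censored]
  }
  n <- length(consumed)
  if (n < 1) stop("no finished runs to summarize", call. = FALSE)
  lab <- vapply(consumed, classify_outcome, character(1),
                params = params, threshold_frac = threshold_frac)
  n_ext <- sum(lab == "extinct")
  p_hat <- n_ext / n
  p_se <- if (identical(se_p, "empirical")) p_hat else se_p
  se <- sqrt(p_se * (1 - p_se) / n)
  class_stats <- function(x) {
    if (length(x) == 0) return(NULL)
    frac <- x / params$N_cells
    list(n = length(x),
         median = pct_linear(frac, 0.5),
         lower95 = pct_linear(frac, 0.025),
         upper95 = pct_linear(frac, 0.975),
         median_cells = pct_linear(x, 0.5))
  }
  structure(
    list(n_runs = n,
         n_censored = sum(censored),
         extinction_frequency = p_hat,
         extinction_se = se,
         histogram = table(consumed),
         established = class_stats(consumed[lab == "established"]),
         extinct = class_stats(consumed[lab == "extinct"]),
         threshold_frac = threshold_frac),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Ensemble summary over %d runs", x$n_runs))
  if (x$n_censored > 0) cat(sprintf(" (+%d censored)", x$n_censored))
  cat("\n")
  cat(sprintf("  extinction frequency: %.*f (binomial SE %.*f)\n",
              digits, x$extinction_frequency, digits, x$extinction_se))
  for (cls in c("established", "extinct")) {
    st <- x[[cls]]
    if (is.null(st)) {
      cat(sprintf("  %s runs: none\n", cls))
    } else {
      cat(sprintf(
        "  %s runs (n = %d): median consumed fraction %.*f [%.*f, %.*f]\n",
        cls, st$n, digits, st$median, digits, st$lower95, digits,
        st$upper95))
    }
  }
  invisible(x)
}
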