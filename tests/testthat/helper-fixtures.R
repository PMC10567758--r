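# Shared fixtures: the published SARS-CoV-2 baseline and antiviral scenarios
# defined by their exact critical-fraction condition.

baseline <- function(...) sars2_baseline_params(...)

# production-rate antiviral tuned so that T*/N_cells equals `tf`
tstar_setting <- function(tf, par = baseline()) {
  apply_antiviral(par, "reduce_p",
                  efficacy_for_critical_fraction(par, "reduce_p", tf))
}

# independent oracle: fixed-point iteration of the extinction relation with
# the negative binomial burst sum truncated at cumulative mass 1 - 1e-12
ext_fixed_point_oracle <- function(params, iter = 5000) {
  d <- derive_quantities(params)
  nI <- params$n_I
  pr <- nI / (nI + d$B)
  m_max <- stats::qnbinom(1 - 1e-12, size = nI, prob = pr)
  pmf <- stats::dnbinom(0:m_max, size = nI, prob = pr)
  P <- 0.5
  for (i in seq_len(iter)) {
    P <- (1 - d$P_VI) + d$P_VI * sum(pmf * P^(0:m_max))
  }
  P
}
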