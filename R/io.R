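#' Baseline SARS-CoV-2 within-host parameter set
#'
#' The published within-host SARS-CoV-2 parameter values of Czuppon et al.
#' (2021, PLOS Comput Biol 17:e1008752): production rate `p = 11.2/24`
#' IV/cell/h, infectivity loss `c = 10/24` /h, eclipse mean `tau_E = 24/5` h,
#' infectious mean `tau_I = 24/0.595` h, `N_cells = 4e4` susceptible cells in
#' `s = 1` mL, exponential phase durations (`n_E = n_I = 1`), full post-entry
#' success (`gamma = 1`) and the entry rate fixed from `R0 = 7.69`. The
#' default inoculum is a single infectious virion.
#'
#' @param ... Overrides passed to [infection_params()] (e.g. `n_I = 60`,
#'   `V0 = 10`).
#' @return An [infection_params] object.
#' @examples
#' derive_quantities(sars2_baseline_params())
#' @export
sars2_baseline_params <- function(...) {
  defaults <- list(p = 11.2 / 24, c = 10 / 24, tau_E = 24 / 5,
                   tau_I = 24 / 0.595, N_cells = 4e4, R0 = 7.69,
                   gamma = 1, n_E = 1L, n_I = 1L, s = 1, V0 = 1L, I0 = 0L)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop("unknown parameter override(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(over)] <- over
  do.call(infection_params, defaults)
}

config_param_keys <- c("beta", "R0", "p", "c", "gamma", "tau_E", "tau_I",
                       "n_E", "n_I", "N_cells", "s", "V0", "I0")
config_extra_keys <- c("antiviral_mode", "antiviral_efficacy",
                       "P_events", "max_time", "seed")

#' Load a run configuration
#'
#' Reads a flat YAML configuration naming the infection parameters (either
#' `beta` or `R0`, mutually exclusive), an optional antiviral intervention
#' (`antiviral_mode`, `antiviral_efficacy`), and optional simulator settings
#' (`P_events`, `max_time`, `seed`). Unknown keys are rejected by name;
#' validation errors name the offending field. Units: hours, mL, counts.
#'
#' @param path Path to a YAML file, or a preset name (see
#'   [list_config_presets()]).
#' @return List of class `run_config` with elements `params`
#'   ([infection_params]), `antiviral` ([antiviral] or `NULL`), `config`
#'   ([simulator_config]) and `seed` (or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    preset <- system.file("extdata", "presets", paste0(path, ".yaml"),
                          package = "virofate")
    if (preset == "") stop("config file not found: ", path, call. = FALSE)
    path <- preset
  }
  raw <- yaml::yaml.load_file(path)
  if (is.null(raw)) raw <- list()
  known <- c(config_param_keys, config_extra_keys)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  required <- c("p", "c", "tau_E", "tau_I", "N_cells")
  missing <- setdiff(required, names(raw))
  if (!any(c("beta", "R0") %in% names(raw))) {
    missing <- c(missing, "beta (or R0)")
  }
  if (length(missing)) {
    stop("missing required config key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (all(c("beta", "R0") %in% names(raw))) {
    stop("`beta` and `R0` are mutually exclusive", call. = FALSE)
  }
  par_args <- raw[intersect(names(raw), config_param_keys)]
  params <- do.call(infection_params, par_args)
  av <- NULL
  if (!is.null(raw$antiviral_mode)) {
    if (is.null(raw$antiviral_efficacy)) {
      stop("`antiviral_efficacy` required with `antiviral_mode`",
           call. = FALSE)
    }
    av <- antiviral(raw$antiviral_mode, raw$antiviral_efficacy)
  } else if (!is.null(raw$antiviral_efficacy)) {
    stop("`antiviral_mode` required with `antiviral_efficacy`",
         call. = FALSE)
  }
  sim <- simulator_config(
    P_events = if (is.null(raw$P_events)) 0.05 else raw$P_events,
    max_time = if (is.null(raw$max_time)) 1e4 else raw$max_time
  )
  structure(list(params = params, antiviral = av, config = sim,
                 seed = raw$seed),
            class = "run_config")
}

#' Save a run configuration
#'
#' Writes a `run_config` back to flat YAML; `save_config(load_config(f))`
#' round-trips all values.
#'
#' @param cfg A `run_config` from [load_config()], or an [infection_params]
#'   object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  if (inherits(cfg, "infection_params")) {
    cfg <- structure(list(params = cfg, antiviral = NULL,
                          config = simulator_config(), seed = NULL),
                     class = "run_config")
  }
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg$params)
  if (!is.null(cfg$antiviral)) {
    out$antiviral_mode <- cfg$antiviral$mode
    out$antiviral_efficacy <- cfg$antiviral$efficacy
  }
  out$P_events <- cfg$config$P_events
  out$max_time <- cfg$config$max_time
  if (!is.null(cfg$seed)) out$seed <- cfg$seed
  yaml::write_yaml(out, path)
  invisible(path)
}

#' List packaged configuration presets
#'
#' @return Character vector of preset names usable with [load_config()].
#' @export
list_config_presets <- function() {
  dir <- system.file("extdata", "presets", package = "virofate")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' Effective parameters of a run configuration
#'
#' Applies the configured antiviral (if any) to the configured parameters.
#'
#' @param cfg A `run_config`.
#' @return An [infection_params] object.
#' @export
effective_params <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$antiviral)) cfg$params
  else apply_antiviral(cfg$params, cfg$antiviral)
}

# FNV-1a hash of a serialized object; cheap provenance fingerprint for
# CLI output headers.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(h, b)) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

provenance <- function(cfg = NULL, seed = NULL) {
  list(package = "virofate",
       version = as.character(utils::packageVersion("virofate")),
       config_hash = if (is.null(cfg)) NA_character_ else config_hash(cfg),
       seed = if (is.null(seed)) NA_integer_ else seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Recompute the headline comparison tables
#'
#' Recomputes, from the baseline parameter set, (i) the efficacies at which
#' each antiviral mode halves the establishment probability
#' ([epsilon50_table()]); and (ii) the theoretical extinction probability
#' and final consumed fraction for a ladder of antiviral scenarios defined
#' by their exact critical-fraction condition (`T*/N_cells` in 0.5, 0.6,
#' 0.7, 0.85 under a production-rate antiviral) plus an entry-rate antiviral
#' at the efficacy where its establishment probability equals that of the
#' production-rate antiviral. With `n_runs > 0`, scaled-down stochastic
#' ensembles are run per scenario and reported side by side with absolute
#' errors.
#'
#' @param params Baseline [infection_params]; defaults to
#'   [sars2_baseline_params()].
#' @param n_runs Stochastic runs per scenario (0 = analytic columns only).
#' @param seed Master seed for the ensembles.
#' @return List with data frames `eps50` and `scenarios`.
#' @export
reproduce_tables <- function(params = sars2_baseline_params(),
                             n_runs = 0, seed = 1) {
  eps50 <- epsilon50_table(params)

  tf_targets <- c(0.5, 0.6, 0.7, 0.85)
  scen <- lapply(tf_targets, function(tf) {
    eps <- efficacy_for_critical_fraction(params, "reduce_p", tf)
    list(label = sprintf("reduce_p, T*/N = %.2f", tf),
         params = apply_antiviral(params, "reduce_p", eps), efficacy = eps)
  })
  # entry-rate antiviral at the efficacy where its establishment equals the
  # production-rate antiviral's (the crossing of the two modes)
  cross <- stats::uniroot(function(eps) {
    eb <- extinction_prob_inoculum(
      apply_antiviral(params, "reduce_beta", eps))$establishment
    ep <- extinction_prob_inoculum(
      apply_antiviral(params, "reduce_p", eps))$establishment
    eb - ep
  }, c(0.5, critical_efficacy(params, "reduce_p") - 1e-6), tol = 1e-10)$root
  scen[[length(scen) + 1]] <- list(
    label = sprintf("reduce_beta, equal-establishment (eps = %.4f)", cross),
    params = apply_antiviral(params, "reduce_beta", cross), efficacy = cross)

  rows <- lapply(scen, function(sc) {
    p_ext <- extinction_prob_inoculum(sc$params)$p_ext_inoculum
    frac <- fraction_consumed(sc$params)
    row <- data.frame(scenario = sc$label, efficacy = sc$efficacy,
                      p_extinction_theory = p_ext,
                      consumed_fraction_theory = frac)
    if (n_runs > 0) {
      runs <- simulate_ensemble(sc$params, n_runs, seed)
      sm <- summarize_ensemble(runs, sc$params, se_p = p_ext)
      row$p_extinction_sim <- sm$extinction_frequency
      row$p_extinction_abs_error <- abs(sm$extinction_frequency - p_ext)
      med <- if (is.null(sm$established)) NA_real_ else sm$established$median
      row$consumed_fraction_sim <- med
      row$consumed_fraction_abs_error <- abs(med - frac)
    }
    row
  })
  list(eps50 = eps50, scenarios = do.call(rbind, rows))
}
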