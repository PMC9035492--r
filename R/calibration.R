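## Model calibration: free-parameter selection, objective construction,
## and the NSGA-II driver.

## Resolve a free-parameter name to its slot (printed or supplementary).
.get_param <- function(p, name) {
  if (name %in% names(p$printed)) return(p$printed[[name]])
  supp_rate(p, name)
}

.set_param <- function(p, name, value) {
  if (name %in% names(p$printed)) {
    p$printed[[name]] <- value
  } else {
    supp_rate(p, name)  # fail loudly on unknown names
    p$supplementary_rates[[name]] <- value
  }
  p
}

#' Default calibration bounds
#'
#' Ten-fold bounds around the nominal value of each free parameter, on a
#' log10 scale (the genome lives in log-parameter space, making the
#' search scale-invariant across rate constants that span orders of
#' magnitude).
#'
#' @param p A [parameter_set()] supplying nominal values.
#' @param free_names Parameters to calibrate.
#' @param fold Half-width of the box as a fold change (default 10).
#' @return Two-column matrix of log10 lower/upper bounds, rownames =
#'   `free_names`.
#' @export
calibration_bounds <- function(p, free_names, fold = 10) {
  nominal <- vapply(free_names, .get_param, numeric(1), p = p)
  if (any(nominal <= 0)) {
    stop("free parameters must have positive nominal values: ",
         paste(free_names[nominal <= 0], collapse = ", "), call. = FALSE)
  }
  cbind(lower = log10(nominal / fold), upper = log10(nominal * fold))
}

#' Build the discrepancy objectives for calibration
#'
#' Returns an objective function mapping a genome (log10 values of the
#' free parameters) to one discrepancy per observed population: the sum
#' of squared standardized log-residuals
#' `((log(sim + 1) - log(obs + 1)) / sigma)^2` over sample days, where
#' `sigma = sqrt(log(1 + cv^2))` is the log-scale standard deviation of
#' the observation noise (1 when the CV is 0 or unknown). Log residuals
#' match the multiplicative noise model and weigh each population's
#' trajectory on its own scale. A failed simulation propagates as an
#' error, which [nsga2_evolve()] converts to a dominated sentinel.
#'
#' @param observations An `observation_set`.
#' @param free_names Names of the calibrated parameters.
#' @param p_base A [parameter_set()] providing all fixed values.
#' @param schedule Schedule under which the observations were collected
#'   (default: the observation set's own truth schedule, else no dose).
#' @return Function `genome -> numeric vector` (one objective per
#'   observed population).
#' @export
model_objectives <- function(observations, free_names, p_base,
                             schedule = NULL) {
  stopifnot(inherits(observations, "observation_set"))
  if (!nrow(observations$values)) stop("empty observations", call. = FALSE)
  for (nm in free_names) .get_param(p_base, nm)  # validate names
  if (is.null(schedule)) {
    schedule <- observations$truth$schedule
    if (is.null(schedule)) schedule <- no_dose_schedule()
  }
  cv <- observations$noise_cv
  sigma <- if (is.na(cv) || cv <= 0) 1 else sqrt(log(1 + cv^2))
  days <- observations$sample_days
  vars <- observations$observed_names
  horizon <- max(days) + 1
  log_obs <- log(observations$values + 1)

  function(genome) {
    p <- p_base
    for (i in seq_along(free_names)) {
      p <- .set_param(p, free_names[i], 10^genome[i])
    }
    sim <- observe_trajectory(p, schedule, days, vars, horizon)
    colSums(((log(sim + 1) - log_obs) / sigma)^2)
  }
}

#' Calibrate free parameters against observations
#'
#' Runs [nsga2_evolve()] on [model_objectives()] with log10-scale
#' ten-fold bounds around the nominal values, and reports the Pareto
#' front on the natural parameter scale.
#'
#' @inheritParams model_objectives
#' @param cfg A [ga_config()].
#' @param fold Bound half-width (fold change around nominal).
#' @return List with `front` (data frame: one row per rank-0 genome,
#'   free-parameter columns on the natural scale plus one objective
#'   column per observed population) and `result` (the raw
#'   [nsga2_evolve()] output).
#' @export
calibrate <- function(observations, free_names, p_base, cfg = ga_config(),
                      schedule = NULL, fold = 10) {
  fn <- model_objectives(observations, free_names, p_base, schedule)
  bounds <- calibration_bounds(p_base, free_names, fold)
  res <- nsga2_evolve(fn, bounds, cfg)
  front <- as.data.frame(10^res$pareto$genomes)
  names(front) <- free_names
  objs <- as.data.frame(res$pareto$objectives)
  names(objs) <- paste0("obj_", observations$observed_names)
  list(front = cbind(front, objs), result = res)
}
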