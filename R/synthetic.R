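## Ground-truth-known synthetic observations for calibration and
## pipeline testing.

#' Generate noisy longitudinal observations from a known model
#'
#' Simulates the model under a known parameter set and schedule, samples
#' the named state variables at the requested days, and applies
#' independent multiplicative lognormal noise with the given coefficient
#' of variation (CV): each observation is
#' `x * exp(rnorm(1, 0, sigma) - sigma^2/2)` with
#' `sigma^2 = log(1 + cv^2)`, so the expected value equals the
#' noise-free value and the CV equals `noise_cv`. Cell counts are
#' positive and span orders of magnitude, which is what a multiplicative
#' model captures; it does not emulate flow-cytometry gating or
#' detection limits.
#'
#' @param p A [parameter_set()] (the ground truth).
#' @param schedule A [dosing_schedule()].
#' @param sample_days Observation days within the simulation horizon.
#' @param observed_names Which state variables are observed (default all
#'   14).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (`>= 0`; 0 gives exact trajectory values).
#' @param seed Integer seed; regenerating with the same seed reproduces
#'   the values exactly.
#' @param horizon Simulation horizon (default: past the last sample day).
#' @return An `observation_set`: list with `sample_days`,
#'   `observed_names`, `values` (days x names matrix), `noise_cv`,
#'   `truth` (list of `parameters`, `schedule`), `seed`.
#' @export
generate_observations <- function(p, schedule = no_dose_schedule(),
                                  sample_days = seq(0.5, 11, length.out = 15),
                                  observed_names = state_names(),
                                  noise_cv = 0.1, seed = 1,
                                  horizon = max(sample_days) + 1) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (any(sample_days < 0) || any(sample_days > horizon)) {
    stop("sample_days must lie within [0, horizon]", call. = FALSE)
  }
  unknown <- setdiff(observed_names, STATE_NAMES)
  if (length(unknown)) {
    stop("unknown observed_names: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  clean <- observe_trajectory(p, schedule, sample_days, observed_names,
                              horizon)
  sigma <- sqrt(log(1 + noise_cv^2))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  noise <- matrix(exp(stats::rnorm(length(clean), 0, sigma) - sigma^2 / 2),
                  nrow = nrow(clean))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  values <- clean * noise
  dimnames(values) <- list(NULL, observed_names)
  structure(
    list(sample_days = sample_days, observed_names = observed_names,
         values = values, noise_cv = noise_cv,
         truth = list(parameters = p, schedule = schedule), seed = seed),
    class = "observation_set"
  )
}

## Noise-free sampled trajectory (days x observed_names matrix).
## Samples exactly at the requested days via the solver's dense output.
observe_trajectory <- function(p, schedule, sample_days, observed_names,
                               horizon) {
  days <- sort(unique(sample_days))
  tr <- simulate_model(p, schedule, horizon = horizon,
                       output_times = unique(c(0, days)))
  rows <- match(sample_days, tr$times)
  matrix(tr$states[rows, observed_names], nrow = length(sample_days),
         dimnames = list(NULL, observed_names))
}

#' @export
print.observation_set <- function(x, ...) {
  cat("<observation_set> ", length(x$sample_days), " days x ",
      length(x$observed_names), " variables, noise CV ", x$noise_cv,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Packaged ground-truth presets
#'
#' Returns the reference calibration plus a matching schedule for the
#' three study conditions: no transfer, a single graft-directed dose of
#' `C = 5e5` Tregs on POD0, and the same total split over 14 daily
#' graft-directed doses from POD0.
#'
#' @param preset One of `"untreated"`, `"single_dose_graft"`,
#'   `"multi_dose_14"`.
#' @return List with `parameters` and `schedule`.
#' @export
default_truth <- function(preset = c("untreated", "single_dose_graft",
                                     "multi_dose_14")) {
  preset <- match.arg(preset)
  p <- default_parameters()
  sched <- switch(preset,
    untreated = no_dose_schedule(),
    single_dose_graft = equal_split_schedule(5e5, 1, 0, f_G = 1),
    multi_dose_14 = equal_split_schedule(5e5, 14, 0, f_G = 1)
  )
  list(parameters = p, schedule = sched)
}

#' Write observations as long-format CSV
#'
#' One row per (day, variable); a JSON sidecar (`<path>.json`) records
#' the noise CV, seed, and the schedule of the generating truth.
#'
#' @param obs An `observation_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations_csv <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  df <- data.frame(
    day = rep(obs$sample_days, times = length(obs$observed_names)),
    variable = rep(obs$observed_names, each = length(obs$sample_days)),
    value = as.vector(obs$values)
  )
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(noise_cv = obs$noise_cv, seed = obs$seed,
               schedule = obs$truth$schedule[c("D0", "beta", "dose_days",
                                               "f_G", "f_LN", "f_N")])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read observations from long-format CSV
#'
#' @param path CSV written by [write_observations_csv()] (the sidecar is
#'   optional; without it `noise_cv` and `seed` are `NA`).
#' @return An `observation_set` without a `truth` entry.
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("day", "variable", "value")
  if (!all(need %in% names(df))) {
    stop("observations CSV must have columns day, variable, value",
         call. = FALSE)
  }
  if (any(!is.finite(df$value)) || any(df$value < 0)) {
    stop("observations contain negative or non-finite values",
         call. = FALSE)
  }
  days <- sort(unique(df$day))
  vars <- unique(df$variable)
  values <- matrix(NA_real_, length(days), length(vars),
                   dimnames = list(NULL, vars))
  for (v in vars) {
    sub <- df[df$variable == v, ]
    values[match(sub$day, days), v] <- sub$value
  }
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::fromJSON(side_path) else NULL
  structure(
    list(sample_days = days, observed_names = vars, values = values,
         noise_cv = if (is.null(side)) NA_real_ else side$noise_cv,
         truth = NULL,
         seed = if (is.null(side)) NA_integer_ else side$seed),
    class = "observation_set"
  )
}
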