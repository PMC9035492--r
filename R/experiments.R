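## Dosing-strategy experiments: parameter sweeps over the simulator
## reporting rejection time per condition.

new_sweep_result <- function(axis_name, axis_values, conditions, rejection,
                             horizon) {
  stopifnot(nrow(rejection) == length(conditions),
            ncol(rejection) == length(axis_values))
  structure(
    list(axis_name = axis_name, axis_values = axis_values,
         conditions = conditions, rejection_times = rejection,
         horizon = horizon),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> axis:", x$axis_name, "(", length(x$axis_values),
      "values ) x", length(x$conditions), "condition(s)\n")
  invisible(x)
}

#' Tidy data frame of a sweep result
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return Data frame with columns `condition`, `axis`, `axis_value`,
#'   `rejection_day` (`NA` when censored) and `censored` (no rejection
#'   within the horizon).
#' @export
as.data.frame.sweep_result <- function(x, ...) {
  data.frame(
    condition = rep(x$conditions, times = length(x$axis_values)),
    axis = x$axis_name,
    axis_value = rep(x$axis_values, each = length(x$conditions)),
    rejection_day = as.vector(x$rejection_times),
    censored = is.na(as.vector(x$rejection_times)),
    stringsAsFactors = FALSE
  )
}

.rej_for <- function(p, sched, horizon, output_step) {
  rejection_time(simulate_model(p, sched, horizon = horizon,
                                output_step = output_step))
}

#' Compare Treg accumulation sites
#'
#' Simulates a single dose of `C` activated Tregs delivered entirely to
#' the graft, entirely to the lymph node, and no transfer at all, and
#' reports the three rejection times.
#'
#' @param p A [parameter_set()].
#' @param C Dose magnitude in cells (total reaching the modeled
#'   compartments).
#' @param start_day Injection day (POD).
#' @param horizon,output_step Passed to [simulate_model()].
#' @return A `sweep_result` with conditions `graft`, `ln`, `none`.
#' @export
compare_accumulation_sites <- function(p, C = 5e5, start_day = 0,
                                       horizon = 150, output_step = 0.05) {
  if (C < 0) stop("C must be >= 0", call. = FALSE)
  scheds <- list(
    graft = if (C > 0) equal_split_schedule(C, 1, start_day, f_G = 1)
            else no_dose_schedule(),
    ln    = if (C > 0) equal_split_schedule(C, 1, start_day, f_LN = 1)
            else no_dose_schedule(),
    none  = no_dose_schedule()
  )
  rej <- vapply(scheds, .rej_for, numeric(1), p = p,
                horizon = horizon, output_step = output_step)
  new_sweep_result("site", C, names(scheds),
                   matrix(rej, ncol = 1, dimnames = list(names(scheds), NULL)),
                   horizon)
}

#' Sweep single-dose magnitude
#'
#' Rejection time as a function of the total dose `C` for graft-directed
#' and lymph-node-directed delivery of activated Tregs.
#'
#' @inheritParams compare_accumulation_sites
#' @param C_values Dose magnitudes to sweep (cells). Default: 200
#'   log-spaced points over `[1e3, 1e7]`.
#' @param sites Which delivery conditions to run (`"graft"`, `"ln"`).
#' @return A `sweep_result`, axis `dose_magnitude`.
#' @export
sweep_dose_magnitude <- function(p, sites = c("graft", "ln"), start_day = 0,
                                 C_values = 10^seq(3, 7, length.out = 200),
                                 horizon = 150, output_step = 0.05) {
  if (any(C_values < 0)) stop("C_values must be >= 0", call. = FALSE)
  sites <- match.arg(sites, c("graft", "ln"), several.ok = TRUE)
  rej <- matrix(NA_real_, nrow = length(sites), ncol = length(C_values),
                dimnames = list(sites, NULL))
  for (s in sites) {
    rej[s, ] <- vapply(C_values, function(C) {
      sched <- if (C > 0) {
        equal_split_schedule(C, 1, start_day,
                             f_G = as.numeric(s == "graft"),
                             f_LN = as.numeric(s == "ln"))
      } else no_dose_schedule()
      .rej_for(p, sched, horizon, output_step)
    }, numeric(1))
  }
  new_sweep_result("dose_magnitude", C_values, sites, rej, horizon)
}

#' Sweep single-dose timing
#'
#' Rejection time as a function of the administration day, for one or
#' more dose magnitudes delivered to the chosen site.
#'
#' @inheritParams compare_accumulation_sites
#' @param site `"graft"` or `"ln"`.
#' @param C Dose magnitude(s) in cells; one sweep curve per value.
#' @param start_days Administration days to sweep. Default: 0 to 10 in
#'   0.1-day steps.
#' @return A `sweep_result`, axis `start_day`, one condition per `C`.
#' @export
sweep_timing <- function(p, site = "graft", C = 5e5,
                         start_days = seq(0, 10, by = 0.1),
                         horizon = 150, output_step = 0.05) {
  site <- match.arg(site, c("graft", "ln"))
  if (any(start_days < 0)) stop("start_days must be >= 0", call. = FALSE)
  conds <- paste0("C=", formatC(C, format = "g"))
  rej <- matrix(NA_real_, nrow = length(C), ncol = length(start_days),
                dimnames = list(conds, NULL))
  for (i in seq_along(C)) {
    rej[i, ] <- vapply(start_days, function(t0) {
      sched <- if (C[i] > 0) {
        equal_split_schedule(C[i], 1, t0,
                             f_G = as.numeric(site == "graft"),
                             f_LN = as.numeric(site == "ln"))
      } else no_dose_schedule()
      .rej_for(p, sched, horizon, output_step)
    }, numeric(1))
  }
  new_sweep_result("start_day", start_days, conds, rej, horizon)
}

#' Sweep number of doses
#'
#' Splits a fixed total of `C` cells into `n` daily graft-directed doses
#' (via [equal_split_schedule()]) and reports rejection time per `n`,
#' one curve per start day.
#'
#' @inheritParams compare_accumulation_sites
#' @param n_values Numbers of doses to sweep (default 1 to 30).
#' @param start_day First-dose day(s); one curve per value.
#' @param f_G,f_LN,f_N Partition fractions (default all-graft).
#' @return A `sweep_result`, axis `n_doses`.
#' @export
sweep_num_doses <- function(p, C = 5e5, start_day = 0, n_values = 1:30,
                            f_G = 1, f_LN = 0, f_N = 0,
                            horizon = 150, output_step = 0.05) {
  if (any(n_values < 1)) stop("n_values must be >= 1", call. = FALSE)
  conds <- paste0("start=", start_day)
  rej <- matrix(NA_real_, nrow = length(start_day), ncol = length(n_values),
                dimnames = list(conds, NULL))
  for (i in seq_along(start_day)) {
    rej[i, ] <- vapply(n_values, function(n) {
      .rej_for(p, equal_split_schedule(C, n, start_day[i], f_G = f_G,
                                       f_LN = f_LN, f_N = f_N),
               horizon, output_step)
    }, numeric(1))
  }
  new_sweep_result("n_doses", n_values, conds, rej, horizon)
}

#' Sweep the graft-homing fraction
#'
#' Varies the fraction `f_G` of activated Tregs entering the graft; the
#' remainder (`1 - f_G`) enters the lymph node as activated Tregs
#' (`f_N = 0`). One curve per start day (single dose) or per regimen
#' when `n > 1`.
#'
#' @inheritParams compare_accumulation_sites
#' @param f_G_values Fractions in `[0, 1]` (default 0 to 1, step 0.01).
#' @param start_days One curve per start day.
#' @param n Number of daily doses (default 1).
#' @return A `sweep_result`, axis `f_G`.
#' @export
sweep_graft_fraction <- function(p, C = 5e5, start_days = 0,
                                 f_G_values = seq(0, 1, by = 0.01), n = 1,
                                 horizon = 150, output_step = 0.05) {
  if (any(f_G_values < 0 | f_G_values > 1)) {
    stop("f_G_values must lie in [0, 1]", call. = FALSE)
  }
  conds <- paste0("start=", start_days, ",n=", n)
  rej <- matrix(NA_real_, nrow = length(start_days),
                ncol = length(f_G_values), dimnames = list(conds, NULL))
  for (i in seq_along(start_days)) {
    rej[i, ] <- vapply(f_G_values, function(fg) {
      .rej_for(p, equal_split_schedule(C, n, start_days[i],
                                       f_G = fg, f_LN = 1 - fg),
               horizon, output_step)
    }, numeric(1))
  }
  new_sweep_result("f_G", f_G_values, conds, rej, horizon)
}

#' Argmax of a sweep curve
#'
#' Returns the axis value maximizing rejection time for one condition,
#' breaking ties toward the smaller axis value (the conservative
#' clinical reading: the earlier day or the fewer doses). Censored
#' entries (no rejection within the horizon) are excluded unless every
#' entry is censored, in which case the smallest censored axis value is
#' returned.
#'
#' @param sw A `sweep_result`.
#' @param condition Row name or index (default first).
#' @return List with `axis_value` and `rejection_day` (`NA` if censored).
#' @export
sweep_argmax <- function(sw, condition = 1) {
  stopifnot(inherits(sw, "sweep_result"))
  r <- sw$rejection_times[condition, ]
  if (all(is.na(r))) {
    return(list(axis_value = sw$axis_values[1], rejection_day = NA_real_))
  }
  i <- which(r == max(r, na.rm = TRUE))[1]
  list(axis_value = sw$axis_values[i], rejection_day = r[i])
}

#' Immune-dynamics report for a set of regimens
#'
#' Time courses of the graft-compartment populations that drive
#' rejection (`T_R_G`, `A_mat_G`, `T_E_G`, `A_inf`) and the two
#' instantaneous graft-destruction channels, for each supplied schedule.
#'
#' @param p A [parameter_set()].
#' @param schedules Named list of [dosing_schedule()] objects.
#' @param horizon,output_step Passed to [simulate_model()].
#' @return Tidy data frame with columns `schedule`, `time`, `variable`,
#'   `value`; variables are `T_R_G`, `A_mat_G`, `T_E_G`, `A_inf`,
#'   `by_cd8`, `by_macrophage`.
#' @export
immune_dynamics_report <- function(p, schedules, horizon = 150,
                                   output_step = 0.05) {
  if (is.null(names(schedules)) || any(names(schedules) == "")) {
    stop("schedules must be a named list", call. = FALSE)
  }
  vars <- c("T_R_G", "A_mat_G", "T_E_G", "A_inf")
  out <- lapply(names(schedules), function(nm) {
    tr <- simulate_model(p, schedules[[nm]], horizon = horizon,
                         output_step = output_step)
    wide <- cbind(tr$states[, vars, drop = FALSE], tr$destruction)
    data.frame(
      schedule = nm,
      time = rep(tr$times, times = ncol(wide)),
      variable = rep(colnames(wide), each = length(tr$times)),
      value = as.vector(wide),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
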