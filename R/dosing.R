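#' Construct an adoptive-transfer dosing schedule
#'
#' The dosing input is a sum of exponentially decaying boluses,
#' \deqn{D(t) = D_0 \sum_{i=1}^{n} d_i(t), \qquad
#'       d_i(t) = \begin{cases} 0 & t < t_i \\
#'       e^{-\beta (t - t_i)} & t \ge t_i, \end{cases}}
#' where `D0` is the dosing rate (cells/day), `beta` the absorption/decay
#' rate (1/day) and `dose_days` the post-operative days \eqn{t_i} of the
#' injections. The total cell number delivered is \eqn{C = n D_0/\beta}.
#' Fractions `f_G`, `f_LN`, `f_N` partition each dose into activated
#' Tregs entering the graft, activated Tregs entering the lymph node, and
#' naive Tregs entering the lymph node; for an active schedule they sum
#' to 1, and an inactive (zero-dose) schedule has all three equal to 0.
#'
#' `C` is defined as the number of injected cells that reach the modeled
#' lymph-node and graft compartments; systemic losses (roughly half of an
#' injection in practice) are outside the model by convention rather than
#' carried as an extra parameter.
#'
#' @param D0 Dosing rate (cells/day), `>= 0`.
#' @param beta Decay rate (1/day), `> 0`. Default 2/day, representing
#'   fast absorption of an injected bolus.
#' @param dose_days Strictly increasing nonnegative injection days.
#' @param f_G,f_LN,f_N Dose partition fractions in `[0, 1]`.
#' @return An object of class `dosing_schedule` with fields `D0`, `beta`,
#'   `dose_days`, `n`, `f_G`, `f_LN`, `f_N`.
#' @export
#' @examples
#' s <- dosing_schedule(D0 = 1e6, beta = 2, dose_days = 0, f_G = 1)
#' total_dose(s)  # 5e5 cells
dosing_schedule <- function(D0, beta = 2, dose_days = 0,
                            f_G = 0, f_LN = 0, f_N = 0) {
  if (!is.finite(D0) || D0 < 0) stop("D0 must be finite and >= 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  dose_days <- as.numeric(dose_days)
  if (length(dose_days) < 1 || any(!is.finite(dose_days)) ||
      any(dose_days < 0)) {
    stop("dose_days must be nonnegative and finite", call. = FALSE)
  }
  if (is.unsorted(dose_days, strictly = TRUE)) {
    stop("dose_days must be strictly increasing", call. = FALSE)
  }
  f <- c(f_G = f_G, f_LN = f_LN, f_N = f_N)
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("partition fractions must lie in [0, 1]", call. = FALSE)
  }
  active <- D0 > 0
  fsum <- sum(f)
  if (active && abs(fsum - 1) > 1e-8) {
    stop("active schedule requires f_G + f_LN + f_N = 1 (got ", fsum, ")",
         call. = FALSE)
  }
  if (!active && fsum != 0) {
    ## inactive schedule: fractions are irrelevant; normalize to all-zero
    f[] <- 0
  }
  structure(
    list(D0 = D0, beta = beta, dose_days = dose_days,
         n = length(dose_days),
         f_G = unname(f["f_G"]), f_LN = unname(f["f_LN"]),
         f_N = unname(f["f_N"])),
    class = "dosing_schedule"
  )
}

#' Zero-dose (untreated) schedule
#'
#' @return A [dosing_schedule()] with `D0 = 0` and all partition
#'   fractions 0, reproducing the untreated model exactly.
#' @export
no_dose_schedule <- function() {
  dosing_schedule(D0 = 0, beta = 2, dose_days = 0)
}

#' Evaluate the dosing rate D(t)
#'
#' Right-continuous at every injection day: `dose_rate(t_i)` includes the
#' full amplitude of the dose delivered at `t_i`. Vectorized over `t`.
#'
#' @param t Time(s) in days.
#' @param s A [dosing_schedule()].
#' @return Dosing rate in cells/day, same length as `t`.
#' @export
dose_rate <- function(t, s) {
  stopifnot(inherits(s, "dosing_schedule"))
  if (s$D0 == 0) return(numeric(length(t)) + 0 * t)
  vapply(t, function(tt) {
    dt <- tt - s$dose_days
    s$D0 * sum(exp(-s$beta * dt[dt >= 0]))
  }, numeric(1))
}

#' Total cells delivered by a schedule
#'
#' The dose magnitude \eqn{C} is the area under `dose_rate`, which for
#' `n` boluses of amplitude `D0` and decay `beta` is \eqn{n D_0/\beta}.
#'
#' @param s A [dosing_schedule()].
#' @return Total cells delivered over `[0, Inf)`.
#' @export
total_dose <- function(s) {
  stopifnot(inherits(s, "dosing_schedule"))
  s$n * s$D0 / s$beta
}

#' Build an equal-split multi-dose schedule
#'
#' Distributes a total of `C` cells over `n` doses at fixed intervals
#' (daily by default), i.e. `D0 = C * beta / n`, so that
#' `total_dose()` returns `C` exactly.
#'
#' @param C Total cells to deliver (`>= 0`).
#' @param n Number of doses (`>= 1`).
#' @param start_day First injection day (POD).
#' @param interval Days between doses (default 1).
#' @param beta Decay rate (1/day, default 2).
#' @param f_G,f_LN,f_N Partition fractions (must sum to 1 when `C > 0`).
#' @return A [dosing_schedule()].
#' @export
#' @examples
#' equal_split_schedule(5e5, n = 5, start_day = 0, f_G = 1)$D0  # 2e5
equal_split_schedule <- function(C, n, start_day = 0, interval = 1, beta = 2,
                                 f_G = 0, f_LN = 0, f_N = 0) {
  if (!is.finite(C) || C < 0) stop("C must be >= 0", call. = FALSE)
  if (!is.finite(n) || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (interval <= 0) stop("interval must be > 0", call. = FALSE)
  dosing_schedule(
    D0 = C * beta / n, beta = beta,
    dose_days = start_day + interval * (seq_len(n) - 1),
    f_G = f_G, f_LN = f_LN, f_N = f_N
  )
}
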