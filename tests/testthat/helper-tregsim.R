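# Shared fixtures built in code.

# Parameter set with every rate zero (all dynamics switched off) except
# the mandatory positive T_0 / G constraints; useful for analytic cases.
zero_params <- function(T_0 = 1e3, G0 = 1e6, ...) {
  supp <- as.list(stats::setNames(numeric(length(supplementary_rate_names())),
                                  supplementary_rate_names()))
  printed <- list(k_eR = 0, mu_R = 0, r_RG = 0, alpha_6 = 1, a_R = 0,
                  gamma_2 = 1, r_R = 0, alpha_2 = 1, e_R = 0, mu_RN = 0,
                  T_0 = T_0)
  extra <- list(...)
  for (nm in names(extra)) {
    if (nm %in% names(printed)) printed[[nm]] <- extra[[nm]]
    else supp[[nm]] <- extra[[nm]]
  }
  parameter_set(printed, supp, immune_state(T_RN_LN = T_0, G = G0))
}

# Random valid immune state at immunologically plausible magnitudes.
random_state <- function() {
  vals <- stats::runif(14) * c(rep(1e5, 11), 5, 5, 1e9)
  immune_state(values = stats::setNames(vals, state_names()))
}

# Random active single- or multi-dose schedule.
random_schedule <- function() {
  n <- sample(1:6, 1)
  f <- stats::runif(3); f <- f / sum(f)
  dosing_schedule(D0 = stats::runif(1, 1e4, 2e6),
                  beta = stats::runif(1, 0.5, 4),
                  dose_days = cumsum(stats::runif(n, 0.2, 3)),
                  f_G = f[1], f_LN = f[2], f_N = f[3])
}

# O(n^2 m) brute-force non-dominated ranking: repeatedly strip the set
# of points not dominated by any remaining point. Independent of the
# package's fast_nondominated_sort.
brute_force_ranks <- function(objs) {
  n <- nrow(objs)
  rank <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  k <- 0L
  dom <- function(a, b) all(objs[a, ] <= objs[b, ]) && any(objs[a, ] < objs[b, ])
  while (length(remaining)) {
    front <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) j != i && dom(j, i), logical(1)))
    }, logical(1))]
    rank[front] <- k
    remaining <- setdiff(remaining, front)
    k <- k + 1L
  }
  rank
}

# Piecewise quadrature of the dosing input: integrate() on each smooth
# segment between dose days (the integrand has a kink at every t_i).
quad_dose <- function(s, upper) {
  cuts <- sort(unique(c(0, s$dose_days[s$dose_days < upper], upper)))
  total <- 0
  for (k in seq_len(length(cuts) - 1)) {
    total <- total + stats::integrate(dose_rate, cuts[k], cuts[k + 1],
                                      s = s, subdivisions = 500,
                                      rel.tol = 1e-10)$value
  }
  total
}

# Minimal synthetic trajectory object for rejection-time unit tests.
fake_trajectory <- function(times, G) {
  states <- matrix(0, length(times), 14,
                   dimnames = list(NULL, state_names()))
  states[, "G"] <- G
  structure(list(times = times, states = states,
                 destruction = matrix(0, length(times), 2),
                 schedule = no_dose_schedule(), parameters = NULL,
                 solver = list()),
            class = "trajectory")
}
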