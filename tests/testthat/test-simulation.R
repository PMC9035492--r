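test_that("with all rates zero every state stays at its initial value", {
  p <- zero_params(T_0 = 500, G0 = 1e6)
  tr <- suppressWarnings(simulate_model(p, horizon = 20, output_step = 0.5))
  for (v in state_names()) {
    expect_equal(tr$states[, v], rep(p$initial_state[[v]], length(tr$times)),
                 tolerance = 1e-10)
  }
})

test_that("isolated linear decay integrates to the closed-form exponential", {
  p0 <- zero_params(mu_R = 0.7)
  init <- immune_state(T_R_G = 1e4, T_RN_LN = p0$printed$T_0, G = 1e6)
  p <- parameter_set(p0$printed, p0$supplementary_rates, init)
  tr <- suppressWarnings(simulate_model(p, horizon = 10, output_step = 0.25))
  expect_equal(tr$states[, "T_R_G"], 1e4 * exp(-0.7 * tr$times),
               tolerance = 1e-6)
})

test_that("central differences of the trajectory match the RHS", {
  p <- default_parameters()
  h <- 0.02
  tr <- simulate_model(p, horizon = 6, output_step = h)
  idx <- seq(10, length(tr$times) - 10, by = 25)
  for (i in idx) {
    fd <- (tr$states[i + 1, ] - tr$states[i - 1, ]) / (2 * h)
    an <- rhs_full(stats::setNames(tr$states[i, ], state_names()),
                   tr$times[i], p)
    scale <- pmax(abs(an), pmax(abs(tr$states[i, ]), 1))
    expect_lt(max(abs(fd - an) / scale), 50 * h^2)
  }
})

test_that("compiled and reference R right-hand sides integrate identically", {
  p <- default_parameters()
  sched <- dosing_schedule(1e6, 2, c(0, 1.5), f_G = 0.6, f_LN = 0.4)
  tr_c <- simulate_model(p, sched, horizon = 8, output_step = 0.2)
  tr_r <- simulate_model(p, sched, horizon = 8, output_step = 0.2,
                         compiled = FALSE)
  expect_equal(tr_c$states, tr_r$states, tolerance = 1e-6)
})

test_that("zero-dose schedules reproduce the untreated trajectory", {
  p <- default_parameters()
  untreated <- simulate_model(p, horizon = 15, output_step = 0.1)
  zero_C <- simulate_model(p, dosing_schedule(0, 2, 0), horizon = 15,
                           output_step = 0.1)
  expect_equal(zero_C$states, untreated$states, tolerance = 1e-8)
})

test_that("rejection_time locates threshold crossings on interpolants", {
  # constant graft: no crossing
  tr_const <- fake_trajectory(0:50, rep(1e6, 51))
  expect_true(is.na(rejection_time(tr_const)))
  # linear decay G0*(1 - t/100) crosses 25% at t = 75
  tt <- seq(0, 100, by = 0.5)
  tr_lin <- fake_trajectory(tt, 1e6 * (1 - tt / 100))
  expect_equal(rejection_time(tr_lin), 75, tolerance = 1e-3)
  # smooth nonlinear decay: exp(-k t) crossing ln(4)/k
  k <- 0.05
  tr_exp <- fake_trajectory(tt, 1e6 * exp(-k * tt))
  expect_equal(rejection_time(tr_exp), log(4) / k, tolerance = 1e-3)
})

test_that("rejection_time is monotone in the reduction level", {
  tt <- seq(0, 100, by = 0.5)
  tr <- fake_trajectory(tt, 1e6 * exp(-0.05 * tt))
  reductions <- seq(0.1, 0.9, by = 0.1)
  times <- vapply(reductions, function(r) rejection_time(tr, r), numeric(1))
  expect_true(all(diff(times) > 0))
  expect_error(rejection_time(tr, 1.5), "reduction")
})

test_that("rejection time is robust to halving solver tolerances", {
  p <- default_parameters()
  rt1 <- rejection_time(simulate_model(p, horizon = 14, output_step = 0.05))
  rt2 <- rejection_time(simulate_model(p, horizon = 14, output_step = 0.05,
                                       rtol = 5e-9, atol_scale = 5e-11))
  expect_lt(abs(rt1 - rt2), 0.05)
})

test_that("explicit output_times sample the trajectory exactly", {
  p <- default_parameters()
  days <- c(0, 0.5, 2, 3.7, 9)
  tr <- simulate_model(p, horizon = 10, output_times = days)
  expect_equal(tr$times, days)
  ref <- simulate_model(p, horizon = 10, output_step = 0.05)
  G_ref <- stats::approx(ref$times, ref$states[, "G"], xout = days)$y
  expect_equal(tr$states[, "G"], G_ref, tolerance = 1e-6)
})

test_that("trajectory accessors are tidy and consistent", {
  p <- default_parameters()
  tr <- simulate_model(p, horizon = 2, output_step = 0.5)
  df <- as.data.frame(tr)
  expect_setequal(unique(df$variable),
                  c(state_names(), "by_cd8", "by_macrophage"))
  expect_equal(nrow(df), length(tr$times) * 16)
  expect_error(simulate_model(p, horizon = -1), "horizon")
})
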