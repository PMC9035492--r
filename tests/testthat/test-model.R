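test_that("graft Treg equation matches hand-substituted values", {
  p <- zero_params(k_eR = 0.1, mu_R = 0.2, r_RG = 0.05, alpha_6 = 50)
  # zero state with zero dose is a fixed point
  s0 <- immune_state(G = 1)  # G>0 only enters other equations
  p0 <- zero_params()
  expect_equal(rhs_treg_graft(s0, 0, p0, 0), 0)
  # k_eR*100 - mu_R*50 + r_RG*50*(200+100)/(50+50) + 1000
  s <- immune_state(T_R_LN = 100, T_R_G = 50, T_E_G = 200, T_H_G = 100,
                    G = 1)
  expect_equal(rhs_treg_graft(s, 0, p, 1000), 10 - 10 + 7.5 + 1000)
  # f_G = 0 is identical to no dose
  expect_equal(rhs_treg_graft(s, 0, p, 0 * 123), rhs_treg_graft(s, 0, p))
})

test_that("lymph-node Treg equation: activation at half-saturation", {
  # only activation active: a_R * T_RN * A/(gamma_2 + A) with A = gamma_2
  p <- zero_params(a_R = 0.2, gamma_2 = 40)
  s <- immune_state(T_RN_LN = 1000, A_mat_LN = 40, G = 1)
  expect_equal(rhs_treg_ln(s, 0, p, 0), 100)
  # empty compartment, no dose
  expect_equal(rhs_treg_ln(immune_state(G = 1), 0, p, 0), 0)
  # doubling gamma_2 strictly decreases the activation term
  p2 <- zero_params(a_R = 0.2, gamma_2 = 80)
  expect_lt(rhs_treg_ln(s, 0, p2, 0), rhs_treg_ln(s, 0, p, 0))
})

test_that("naive Treg equation relaxes to the set point", {
  p <- zero_params(mu_RN = 0.05, T_0 = 1000)
  at_setpoint <- immune_state(T_RN_LN = 1000, G = 1)
  expect_equal(rhs_treg_naive(at_setpoint, 0, p, 0), 0)
  depleted <- immune_state(T_RN_LN = 0, G = 1)
  expect_equal(rhs_treg_naive(depleted, 0, p, 0), 50)
  expect_equal(rhs_treg_naive(depleted, 0, p, 100), 150)
})

test_that("rhs_full: no dynamics without rates; Treg rows delegate", {
  p0 <- zero_params()
  s <- random_state()
  expect_equal(unname(rhs_full(s, 0, p0)), rep(0, 14))

  set.seed(31)
  p <- default_parameters()
  sched <- dosing_schedule(1e6, 2, 0, f_G = 0.3, f_LN = 0.4, f_N = 0.3)
  for (i in 1:10) {
    s <- random_state()
    t <- stats::runif(1, 0, 3)
    d <- rhs_full(s, t, p, sched)
    D <- dose_rate(t, sched)
    expect_equal(d[["T_RN_LN"]], rhs_treg_naive(s, t, p, 0.3 * D))
    expect_equal(d[["T_R_G"]], rhs_treg_graft(s, t, p, 0.3 * D))
    expect_equal(d[["T_R_LN"]], rhs_treg_ln(s, t, p, 0.4 * D))
  }
})

test_that("dose terms enter only the three Treg equations", {
  set.seed(32)
  p <- default_parameters()
  sched <- dosing_schedule(2e6, 2, c(0, 1), f_G = 0.5, f_LN = 0.25,
                           f_N = 0.25)
  for (i in 1:10) {
    s <- random_state()
    t <- stats::runif(1, 0, 4)
    diff <- rhs_full(s, t, p, sched) - rhs_full(s, t, p)
    D <- dose_rate(t, sched)
    expected <- stats::setNames(rep(0, 14), state_names())
    expected[c("T_R_G", "T_R_LN", "T_RN_LN")] <- c(0.5, 0.25, 0.25) * D
    expect_equal(diff, expected)
  }
})

test_that("DC maturation requires pro-inflammatory cytokine or graft CD4", {
  p <- default_parameters()
  s <- immune_state(A_imm = 5e4, A_mat_G = 0, C_p = 0, T_H_G = 0, G = 1e9)
  d <- rhs_full(s, 0, p)
  # no maturation flux: immature DCs only decay, graft mature DCs gain nothing
  mu_IA <- supp_rate(p, "mu_IA")
  expect_equal(d[["A_imm"]],
               -mu_IA * (1e9 / p$initial_state[["G"]]) * 5e4)
  expect_equal(d[["A_mat_G"]], 0)
  # either signal alone switches maturation on
  expect_gt(rhs_full(immune_state(A_imm = 5e4, C_p = 1, G = 1e9),
                     0, p)[["A_mat_G"]], 0)
  expect_gt(rhs_full(immune_state(A_imm = 5e4, T_H_G = 1e4, G = 1e9),
                     0, p)[["A_mat_G"]], 0)
})

test_that("immature DC decay scales with remaining graft mass", {
  p <- default_parameters()
  G0 <- p$initial_state[["G"]]
  s_full <- immune_state(A_imm = 1e4, G = G0)
  s_half <- immune_state(A_imm = 1e4, G = G0 / 2)
  d_full <- rhs_full(s_full, 0, p)[["A_imm"]]
  d_half <- rhs_full(s_half, 0, p)[["A_imm"]]
  expect_equal(d_half, d_full / 2)
})

test_that("boundary states have nonnegative derivatives (no leak below zero)", {
  set.seed(33)
  p <- default_parameters()
  sched <- dosing_schedule(1e6, 2, 0, f_G = 0.4, f_LN = 0.3, f_N = 0.3)
  for (i in 1:50) {
    s <- random_state()
    k <- sample(14, 1)
    s[k] <- 0
    d <- rhs_full(s, stats::runif(1, 0, 2), p, sched)
    expect_gte(d[[k]], 0)
  }
})

test_that("saturating terms never exceed their capacity", {
  # activation term of the LN Treg equation is bounded by a_R * T_RN_LN
  set.seed(34)
  for (i in 1:100) {
    a_R <- stats::runif(1, 0, 2)
    gamma_2 <- stats::runif(1, 1, 1e5)
    p <- zero_params(a_R = a_R, gamma_2 = gamma_2)
    s <- immune_state(T_RN_LN = stats::runif(1, 0, 1e6),
                      A_mat_LN = stats::runif(1, 0, 1e7), G = 1)
    expect_lte(rhs_treg_ln(s, 0, p, 0), a_R * s[["T_RN_LN"]])
  }
})

test_that("destruction channels decompose -dG/dt exactly", {
  p <- default_parameters()
  expect_equal(graft_destruction_terms(immune_state(G = 1e9), p),
               list(by_cd8 = 0, by_macrophage = 0))
  s_dead <- immune_state(T_E_G = 1e5, A_inf = 1e4, G = 0)
  d0 <- graft_destruction_terms(s_dead, p)
  expect_equal(d0$by_cd8 + d0$by_macrophage, 0)

  set.seed(35)
  for (i in 1:200) {
    s <- random_state()
    d <- graft_destruction_terms(s, p)
    expect_gte(d$by_cd8, 0)
    expect_gte(d$by_macrophage, 0)
    expect_equal(d$by_cd8 + d$by_macrophage, -rhs_full(s, 0, p)[["G"]],
                 tolerance = 1e-12)
  }
})

test_that("state and parameter validation fails loudly", {
  p <- default_parameters()
  expect_error(immune_state(G = -1), "negative")
  expect_error(immune_state(G = NaN), "non-finite")
  expect_error(immune_state(bogus = 1), "unknown state field")
  expect_error(supp_rate(p, "not_a_rate"), "unknown supplementary_rates key")
  p_broken <- p
  p_broken$supplementary_rates$k_GE <- NULL
  expect_error(rhs_full(random_state(), 0, p_broken), "k_GE")
  expect_error(parameter_set(p$printed[-1], p$supplementary_rates,
                             p$initial_state), "missing printed parameter")
})
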