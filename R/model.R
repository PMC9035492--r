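## Right-hand sides of the 14-equation alloimmune model.
##
## The three activated/naive Treg equations follow the printed model
## equations verbatim; the remaining ten follow the predecessor
## rejection model's structure with two updated dendritic-cell
## assumptions: (i) immature DCs decay at a rate proportional to the
## remaining graft mass, and (ii) DC maturation requires the presence of
## pro-inflammatory cytokine or graft-infiltrating CD4 T cells (the
## maturation signal is zero when both are zero).
##
## Saturation denominators are evaluated on states clamped at 0 so that
## a solver excursion a hair below zero cannot flip the sign of a
## Michaelis term; the solver applies its own nonnegativity policy.

.check_finite_state <- function(state) {
  bad <- !is.finite(state)
  if (any(bad)) {
    stop("non-finite state value in field(s) ",
         paste(STATE_NAMES[bad], collapse = ", "), call. = FALSE)
  }
}

.clamp0 <- function(x) pmax(x, 0)

## Saturating ratio num/den with the convention 0 when den == 0 (every
## such term carries a vanishing numerator in that limit).
.sdiv <- function(num, den) if (den > 0) num / den else 0

#' Graft activated-Treg derivative
#'
#' \deqn{dT_{RG}/dt = k_{eR} T_{RLN} - \mu_R T_{RG}
#'   + r_{RG} T_{RG} (T_{EG} + T_{HG})/(\alpha_6 + T_{RG}) + f_G D(t)}
#' Trafficking in from the lymph node, first-order death, proliferation
#' driven by graft effector/helper T cells and saturating in the Treg
#' population itself, plus the graft-directed share of the dose.
#'
#' @param state Named state vector (see [state_names()]).
#' @param t Time in days (unused; the equation is autonomous apart from
#'   the dose, which enters through `dose_rate_graft`).
#' @param p A [parameter_set()].
#' @param dose_rate_graft `f_G * D(t)` in cells/day.
#' @return dT_R_G/dt in cells/day.
#' @export
rhs_treg_graft <- function(state, t, p, dose_rate_graft = 0) {
  .check_finite_state(state)
  if (!is.finite(dose_rate_graft) || dose_rate_graft < 0) {
    stop("non-finite or negative dose_rate_graft", call. = FALSE)
  }
  pr <- p$printed
  TRG <- .clamp0(state[["T_R_G"]])
  pr$k_eR * state[["T_R_LN"]] - pr$mu_R * state[["T_R_G"]] +
    pr$r_RG * state[["T_R_G"]] *
      .sdiv(state[["T_E_G"]] + state[["T_H_G"]], pr$alpha_6 + TRG) +
    dose_rate_graft
}

#' Lymph-node activated-Treg derivative
#'
#' \deqn{dT_{RLN}/dt = a_R T_{RNLN} A_{matLN}/(\gamma_2 + A_{matLN})
#'   - \mu_R T_{RLN} + r_R T_{RLN}(T_{ELN}+T_{HLN})/(\alpha_2 + T_{RLN})
#'   - e_R T_{RLN} + f_{LN} D(t)}
#'
#' @inheritParams rhs_treg_graft
#' @param dose_rate_ln `f_LN * D(t)` in cells/day.
#' @return dT_R_LN/dt in cells/day.
#' @export
rhs_treg_ln <- function(state, t, p, dose_rate_ln = 0) {
  .check_finite_state(state)
  if (!is.finite(dose_rate_ln) || dose_rate_ln < 0) {
    stop("non-finite or negative dose_rate_ln", call. = FALSE)
  }
  pr <- p$printed
  Amat <- .clamp0(state[["A_mat_LN"]])
  TRLN <- .clamp0(state[["T_R_LN"]])
  pr$a_R * state[["T_RN_LN"]] * .sdiv(Amat, pr$gamma_2 + Amat) -
    pr$mu_R * state[["T_R_LN"]] +
    pr$r_R * state[["T_R_LN"]] *
      .sdiv(state[["T_E_LN"]] + state[["T_H_LN"]], pr$alpha_2 + TRLN) -
    pr$e_R * state[["T_R_LN"]] +
    dose_rate_ln
}

#' Naive-Treg derivative
#'
#' \deqn{dT_{RNLN}/dt = \mu_{RN}(T_0 - T_{RNLN}) + f_N D(t)}
#' Homeostatic relaxation to the set point `T_0` plus the naive share of
#' the dose.
#'
#' @inheritParams rhs_treg_graft
#' @param dose_rate_naive `f_N * D(t)` in cells/day.
#' @return dT_RN_LN/dt in cells/day.
#' @export
rhs_treg_naive <- function(state, t, p, dose_rate_naive = 0) {
  .check_finite_state(state)
  if (!is.finite(dose_rate_naive) || dose_rate_naive < 0) {
    stop("non-finite or negative dose_rate_naive", call. = FALSE)
  }
  pr <- p$printed
  pr$mu_RN * (pr$T_0 - state[["T_RN_LN"]]) + dose_rate_naive
}

## DC maturation signal: saturating in pro-inflammatory cytokine OR
## graft CD4 T cells; identically zero when both are zero.
.maturation_signal <- function(state, sp) {
  Cp <- .clamp0(state[["C_p"]])
  THG <- .clamp0(state[["T_H_G"]])
  .sdiv(Cp, sp$k_mp + Cp) + .sdiv(THG, sp$k_mh + THG)
}

#' Instantaneous graft-destruction channels
#'
#' Splits the graft-cell loss rate into its two effector channels:
#' killing by graft-infiltrating cytotoxic CD8 T cells and destruction
#' by inflammatory macrophages. Both channels act on surviving graft
#' cells by mass action and are jointly inhibited by graft Tregs and
#' anti-inflammatory cytokine. Their sum equals `-dG/dt` exactly.
#'
#' @param state Named state vector.
#' @param p A [parameter_set()].
#' @return A list with fields `by_cd8` and `by_macrophage`, both in
#'   cells/day and `>= 0`.
#' @export
graft_destruction_terms <- function(state, p) {
  .check_finite_state(state)
  sp <- p$supplementary_rates
  suppress <- .sdiv(sp$kappa_k, sp$kappa_k + .clamp0(state[["T_R_G"]])) *
    .sdiv(sp$kappa_ca, sp$kappa_ca + .clamp0(state[["C_a"]]))
  G <- state[["G"]]
  list(
    by_cd8 = sp$k_GE * state[["T_E_G"]] * G * suppress,
    by_macrophage = sp$k_GM * state[["A_inf"]] * G * suppress
  )
}

#' Full model derivative
#'
#' Evaluates the time derivative of all 14 states. The three Treg
#' components delegate to [rhs_treg_graft()], [rhs_treg_ln()] and
#' [rhs_treg_naive()] with dose partitions `f_G D(t)`, `f_LN D(t)`,
#' `f_N D(t)`; the dose enters no other equation. The graft equation has
#' only destruction terms (no regrowth), so its derivative is always
#' `<= 0`.
#'
#' @param state Named numeric state vector in [state_names()] order.
#' @param t Time (days).
#' @param p A [parameter_set()].
#' @param schedule A [dosing_schedule()] (default: no dose).
#' @return Named numeric vector of the 14 derivatives.
#' @export
rhs_full <- function(state, t, p, schedule = no_dose_schedule()) {
  .check_finite_state(state)
  pr <- p$printed
  sp <- p$supplementary_rates
  missing_k <- setdiff(SUPPLEMENTARY_RATE_NAMES, names(sp))
  if (length(missing_k)) {
    stop("missing supplementary_rates key: '", missing_k[1], "'",
         call. = FALSE)
  }
  D <- dose_rate(t, schedule)
  s <- state
  cl <- .clamp0(s)

  phi <- .maturation_signal(s, sp)
  sup_G  <- .sdiv(sp$kappa_RA, sp$kappa_RA + cl[["T_R_G"]])    # Treg block on DC maturation
  sup_LN <- .sdiv(sp$kappa_act, sp$kappa_act + cl[["T_R_LN"]])  # Treg block on activation
  mat_flux <- sp$m_A * phi * sup_G * s[["A_imm"]]
  act_drive <- .sdiv(cl[["A_mat_LN"]], sp$gamma_act + cl[["A_mat_LN"]])

  d <- numeric(14)
  names(d) <- STATE_NAMES

  d[["T_H_LN"]] <- sp$a_H * act_drive * sup_LN +
    sp$r_H * s[["T_H_LN"]] *
      .sdiv(cl[["A_mat_LN"]], sp$alpha_T + cl[["T_H_LN"]]) * sup_LN -
    (sp$mu_TH + sp$e_H) * s[["T_H_LN"]]

  d[["T_E_LN"]] <- sp$a_E * act_drive * sup_LN +
    sp$r_E * s[["T_E_LN"]] *
      .sdiv(cl[["A_mat_LN"]], sp$alpha_T + cl[["T_E_LN"]]) * sup_LN -
    (sp$mu_TE + sp$e_E) * s[["T_E_LN"]]

  d[["T_R_LN"]]  <- rhs_treg_ln(s, t, p, schedule$f_LN * D)
  d[["T_RN_LN"]] <- rhs_treg_naive(s, t, p, schedule$f_N * D)

  d[["A_mat_LN"]] <- sp$e_A * s[["A_mat_G"]] - sp$mu_A * s[["A_mat_LN"]]

  d[["T_H_G"]] <- sp$e_H * s[["T_H_LN"]] - sp$mu_THG * s[["T_H_G"]]
  d[["T_E_G"]] <- sp$e_E * s[["T_E_LN"]] - sp$mu_TEG * s[["T_E_G"]]

  d[["T_R_G"]] <- rhs_treg_graft(s, t, p, schedule$f_G * D)

  d[["A_imm"]] <- -sp$mu_IA * (cl[["G"]] / p$initial_state[["G"]]) *
    s[["A_imm"]] - mat_flux

  d[["A_mat_G"]] <- mat_flux - (sp$e_A + sp$mu_A) * s[["A_mat_G"]]

  d[["A_inf"]] <- sp$a_M * .sdiv(cl[["C_p"]], sp$gamma_M + cl[["C_p"]]) *
    .sdiv(sp$kappa_Ma, sp$kappa_Ma + cl[["C_a"]]) - sp$mu_M * s[["A_inf"]]

  d[["C_p"]] <- sp$p_p *
    (s[["A_mat_G"]] + s[["A_inf"]] + s[["T_E_G"]] + s[["T_H_G"]]) *
    .sdiv(sp$kappa_pa, sp$kappa_pa + cl[["C_a"]]) - sp$mu_Cp * s[["C_p"]]

  d[["C_a"]] <- sp$p_a * s[["T_R_G"]] - sp$mu_Ca * s[["C_a"]]

  destr <- graft_destruction_terms(s, p)
  d[["G"]] <- -(destr$by_cd8 + destr$by_macrophage)

  d
}
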