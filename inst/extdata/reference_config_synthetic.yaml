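# Reference model configuration (synthetic): the package's own
# calibration of the alloimmune transplant-rejection model, not a
# transcription of experimentally fitted tables. The embedded
# schedule is a single graft-directed dose of C = 5e5 Tregs on POD0.
printed_parameters:
  k_eR: 0.00359
  mu_R: 0.188
  r_RG: 0.443
  alpha_6: 124000.0
  a_R: 0.05
  gamma_2: 20000.0
  r_R: 0.05
  alpha_2: 100000.0
  e_R: 0.385
  mu_RN: 0.05
  T_0: 100000.0
supplementary_rates:
  mu_IA: 0.859
  m_A: 1.5
  k_mp: 0.5
  k_mh: 50000.0
  kappa_RA: 142000.0
  e_A: 0.319
  mu_A: 0.0404
  a_H: 2000.0
  a_E: 2000.0
  gamma_act: 2000.0
  kappa_act: 73200.0
  r_H: 4.89
  r_E: 3.09
  alpha_T: 33200.0
  mu_TH: 0.25
  mu_TE: 0.25
  e_H: 0.6
  e_E: 0.6
  mu_THG: 0.35
  mu_TEG: 0.35
  a_M: 17600.0
  gamma_M: 1.31
  kappa_Ma: 2.85
  mu_M: 0.342
  p_p: 0.000102
  kappa_pa: 2.0
  mu_Cp: 1.69
  p_a: 1.41e-05
  mu_Ca: 1.0
  k_GE: 3.93e-06
  k_GM: 6.6e-07
  kappa_k: 9990.0
  kappa_ca: 4.55
initial_state:
  T_H_LN: 0.0
  T_E_LN: 0.0
  T_R_LN: 0.0
  T_RN_LN: 100000.0
  A_mat_LN: 0.0
  T_H_G: 0.0
  T_E_G: 0.0
  T_R_G: 0.0
  A_imm: 100000.0
  A_mat_G: 0.0
  A_inf: 0.0
  C_p: 0.167
  C_a: 0.0
  G: 1.0e+09
schedule:
  D0: 1000000.0
  beta: 2.0
  dose_days: 0.0
  f_G: 1.0
  f_LN: 0.0
  f_N: 0.0
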