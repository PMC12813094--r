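sample: LP1
kind: lamina_propria
histology:
  theta0_deg: 16.0
  phi0_deg: 83.0
  families:
    collagen: {H0_um: 42.0, R0_um: 5.0, d0_um: 0.4, phi: 0.46}
hyperelastic:
  mu_Pa: 200.0
  families:
    collagen: {Ef_MPa: 847.0, alpha: 4.4e-3}
  steric: {beta_N: 2.0e-4, kappa: 3.0, delta_c_um: 66.0}
viscoelastic:
  bundle: {E_MPa: 1.47, eta0_MPa_s: 14.2, edot0_per_s: 5.0e-4, n_index: 0.27}
  steric: {Eprime_MPa: 0.99, eta0prime_MPa_s: 8.3, edot0prime_per_s: 5.5e-3}
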