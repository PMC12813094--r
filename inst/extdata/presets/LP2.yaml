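sample: LP2
kind: lamina_propria
histology:
  theta0_deg: 16.0
  phi0_deg: 83.0
  families:
    collagen: {H0_um: 42.5, R0_um: 5.0, d0_um: 0.4, phi: 0.48}
hyperelastic:
  mu_Pa: 190.0
  families:
    collagen: {Ef_MPa: 847.0, alpha: 4.3e-3}
  steric: {beta_N: 4.0e-4, kappa: 3.0, delta_c_um: 65.7}
viscoelastic:
  bundle: {E_MPa: 1.3, eta0_MPa_s: 19.6, edot0_per_s: 6.0e-4, n_index: 0.27}
  steric: {Eprime_MPa: 1.63, eta0prime_MPa_s: 16.0, edot0prime_per_s: 4.5e-3}
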