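sample: V2
kind: vocalis
histology:
  theta0_deg: 28.0
  phi0_deg: 67.0
  families:
    collagen: {H0_um: 30.0, R0_um: 5.5, d0_um: 0.4, phi: 0.12}
    myofibril: {H0_um: 1620.0, R0_um: 90.0, d0_um: 1.0, phi: 0.7}
hyperelastic:
  mu_Pa: 170.0
  families:
    collagen: {Ef_MPa: 847.0, alpha: 4.4e-3}
    myofibril: {Ef_MPa: 0.05, alpha: 2.7e-2}
  steric: {beta_N: 7.6e-5, kappa: 3.0, delta_c_um: 360.0}
viscoelastic:
  bundle: {E_MPa: 0.11, eta0_MPa_s: 1.06, edot0_per_s: 3.3e-3, n_index: 0.27}
  steric: {Eprime_MPa: 0.07, eta0prime_MPa_s: 0.67, edot0prime_per_s: 4.5e-3}
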