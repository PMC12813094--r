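sample: V1
kind: vocalis
histology:
  theta0_deg: 33.0
  phi0_deg: 70.0
  families:
    collagen: {H0_um: 28.0, R0_um: 6.4, d0_um: 0.4, phi: 0.1}
    myofibril: {H0_um: 1350.0, R0_um: 130.0, d0_um: 1.0, phi: 0.7}
hyperelastic:
  mu_Pa: 170.0
  families:
    collagen: {Ef_MPa: 847.0, alpha: 4.4e-3}
    myofibril: {Ef_MPa: 0.05, alpha: 1.1e-2}
  steric: {beta_N: 2.2e-4, kappa: 3.0, delta_c_um: 367.0}
viscoelastic:
  bundle: {E_MPa: 0.11, eta0_MPa_s: 0.38, edot0_per_s: 3.6e-3, n_index: 0.27}
  steric: {Eprime_MPa: 0.11, eta0prime_MPa_s: 0.53, edot0prime_per_s: 4.5e-3}
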