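sample: CSAOS
kind: lamina_propria
histology:
  theta0_deg: 10.5
  phi0_deg: 83.7
  families:
    collagen: {H0_um: 34.5, R0_um: 7.3, d0_um: 0.21, phi: 0.30}
hyperelastic:
  mu_Pa: 31.0
  families:
    collagen: {Ef_MPa: 720.0, alpha: 1.6e-3}
viscoelastic:
  bundle: {E_MPa: 3.68, eta0_MPa_s: 1.56, edot0_per_s: 2.1e-3, n_index: 0.27}
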