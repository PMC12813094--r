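sample: CLAOS
kind: lamina_propria
histology:
  theta0_deg: 32.6
  phi0_deg: 65.7
  families:
    collagen: {H0_um: 45.0, R0_um: 4.5, d0_um: 0.23, phi: 0.30}
hyperelastic:
  mu_Pa: 30.0
  families:
    collagen: {Ef_MPa: 720.0, alpha: 4.6e-3}
viscoelastic:
  bundle: {E_MPa: 4.19, eta0_MPa_s: 1.14, edot0_per_s: 1.9e-3, n_index: 0.27}
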