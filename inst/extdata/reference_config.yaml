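device:
  R_t:
    value: 5.6749912e-08
    unit: R_ext
  lambda:
    value: 0.05
    unit: L
  L:
    value: 1.0
    unit: L
  eta:
    value: 3.0
    unit: force*tau/L
  q:
    value: 20.0
    unit: charge
  q_T:
    value: 1.0
    unit: force/(temperature/L)
  C_th:
    value: 5.0
    unit: energy/temperature
  kappa:
    value: 0.5
    unit: 1/tau
  k_B:
    value: 0.003
    unit: energy/temperature
  n_particles:
    value: 1
    unit: count
  field_sign:
    value: 1.0
    unit: sign
  potential:
    kind: polynomial
    well_position:
      value: -0.4
      unit: L
    coefficients:
      value:
      - 0.0
      - 0.0
      - 217.093003
      - -2770.6159484
      - 17072.0642122
      - -50253.0099459
      - 55836.6777177
      unit: energy/L^k
circuit:
  R_ext:
    value: 1.0
    unit: R_ext
  C:
    value: 1.0
    unit: tau/R_ext
  D_V:
    value: 0.0
    unit: voltage^2*tau
drive:
  voltage:
    kind: dc
    V: 0.95
  temperature:
    kind: const
    T0: 0.05
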