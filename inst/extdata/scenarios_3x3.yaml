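# Simulation scenarios S1-S6 for the 3 x 3 dosing grid.
# Rows index agent W1 levels (600, 1200, 1800 mg), columns agent W2
# levels (50, 75, 100 kBq/kg).  p_tox / p_act are probabilities of
# observing the event over the full tau = 3 cycle window.  u_printed
# are the published true utility values for these scenarios (rounded
# to three decimals in places); they anchor the reconstruction of the
# utility trade-off weights and are not used by the designs themselves.
grid:
  w1_doses: [600, 1200, 1800]
  w2_doses: [50, 75, 100]
scenarios:
  S1:
    p_tox:
      - [0.10, 0.15, 0.20]
      - [0.15, 0.20, 0.30]
      - [0.20, 0.30, 0.45]
    p_act:
      - [0.05, 0.10, 0.15]
      - [0.20, 0.25, 0.30]
      - [0.35, 0.40, 0.45]
    u_printed:
      - [0.017, 0.0505, 0.084]
      - [0.1505, 0.184, 0.201]
      - [0.284, 0.301, -0.7885]
  S2:
    p_tox:
      - [0.05, 0.09, 0.11]
      - [0.07, 0.13, 0.25]
      - [0.15, 0.20, 0.30]
    p_act:
      - [0.05, 0.08, 0.10]
      - [0.10, 0.12, 0.15]
      - [0.20, 0.30, 0.40]
    u_printed:
      - [0.034, 0.050, 0.064]
      - [0.077, 0.077, 0.068]
      - [0.151, 0.234, 0.301]
  S3:
    p_tox:
      - [0.05, 0.10, 0.15]
      - [0.20, 0.25, 0.30]
      - [0.40, 0.45, 0.50]
    p_act:
      - [0.10, 0.20, 0.30]
      - [0.20, 0.30, 0.40]
      - [0.30, 0.40, 0.50]
    u_printed:
      - [0.084, 0.167, 0.251]
      - [0.134, 0.218, 0.301]
      - [-0.922, -0.839, -0.755]
  S4:
    p_tox:
      - [0.20, 0.25, 0.30]
      - [0.40, 0.45, 0.50]
      - [0.50, 0.55, 0.60]
    p_act:
      - [0.20, 0.25, 0.45]
      - [0.30, 0.40, 0.50]
      - [0.35, 0.50, 0.60]
    u_printed:
      - [0.134, 0.168, 0.351]
      - [-0.922, -0.839, -0.755]
      - [-0.905, -0.772, -0.688]
  S5:
    p_tox:
      - [0.05, 0.10, 0.20]
      - [0.15, 0.25, 0.35]
      - [0.30, 0.40, 0.45]
    p_act:
      - [0.05, 0.15, 0.30]
      - [0.10, 0.25, 0.40]
      - [0.20, 0.35, 0.45]
    u_printed:
      - [0.034, 0.117, 0.234]
      - [0.051, 0.168, -0.806]
      - [0.101, -0.872, -0.789]
  S6:
    p_tox:
      - [0.05, 0.20, 0.40]
      - [0.10, 0.25, 0.45]
      - [0.15, 0.30, 0.50]
    p_act:
      - [0.05, 0.20, 0.35]
      - [0.10, 0.25, 0.40]
      - [0.15, 0.30, 0.45]
    u_printed:
      - [0.034, 0.134, -0.872]
      - [0.067, 0.168, -0.839]
      - [0.101, 0.201, -0.805]
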