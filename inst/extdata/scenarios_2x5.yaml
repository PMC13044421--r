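# Simulation scenarios for the 2 x 5 dosing grid.
# Rows index agent W1 levels (600, 1200 mg), columns agent W2 levels
# (50, 75, 100, 125, 150 kBq/kg).  Probabilities are of observing the
# event at any point in the full follow-up window of tau = 3 cycles.
# Six toxicity profiles (T1-T6) cross with eight activity profiles
# (A1-A8) to give 48 scenarios named e.g. "T2.A4".
grid:
  w1_doses: [600, 1200]
  w2_doses: [50, 75, 100, 125, 150]
toxicity:
  T1:
    - [0.03, 0.07, 0.11, 0.15, 0.20]
    - [0.05, 0.09, 0.13, 0.25, 0.30]
  T2:
    - [0.10, 0.15, 0.20, 0.30, 0.40]
    - [0.45, 0.50, 0.55, 0.60, 0.60]
  T3:
    - [0.05, 0.08, 0.15, 0.20, 0.45]
    - [0.10, 0.12, 0.30, 0.40, 0.50]
  T4:
    - [0.10, 0.20, 0.40, 0.50, 0.60]
    - [0.30, 0.45, 0.55, 0.60, 0.60]
  T5:
    - [0.30, 0.45, 0.50, 0.55, 0.60]
    - [0.40, 0.50, 0.55, 0.60, 0.60]
  T6:
    - [0.40, 0.40, 0.50, 0.50, 0.60]
    - [0.40, 0.40, 0.50, 0.50, 0.60]
activity:
  A1:
    - [0.20, 0.30, 0.35, 0.50, 0.55]
    - [0.25, 0.40, 0.45, 0.60, 0.65]
  A2:
    - [0.30, 0.32, 0.38, 0.40, 0.46]
    - [0.34, 0.36, 0.42, 0.44, 0.48]
  A3:
    - [0.06, 0.08, 0.12, 0.20, 0.30]
    - [0.10, 0.15, 0.25, 0.35, 0.40]
  A4:
    - [0.05, 0.20, 0.30, 0.40, 0.50]
    - [0.10, 0.25, 0.35, 0.45, 0.55]
  A5:
    - [0.10, 0.12, 0.14, 0.16, 0.18]
    - [0.20, 0.30, 0.40, 0.50, 0.60]
  A6:
    - [0.10, 0.10, 0.10, 0.10, 0.10]
    - [0.10, 0.10, 0.10, 0.10, 0.20]
  A7:
    - [0.20, 0.30, 0.40, 0.40, 0.40]
    - [0.25, 0.35, 0.45, 0.45, 0.45]
  A8:
    - [0.20, 0.30, 0.40, 0.30, 0.20]
    - [0.30, 0.35, 0.45, 0.35, 0.25]
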