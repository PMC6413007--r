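# Linear discriminant function for FPR binding-affinity classification.
# DF = 245.5 - 296.2*Cchi1 + 50.2*Dchi4pc - 0.0034*W + 4.4*V4
# Applicability window on the output: a compound is predicted active when
# 0 < DF < 8; -8 <= DF <= 0 is predicted inactive; beyond is unclassified.
response: DF
intercept: 245.5
coefficients:
  Cchi1: -296.2
  Dchi4pc: 50.2
  W: -0.0034
  V4: 4.4
window: [0.0, 8.0]
stats:
  "N": 85
  lambda: 0.421
  F: 27.5
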