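# Multilinear regression model for the decimal log of the FPR binding
# constant (nM scale):
# LogKi = 76.50 + 0.000033*ww - 9.50*MAXDN - 15.68*BELm5 - 3.18*G10 - 5.12*VEA1
# LogKi < 2.60 corresponds to binding below 400 nM; < 1.0 to below 10 nM.
response: LogKi
intercept: 76.50
coefficients:
  ww: 0.000033
  MAXDN: -9.50
  BELm5: -15.68
  G10: -3.18
  VEA1: -5.12
stats:
  "N": 48
  R2: 0.875
  Q2: 0.841
  SEE: 0.376
  F: 58.9
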