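# Published exponential-fit coefficients k = a * exp(-b * d_eff) from
# AAPM Report 204, stored as a cross-check against the tabulated values
# (and selectable as the lookup itself via interpolation = "fit").
body_32cm:
  a: 3.704369
  b: 0.03671937
head_16cm:
  a: 1.874799
  b: 0.03871313
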