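# Fitted vicious-cycle parameterisation for soluble Abeta42 in the
# Tg2576 mouse brain (units: A in pg/mg, t in months).
V1: 1.36e+06
K1: 10.7
k2: 450.0
V1p: 0.998
K1p: 134.2
k2p: 0.00168
hill_n: 2
A_init: 34.0
X_init: 1.0
basal: 0.0
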