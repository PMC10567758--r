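# Within-host SARS-CoV-2 baseline (Czuppon et al. 2021, PLOS Comput Biol).
# Units: hours, mL, counts. beta is derived from R0.
p: 0.4666666666666667     # 11.2/24 IV/cell/h
c: 0.4166666666666667     # 10/24 per h
tau_E: 4.8                # 24/5 h
tau_I: 40.33613445378151  # 24/0.595 h
n_E: 1
n_I: 1
N_cells: 40000
s: 1.0
R0: 7.69
gamma: 1.0
V0: 1
I0: 0
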