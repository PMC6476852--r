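# Nominal parameter set of the kicked-Windkessel model.
# Compliances in ml/mmHg, conductances in ml/(s mmHg), pressures in mmHg,
# rates in beats/breaths per minute, times in s.
C_a: 1.6
C_v: 100.0
C_c: 4.3
Z_vc: 200.0
Z_av: 1.1
Z_ca: 166.0
p0: -6.6
p1: 1.5
r_bpm: 66.0
r0: 0.0
tau: 0.3
tau_n: 0.3
R_bpm: 20.0
kick_unit_time: 0.05
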