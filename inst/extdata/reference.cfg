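# Reference configuration: two-erythrocyte aligned collision at the
# weak-adhesion (fibrinogen) setting. Values in display units.

[physics]
kappa_B  = 432      J/m^3
epsilon  = 0.17     um
gamma    = 138      J/m^3
eta      = 8.0e-12  J/m
alpha_S  = 1.8e-2   J/mm^4
alpha_V  = 5.9e4    J/mm^6
S_target = 197      um^2
V_target = 160      um^3
M        = 7.4e-2   m^3/(J s)
v        = 0.57     um/s

[grid]
n  = 90 90 90
dx = 0.17           um

[protocol]
offset_d      = 0    um
speed_v       = 0.57 um/s
reversal_time = 1.18 s
total_time    = 2.5  s

[output]
directory = rbcphase-out
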