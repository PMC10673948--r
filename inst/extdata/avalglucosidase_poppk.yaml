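# Population PK parameter estimates for avalglucosidase alfa
# (three-compartment model, parallel linear + Michaelis-Menten elimination,
# allometric bodyweight scaling around the 70.5 kg dataset median).
cl: 0.808        # L/h
v1: 3.37         # L
vmax: 12.0       # mg/h
km: 0.541        # ug/mL
q2: 0.254        # L/h, fixed
v2: 296.0        # L, fixed
q3: 1.87         # L/h, fixed
v3: 1.31         # L, fixed
q_pc: 0.0157     # L/h
exp_cl: 0.896
exp_v1: 0.661
exp_vmax: 0.463
wt_ref: 70.5     # kg
omega2_cl: 0.0907
omega2_v1: 0.0184
omega2_vmax: 0.118
omega2_km: 0.243
omega2_q_pc: 1.23
sigma2: 0.12     # proportional residual variance
fixed:
- q2
- v2
- q3
- v3
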