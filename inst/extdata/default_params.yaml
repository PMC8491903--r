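# Baseline configuration of the rescue-dynamics model.
# Units are abstract: [t] time, [u] drug concentration.
growth_kind: logistic
mu0: 1.0e-6      # baseline mutation rate, per cell per [t]
alpha: 1.0e-8    # slope of mu(u), per [u] per [t]
b_S: 0.8         # intrinsic birth rate, sensitive
d_S: 0.3         # intrinsic death rate, sensitive
r_S: 0.5         # net growth, sensitive (= b_S - d_S)
b_R: 0.5         # intrinsic birth rate, resistant
d_R: 0.1         # intrinsic death rate, resistant
r_R: 0.4         # net growth, resistant (= b_R - d_R)
d_max: 1.0       # maximal drug kill rate
u_max: 1000      # concentration where the kill rate has plateaued
u_MTD: 1000      # maximum tolerated instantaneous concentration
k: 2.3           # Hill coefficient
h: 40            # half-effect concentration
T: 35            # treatment window, [t]
K: 1.0e+6         # carrying capacity
S0: 1.0e+5        # initial sensitive cells
R0: 0            # initial resistant cells
theta_S: 0.8     # turnover at capacity, sensitive
theta_R: 0.5     # turnover at capacity, resistant
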