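# Default (wild-type) parameters of the stochastic alarmone-GTP feedback model.
# Units are stated per field. Values are model calibrations chosen so that the
# wild-type scenario reproduces the observed spontaneous dormancy-entrance rate
# (~3e-4 per division) and the printed population fractions; see the package
# vignette ("Model and calibration") and calibrate_entrance_rate().
V_B: 25.0      # max SasB-type self-amplifying alarmone synthesis rate (uM/min)
K_B: 50.0      # allosteric activation constant of the feedback synthase (uM)
n_B: 3.0       # Hill coefficient of allosteric activation (dimensionless)
V_R: 1.0       # basal Rel-type synthesis scale (uM/min)
a_R: 1.0       # Rel activation weight by alarmone (dimensionless)
V_A: 0.0       # envelope-stress synthesis rate (uM/min); >0 only under stress
d_P: 0.2       # alarmone hydrolysis/turnover rate (1/min)
v_G: 0.06      # max GTP supply rate (mM/min)
K_i: 20.0      # alarmone inhibition constant on GTP supply (uM)
s_PG: 0.001    # GTP consumed per unit alarmone synthesized (mM/uM)
mu_max: 0.03   # max specific growth rate (1/min)
K_G: 0.5       # GTP half-saturation for growth (mM)
G_thr: 0.15    # dormancy-associated GTP threshold (mM)
alpha_F: 20.0  # max reporter production (AU/min)
K_C: 0.3       # CodY derepression constant (mM GTP)
h_C: 4.0       # reporter Hill steepness (dimensionless)
sigma_eta: 0.18 # extrinsic noise magnitude (stationary s.d. of the OU factor)
tau_eta: 30.0  # noise autocorrelation time (min)
gamma_mu: 0.15 # attenuation of the extrinsic factor on growth rate
eps_mu: 0.002  # growth-arrest cutoff (1/min)
tau_arrest: 30.0 # minimum arrest duration to call dormancy (min)
k_s: 2.3       # susceptible kill rate under 20x MIC vancomycin (1/h)
k_p: 0.04463   # persister kill rate (1/h)
l_div_noise: 0.05 # CV of the symmetric division-split noise
l_meas_cv: 0.02   # multiplicative measurement noise on recorded length
f_meas_cv: 0.05   # multiplicative measurement noise on recorded fluorescence
g_cal: 64.0    # synthetic reporter calibration (mM * AU): G_est = g_cal / F
               # fixed via calibrate_reporter_gtp() on WT lineage entrances
frame_dt: 15.0 # time-lapse frame interval (min)
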