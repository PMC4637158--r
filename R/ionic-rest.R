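# Frozen quiescent states and stimulus defaults.
#
# .bdk_rest_state / .bdk_rest_V are the quiescent steady state of the
# Bondarenko port, obtained by 5000 ms of stimulus-free explicit-Euler
# integration (dt = 1e-4 ms) and regenerated by tools/freeze-rest-state.R
# whenever the model equations change. Stimulus defaults are twice the
# diastolic threshold of a 2 ms edge-plane pulse on a homogeneous tissue
# strip (the transversal plane, whose threshold is the higher of the two
# directions) (single-cell thresholds are far lower but cannot overcome the
# electrotonic load of coupled quiescent tissue).

.bdk_rest_V <- -83.29096793
.bdk_rest_state <- c(
  Cai = 1.14815939000e-01,
  Cass = 1.14815940000e-01,
  CaJSR = 1.29770236000e+03,
  CaNSR = 1.29767414000e+03,
  LTRPN_Ca = 1.12532999000e+01,
  HTRPN_Ca = 1.25276421000e+02,
  P_RyR = 2.71435483000e-23,
  P_C1 = 9.94612375172e-01,
  P_O1 = 6.65871935115e-05,
  P_O2 = 4.23227250073e-10,
  P_C2 = 5.32103721092e-03,
  C1 = 9.99893511870e-01,
  C2 = 1.06483876985e-04,
  C3 = 4.25250888318e-09,
  C4 = 7.54786453502e-14,
  O = 5.04049790458e-19,
  I1 = 1.36331787933e-18,
  I2 = 1.32658907488e-14,
  I3 = 3.54462812503e-14,
  C_Na3 = 6.12227870861e-01,
  C_Na2 = 1.85365030446e-02,
  C_Na1 = 2.25586221458e-04,
  O_Na = 5.04447784142e-07,
  IF_Na = 1.31880012345e-04,
  I1_Na = 1.81860773536e-04,
  I2_Na = 4.18983020114e-06,
  IC_Na2 = 1.08349012380e-02,
  IC_Na3 = 3.57856703571e-01,
  C_K0 = 9.98289392991e-01,
  C_K1 = 9.29998146777e-04,
  C_K2 = 6.00839746282e-04,
  O_K = 1.53206975212e-04,
  I_K = 2.65621406503e-05,
  a_to_f = 2.43863897000e-03,
  i_to_f = 9.99997801000e-01,
  a_to_s = 3.72489600000e-04,
  i_to_s = 9.98744436000e-01,
  n_Ks = 2.31430749000e-04,
  a_ur = 3.72489600000e-04,
  i_ur = 9.98747480000e-01,
  a_Kss = 4.12953625000e-04,
  i_Kss = 1.00000000000e+00,
  Nai = 1.42402163000e+04,
  Ki = 1.43717282000e+05)

.bdk_stim_default <- 368
.bdk_stim_default_micro <- 800
.sur_stim_default <- 193
.sur_stim_default_micro <- 280
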