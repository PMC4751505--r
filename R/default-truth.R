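## Frozen ground-truth values for the 25 estimated rate constants
## (units: wk^-1 for first-order rates; dimensionless for theta_A, beta_I,
## omega_V and sigma_Ag-type yields). Chosen once so the simulated
## dynamics match the qualitative treatment biology (see the methods
## vignette) and then versioned; synthetic datasets and packaged
## predictions derive from these.
default_truth_values <- c(
  rho_S    = 1.63,
  delta_S  = 0.3989,
  lambda   = 0.6595,
  rho_R    = 0.8939,
  delta_R  = 0.2018,
  eta_S    = 0.4191,
  eta_R    = 0.4483,
  theta_A  = 0.5,
  sigma_Ag = 0.1112,
  delta_Ag = 5.575,
  alpha_D  = 0.4578,
  omega_V  = 3.931,
  delta_D  = 1.435,
  alpha_Dr = 0.4178,
  delta_Dr = 0.3236,
  alpha_C  = 1.749,
  beta_I   = 2.467,
  xi_C     = 0.9291,
  mu_C     = 0.2354,
  tau_C    = 1.321,
  alpha_G  = 0.5062,
  zeta     = 0.9035,
  mu_G     = 0.5666,
  tau_G    = 0.135,
  sigma_I  = 1.841
)
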