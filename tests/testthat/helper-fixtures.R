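# Shared fixtures: parameter sets and small simulated data sets built in
# code at test time.

# joint 12-parameter set estimated from the mean poplar trajectories
# (biphasic coupled model column of the model-comparison table)
ref_joint_params <- function() {
  nge_params(
    alpha_H = 0.5647, K_H1 = 14.9231, beta_H_from_D = -0.0092,
    alpha_D = 0.5399, K_D1 = 19.9831, beta_D_from_H = 0.0059,
    K_H2 = 16.1135, p_H = 1.7521, q_H = 0.1755,
    K_D2 = 18.6017, p_D = 2.5552, q_D = 0.1293)
}

# closed-form logistic (the decoupled juvenile-phase subsystem)
logistic_closed <- function(t, K, H0, a) {
  K / (1 + ((K - H0) / H0) * exp(-a * t))
}

# small two-genotype simulated data set with known truth
small_sim <- function(n = 40, H2 = 0.3, T = 24, seed = 99,
                      sad = NULL, params = sim_true_params()) {
  cfg <- simulation_config(n = n, H2 = H2, M = 1, T = T, reps = 1,
                           seed = seed, params = params)
  if (is.null(sad))
    sad <- calibrate_noise(cfg$params, cfg$freqs, cfg$sad_shape, cfg$H2,
                           cfg$grid)
  mk <- simulate_markers(cfg, seed = seed)
  ph <- simulate_phenotypes(cfg, mk, sad = sad, seed = seed + 1)
  list(config = cfg, markers = mk, pheno = ph, sad = sad,
       codes = as.character(mk[1, rownames(ph)]))
}
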