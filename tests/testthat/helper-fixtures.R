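# Shared fixture builders; everything is generated in code under fixed seeds.

# i.i.d. duration-like stimuli (ms)
fix_iid <- function(n = 400, seed = 1) {
  gen_iid_sequence(n, mean = 1150, sd = 300, bounds = c(400, 1900),
                   seed = seed)
}

# simulated observer on i.i.d. stimuli
fix_observer_trials <- function(params, n = 400, noise = 0.1, seed = 1,
                                stim_seed = seed + 1000) {
  simulate_observer(fix_iid(n, stim_seed), params,
                    response_noise_sd = noise, seed = seed)
}

# small two-condition synthetic study
fix_small_study <- function(n_subjects = 3, n_trials = 100, seed = 5, ...) {
  make_synthetic_study(default_study_config(n_subjects = n_subjects,
                                            n_trials = n_trials,
                                            seed = seed, ...))
}
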