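# Re-seed a scenario configuration and run the standard analysis pair on it.
# Latency-clipping warnings from extreme latency draws are expected in long
# seed sweeps and are silenced here.
run_scenario_once <- function(config, seed, family_alpha = 0.05) {
  fields <- unclass(config)
  fields$seed <- seed
  sim <- suppressWarnings(simulate_scenario(do.call(scenario_config, fields)))
  wt <- within_participant_test(sim, family_alpha)
  pm <- population_mean_test(sim, family_alpha)
  list(k = wt$k, n = wt$n_participants,
       pop_mean_significant = pm$any_significant,
       global_p = prev_test_global(wt$k, wt$n_participants,
                                   family_alpha)$p_value)
}
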