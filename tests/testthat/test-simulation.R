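test_that("simulated datasets are reproducible and match their configuration", {
  cfg <- scenario_config(n_participants = 6, n_trials = 30, seed = 5,
                         effect_fraction = 0.5, amplitude_mean = 1.2,
                         latency_sd = 2)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
  expect_equal(dim(s1$data), c(6, 30, 60))
  expect_equal(sum(s1$truth$has_effect), 3)  # round(0.5 * 6)
  expect_true(all(is.na(s1$truth$amplitude[!s1$truth$has_effect])))
})

test_that("pure-noise datasets are centered and effect draws are shared across trials", {
  cfg <- scenario_config(n_participants = 4, n_trials = 200,
                         effect_fraction = 0, seed = 8)
  sim <- simulate_scenario(cfg)
  grand_means <- apply(sim$data, c(1, 3), mean)
  expect_lt(max(abs(grand_means)), 4 / sqrt(200))
  expect_false(any(sim$truth$has_effect))

  # zero amplitude/latency spread: all effect participants share one waveform
  cfg2 <- scenario_config(n_participants = 5, n_trials = 5, amplitude_sd = 0,
                          latency_sd = 0, amplitude_mean = 1.5, seed = 9)
  sim2 <- simulate_scenario(cfg2)
  expect_equal(length(unique(sim2$truth$amplitude)), 1)
  expect_equal(length(unique(sim2$truth$latency)), 1)
})

test_that("trial-mean peak recovers the per-participant amplitude", {
  cfg <- scenario_config(n_participants = 3, n_trials = 200,
                         amplitude_mean = 2, amplitude_sd = 0.3,
                         latency_sd = 1, seed = 12)
  sim <- simulate_scenario(cfg)
  m <- apply(sim$data, c(1, 3), mean)
  for (p in 1:3) {
    peak <- m[p, sim$truth$latency[p]]
    expect_lt(abs(peak - sim$truth$amplitude[p]), 3 * 1 / sqrt(200))
  }
})

test_that("out-of-range latency draws are clipped with a warning", {
  cfg <- scenario_config(n_participants = 20, n_trials = 2, latency_mean = 2,
                         latency_sd = 10, seed = 3)
  expect_warning(sim <- simulate_scenario(cfg), "clipped")
  expect_true(all(sim$truth$latency >= 1 & sim$truth$latency <= 60))
})

test_that("within-participant testing controls the familywise error rate", {
  # 2000 independent all-noise participants, white noise: the sharp case for
  # the Bonferroni guarantee; 99% binomial bound on the observed rate
  cfg <- scenario_config(n_participants = 2000, n_trials = 30,
                         effect_fraction = 0, noise_smooth = 0, seed = 17)
  wt <- within_participant_test(simulate_scenario(cfg), 0.05)
  bound <- 0.05 + 2.576 * sqrt(0.05 * 0.95 / 2000)
  expect_lte(mean(wt$significant), bound)

  # doubling the number of timepoints must not inflate the familywise rate
  cfg2 <- scenario_config(n_participants = 1000, n_trials = 30,
                          n_timepoints = 120, effect_fraction = 0,
                          noise_smooth = 0, seed = 18)
  wt2 <- within_participant_test(simulate_scenario(cfg2), 0.05)
  bound2 <- 0.05 + 2.576 * sqrt(0.05 * 0.95 / 1000)
  expect_lte(mean(wt2$significant), bound2)
})

test_that("overwhelming effects are detected within participants", {
  cfg <- scenario_config(n_participants = 3, n_trials = 100,
                         amplitude_mean = 20, amplitude_sd = 0,
                         latency_sd = 0, seed = 21)
  wt <- within_participant_test(simulate_scenario(cfg))
  expect_true(all(wt$significant))
  expect_equal(wt$k, 3)
  expect_equal(wt$per_test_alpha, 0.05 / 60)
})

test_that("degenerate zero-variance timepoints yield p = 1 with a warning", {
  sim <- simulate_scenario(scenario_config(n_participants = 2, n_trials = 10,
                                           effect_fraction = 0, seed = 2))
  sim$data[1, , 5] <- 3
  expect_warning(wt <- within_participant_test(sim), "zero variance")
  expect_equal(wt$p_value[1, 5], 1)
})

test_that("population-mean testing finds aligned same-sign effects and only those", {
  # constant strong effect in every participant: significant at the latency
  cfg <- scenario_config(n_participants = 20, n_trials = 50,
                         amplitude_mean = 1, amplitude_sd = 0,
                         latency_sd = 0, seed = 23)
  pm <- population_mean_test(simulate_scenario(cfg))
  expect_true(pm$mask[30])

  # all-noise dataset: nothing significant (single representative run; the
  # familywise rate itself is checked above)
  cfg0 <- scenario_config(n_participants = 20, n_trials = 50,
                          effect_fraction = 0, seed = 24)
  pm0 <- population_mean_test(simulate_scenario(cfg0))
  expect_false(pm0$any_significant)
})

test_that("prevalence time course summarizes per-timepoint counts", {
  cfg <- scenario_config(n_participants = 10, n_trials = 80,
                         amplitude_mean = 1.5, amplitude_sd = 0,
                         latency_sd = 0, effect_fraction = 0.5, seed = 27)
  wt <- within_participant_test(simulate_scenario(cfg))
  tc <- prevalence_timecourse(wt, mass = 0.96)
  expect_equal(nrow(tc), 60)
  expect_equal(tc$k, unname(colSums(wt$mask)))
  expect_true(all(tc$k <= 10))
  expect_true(all(tc$map >= tc$lower & tc$map <= tc$upper))
  expect_equal(attr(tc, "alpha"), wt$per_test_alpha)
  # effect latency carries the signal; far-away timepoints carry none
  expect_gt(tc$map[30], 0.3)

  # all-noise time course: MAP zero and HPD lower edge zero wherever k = 0
  cfg0 <- scenario_config(n_participants = 10, n_trials = 80,
                          effect_fraction = 0, seed = 28)
  tc0 <- prevalence_timecourse(within_participant_test(simulate_scenario(cfg0)))
  expect_true(all(tc0$lower[tc0$k == 0] == 0))
  expect_true(mean(tc0$map == 0) > 0.9)
})

test_that("high-SNR prevalence recovery approaches the simulated fraction", {
  cfg <- scenario_config(n_participants = 100, n_trials = 60,
                         amplitude_mean = 3, amplitude_sd = 0,
                         latency_sd = 1, effect_fraction = 0.5, seed = 31)
  wt <- within_participant_test(simulate_scenario(cfg))
  overall_map <- prev_map(wt$k, wt$n_participants, wt$family_alpha)
  expect_lt(abs(overall_map - 0.5), 0.1)
})

test_that("shipped presets encode the four scenario designs", {
  pr <- scenario_presets()
  expect_named(pr, c("A", "B", "C", "D"))
  expect_equal(pr$C$n_participants, 5L)
  expect_equal(pr$D$effect_fraction, 0.5)
  expect_equal(pr$D$n_participants, 20L)
  expect_gt(pr$B$latency_sd, 0)
  expect_equal(pr$B$amplitude_sd, 0)
  expect_equal(pr$A$amplitude_mean, 0)
  expect_gt(pr$A$amplitude_sd, 0)
})
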