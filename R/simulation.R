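#' Configuration for a simulated ERP-like experiment
#'
#' Describes a multi-participant, multi-trial, time-resolved experiment of
#' the kind used to contrast population-mean inference with prevalence
#' inference. Each participant contributes `n_trials` traces of
#' `n_timepoints` samples. A subset of participants (`effect_fraction`)
#' carries a genuine effect: a Gaussian bump of unit peak shape, with
#' per-participant amplitude `A_p ~ Normal(amplitude_mean, amplitude_sd)`
#' and latency `L_p ~ Normal(latency_mean, latency_sd)` (drawn once per
#' participant, shared across that participant's trials). All trials carry
#' additive Gaussian noise of standard deviation `noise_sd`; `noise_smooth`
#' sets the temporal autocorrelation of that noise (the SD, in samples, of a
#' Gaussian smoothing kernel applied to white noise and rescaled to keep the
#' marginal SD at `noise_sd`; 0 gives white noise). Smooth noise mimics the
#' strong autocorrelation of real electrophysiological recordings.
#'
#' @param n_participants,n_trials,n_timepoints Dimensions of the experiment.
#' @param noise_sd Trial noise standard deviation (signal units).
#' @param noise_smooth Temporal autocorrelation scale of the noise, in
#'   samples (0 = white noise).
#' @param amplitude_mean,amplitude_sd Distribution of per-participant effect
#'   amplitudes (signal units).
#' @param latency_mean,latency_sd Distribution of per-participant effect
#'   latencies (sample index; draws are rounded and clipped into range, with
#'   a warning when clipping occurs).
#' @param effect_width SD of the Gaussian effect bump over time (samples).
#' @param effect_fraction Proportion of participants carrying a genuine
#'   effect.
#' @param seed Integer seed making the simulated dataset reproducible.
#' @return An object of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(n_participants = 5, seed = 1)
#' @export
scenario_config <- function(n_participants = 20, n_trials = 100,
                            n_timepoints = 60, noise_sd = 1,
                            noise_smooth = 6, amplitude_mean = 1,
                            amplitude_sd = 0, latency_mean = 30,
                            latency_sd = 0, effect_width = 3,
                            effect_fraction = 1, seed = 1) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_trials = as.integer(n_trials),
              n_timepoints = as.integer(n_timepoints),
              noise_sd = noise_sd, noise_smooth = noise_smooth,
              amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
              latency_mean = latency_mean, latency_sd = latency_sd,
              effect_width = effect_width,
              effect_fraction = effect_fraction, seed = as.integer(seed))
  with(cfg, {
    if (n_participants < 1 || n_trials < 1 || n_timepoints < 1)
      stop("counts must be at least 1", call. = FALSE)
    if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
    if (noise_smooth < 0) stop("noise_smooth must be nonnegative", call. = FALSE)
    if (effect_fraction < 0 || effect_fraction > 1)
      stop("effect_fraction must lie in [0, 1]", call. = FALSE)
    if (latency_mean < 1 || latency_mean > n_timepoints)
      stop("latency_mean must be a valid sample index", call. = FALSE)
    if (latency_sd < 0 || amplitude_sd < 0 || effect_width <= 0)
      stop("latency_sd, amplitude_sd must be nonnegative and effect_width positive",
           call. = FALSE)
  })
  structure(cfg, class = "scenario_config")
}

#' Shipped simulation scenarios
#'
#' Four preset experiments in which prevalence inference finds strong
#' population-level evidence while population-mean inference finds nothing:
#'
#' * `A` — variable effect size: 20 participants all carry an effect, with
#'   amplitudes of mean zero and high variance, so signed effects cancel in
#'   the group mean.
#' * `B` — variable alignment: 20 participants with a fixed amplitude but
#'   widely variable latency, so effects do not align in time across
#'   participants.
#' * `C` — few participants: 5 participants with medium amplitude variance
#'   and consistent timing.
#' * `D` — subgroups: 20 participants of whom only 10 carry the effect, with
#'   fixed amplitude and some timing variability.
#'
#' @return Named list of [scenario_config()] objects `A`, `B`, `C`, `D`.
#' @export
scenario_presets <- function() {
  list(
    A = scenario_config(n_participants = 20, amplitude_mean = 0,
                        amplitude_sd = 1.5, latency_sd = 1,
                        effect_fraction = 1, seed = 101L),
    B = scenario_config(n_participants = 20, amplitude_mean = 1,
                        amplitude_sd = 0, latency_sd = 12,
                        effect_fraction = 1, seed = 102L),
    C = scenario_config(n_participants = 5, amplitude_mean = 1,
                        amplitude_sd = 0.5, latency_sd = 1,
                        effect_fraction = 1, seed = 103L),
    D = scenario_config(n_participants = 20, amplitude_mean = 1.2,
                        amplitude_sd = 0, latency_sd = 5,
                        effect_fraction = 0.5, seed = 104L))
}

# Row-normalized Gaussian smoothing matrix: smoothing white noise with it
# leaves the marginal SD exactly 1 at every timepoint (rows have unit
# Euclidean norm).
smoothing_matrix <- function(n_timepoints, smooth_sd) {
  d <- outer(seq_len(n_timepoints), seq_len(n_timepoints), "-")
  s <- exp(-d^2 / (2 * smooth_sd^2))
  s / sqrt(rowSums(s^2))
}

#' Simulate an ERP-like experiment
#'
#' Generates the participant x trial x timepoint data array described by a
#' [scenario_config()]. Which participants carry the effect, and their
#' amplitudes and latencies, are drawn once; every trial of an effect
#' participant is `A_p * g(t; L_p, effect_width) + noise` with `g` a
#' unit-peak Gaussian bump, and non-effect participants contribute pure
#' noise. Identical configurations (including seed) give bit-identical data.
#'
#' @param config A [scenario_config()].
#' @return An object of class `prev_simulation`: list with `data` (array
#'   `n_participants x n_trials x n_timepoints`), `truth` (data.frame with
#'   per-participant `has_effect`, `amplitude`, `latency`) and `config`.
#' @examples
#' sim <- simulate_scenario(scenario_config(n_participants = 4, n_trials = 20,
#'                                          seed = 7))
#' dim(sim$data)
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    np <- cfg$n_participants; nt <- cfg$n_trials; tt <- cfg$n_timepoints
    n_eff <- round(cfg$effect_fraction * np)
    effect_ids <- sort(sample.int(np, n_eff))
    has_effect <- seq_len(np) %in% effect_ids
    amplitude <- rep(NA_real_, np)
    latency <- rep(NA_real_, np)
    if (n_eff > 0) {
      amplitude[effect_ids] <- rnorm(n_eff, cfg$amplitude_mean,
                                     cfg$amplitude_sd)
      raw_lat <- round(rnorm(n_eff, cfg$latency_mean, cfg$latency_sd))
      if (any(raw_lat < 1 | raw_lat > tt))
        warning(sprintf("%d latency draw(s) clipped to [1, %d]",
                        sum(raw_lat < 1 | raw_lat > tt), tt), call. = FALSE)
      latency[effect_ids] <- pmin(pmax(raw_lat, 1), tt)
    }
    smat <- if (cfg$noise_smooth > 0)
      t(smoothing_matrix(tt, cfg$noise_smooth)) else NULL
    data <- array(0, dim = c(np, nt, tt))
    tgrid <- seq_len(tt)
    for (p in seq_len(np)) {
      e <- matrix(rnorm(nt * tt), nt, tt)
      if (!is.null(smat)) e <- e %*% smat
      e <- e * cfg$noise_sd
      if (has_effect[p]) {
        bump <- amplitude[p] *
          exp(-(tgrid - latency[p])^2 / (2 * cfg$effect_width^2))
        e <- e + rep(bump, each = nt)
      }
      data[p, , ] <- e
    }
    structure(list(data = data,
                   truth = data.frame(participant = seq_len(np),
                                      has_effect = has_effect,
                                      amplitude = amplitude,
                                      latency = latency),
                   config = cfg),
              class = "prev_simulation")
  })
}

# Vectorized two-sided one-sample t-test of each column of x against zero.
# Returns statistic and p-value per column; zero-variance columns get p = 1.
col_ttest <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  v <- (colSums(x^2) - n * mu^2) / (n - 1)
  v[v < 0] <- 0
  degenerate <- v == 0
  if (any(degenerate))
    warning("zero variance at some timepoints; their p-values are set to 1",
            call. = FALSE)
  se <- sqrt(v / n)
  stat <- ifelse(degenerate, 0, mu / se)
  p <- ifelse(degenerate, 1, 2 * pt(-abs(stat), df = n - 1))
  list(statistic = stat, p_value = p)
}

#' Within-participant significance tests over time
#'
#' For each participant and timepoint, a two-sided one-sample t-test of the
#' trial values against zero, Bonferroni-corrected over timepoints: a
#' timepoint is significant when its p-value falls below
#' `family_alpha / n_timepoints`, and a participant is significant overall
#' when any timepoint passes. The familywise false-positive rate per
#' participant is thus controlled at `family_alpha`, which is the `alpha` to
#' use for the overall prevalence posterior.
#'
#' @param sim A [simulate_scenario()] result.
#' @param family_alpha Familywise significance level per participant.
#' @return An object of class `within_tests`: list with matrices `statistic`
#'   and `p_value` (participant x timepoint), logical `mask` of corrected
#'   significance, per-participant logical `significant`, the count `k`,
#'   `n_participants`, `n_timepoints`, `family_alpha` and the per-timepoint
#'   threshold `per_test_alpha`.
#' @examples
#' sim <- simulate_scenario(scenario_config(n_participants = 4, n_trials = 50,
#'                                          seed = 2))
#' wt <- within_participant_test(sim)
#' wt$k
#' @export
within_participant_test <- function(sim, family_alpha = 0.05) {
  stopifnot(inherits(sim, "prev_simulation"))
  if (sim$config$n_trials < 2)
    stop("at least 2 trials are required", call. = FALSE)
  check_alpha(family_alpha)
  np <- sim$config$n_participants
  tt <- sim$config$n_timepoints
  stat <- pmat <- matrix(NA_real_, np, tt)
  for (p in seq_len(np)) {
    res <- col_ttest(sim$data[p, , , drop = TRUE])
    stat[p, ] <- res$statistic
    pmat[p, ] <- res$p_value
  }
  per_test_alpha <- family_alpha / tt
  mask <- pmat < per_test_alpha
  significant <- rowSums(mask) > 0
  structure(list(statistic = stat, p_value = pmat, mask = mask,
                 significant = significant, k = sum(significant),
                 n_participants = np, n_timepoints = tt,
                 family_alpha = family_alpha,
                 per_test_alpha = per_test_alpha),
            class = "within_tests")
}

#' Population-mean significance test over time
#'
#' The conventional second-level analysis: per timepoint, a two-sided
#' one-sample t-test of the participant trial means against zero, Bonferroni
#' corrected over timepoints.
#'
#' @inheritParams within_participant_test
#' @return List with per-timepoint `statistic` and `p_value`, the corrected
#'   significance `mask`, `any_significant`, `family_alpha` and
#'   `per_test_alpha`.
#' @export
population_mean_test <- function(sim, family_alpha = 0.05) {
  stopifnot(inherits(sim, "prev_simulation"))
  if (sim$config$n_participants < 2)
    stop("at least 2 participants are required", call. = FALSE)
  check_alpha(family_alpha)
  # participant x timepoint matrix of trial means
  m <- apply(sim$data, c(1, 3), mean)
  res <- col_ttest(m)
  per_test_alpha <- family_alpha / sim$config$n_timepoints
  mask <- res$p_value < per_test_alpha
  list(statistic = res$statistic, p_value = res$p_value, mask = mask,
       any_significant = any(mask), family_alpha = family_alpha,
       per_test_alpha = per_test_alpha)
}

#' Prevalence time course
#'
#' At each timepoint, counts the participants whose corrected
#' within-participant mask is significant there and summarizes the
#' prevalence posterior for that count. Because each timepoint's test is the
#' Bonferroni-corrected one, the false-positive rate actually controlled per
#' timepoint is `family_alpha / n_timepoints`, and that is the `alpha` used
#' in the per-timepoint posterior.
#'
#' @param wt A [within_participant_test()] result.
#' @param mass Credible level for the HPD interval.
#' @return A data.frame with columns `time`, `k`, `map`, `lower`, `upper`;
#'   the credible level and the per-timepoint alpha are attached as
#'   attributes `mass` and `alpha`.
#' @export
prevalence_timecourse <- function(wt, mass = 0.96) {
  stopifnot(inherits(wt, "within_tests"))
  kt <- colSums(wt$mask)
  np <- wt$n_participants
  a <- wt$per_test_alpha
  uk <- sort(unique(kt))
  maps <- vapply(uk, function(k) prev_map(k, np, a), 0)
  his <- lapply(uk, function(k) prev_hpdi(k, np, a, mass))
  i <- match(kt, uk)
  out <- data.frame(time = seq_along(kt), k = as.integer(kt),
                    map = maps[i],
                    lower = vapply(his, `[[`, 0, "lower")[i],
                    upper = vapply(his, `[[`, 0, "upper")[i])
  attr(out, "mass") <- mass
  attr(out, "alpha") <- a
  out
}
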