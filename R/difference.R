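#' Posterior for the difference in prevalence between two populations
#'
#' Monte-Carlo posterior for `delta = gamma_a - gamma_b`, where the two
#' prevalences have independent posteriors from separate experiments (the
#' same within-participant test applied to samples from two populations).
#' Draws from each prevalence posterior are generated by pushing uniform
#' variates through the posterior quantile function; their pairwise
#' differences are summarized by the median, a central (equal-tail) credible
#' interval, and the posterior probability that `delta > 0`.
#'
#' @param a,b [test_outcomes] for the two experiments (or construct them with
#'   [test_outcomes()]).
#' @param n_samples Number of Monte-Carlo draws.
#' @param seed Integer root seed; all randomness in the call derives from it
#'   and the caller's RNG state is untouched.
#' @param mass Credible level of the equal-tail interval.
#' @return An object of class `prev_diff`: list with `draws`, `n_samples`,
#'   `seed`, `summary` (median, interval, `p_greater`), `method`, and for the
#'   paired model an effective-sample-size diagnostic `ess`.
#' @examples
#' d <- prev_diff_between(test_outcomes(8, 10), test_outcomes(3, 10),
#'                        n_samples = 5000, seed = 1)
#' d$summary$p_greater
#' @export
prev_diff_between <- function(a, b, n_samples = 10000, seed = NULL,
                              mass = 0.96) {
  stopifnot(inherits(a, "test_outcomes"), inherits(b, "test_outcomes"))
  check_samples(n_samples)
  delta <- with_optional_seed(seed, {
    ga <- qprev(runif(n_samples), a)
    gb <- qprev(runif(n_samples), b)
    ga - gb
  })
  new_prev_diff(delta, n_samples, seed, mass, method = "between", ess = NA_real_)
}

#' Joint detection-cell probabilities of the paired prevalence model
#'
#' In the paired design every participant takes two tests (false-positive
#' rates `alpha1`, `alpha2`). The population divides into four latent
#' classes with probabilities `rho = (rho11, rho10, rho01, rho00)`: a true
#' (detectable) effect in both tests, only in test A, only in test B, or in
#' neither. Assuming a test always detects a true effect in its class and
#' otherwise fires at its false-positive rate, the probability of each
#' observed significance pattern is a bilinear map of `rho` and the alphas;
#' the four cell probabilities always sum to 1.
#'
#' @param rho Numeric vector of 4 class probabilities (or a 4-column matrix
#'   of rows on the simplex), in order (both, A only, B only, neither).
#' @param alpha1,alpha2 False-positive rates of tests A and B.
#' @return A vector (or matrix) of probabilities for the observed patterns
#'   (both significant, A only, B only, neither), same shape as `rho`.
#' @export
paired_cell_probs <- function(rho, alpha1, alpha2) {
  check_alpha(alpha1); check_alpha(alpha2)
  r <- if (is.matrix(rho)) rho else matrix(rho, nrow = 1)
  if (ncol(r) != 4) stop("rho must have 4 components", call. = FALSE)
  p11 <- r[, 1] + r[, 2] * alpha2 + r[, 3] * alpha1 + r[, 4] * alpha1 * alpha2
  p10 <- r[, 2] * (1 - alpha2) + r[, 4] * alpha1 * (1 - alpha2)
  p01 <- r[, 3] * (1 - alpha1) + r[, 4] * (1 - alpha1) * alpha2
  p00 <- r[, 4] * (1 - alpha1) * (1 - alpha2)
  out <- cbind(p11, p10, p01, p00)
  if (is.matrix(rho)) out else drop(out)
}

#' Posterior for the difference in prevalence between two paired tests
#'
#' Monte-Carlo posterior for `delta = rho10 - rho01`, the difference between
#' the prevalence of effects detectable by test A (`gamma_A = rho11 + rho10`)
#' and by test B (`gamma_B = rho11 + rho01`) when both tests are applied to
#' the same `n` participants. The data are the four joint counts
#' (significant on both, A only, B only, neither); the model is multinomial
#' with the cell probabilities of [paired_cell_probs()] and a uniform
#' Dirichlet prior on the latent class probabilities.
#'
#' The posterior is approximated by sampling-importance-resampling (SIR):
#' `proposal_factor * n_samples` proposals are drawn from the Dirichlet
#' posterior that ignores test error (shape `counts + 1`), weighted in log
#' space by the ratio of the error-aware multinomial likelihood to the
#' proposal kernel, and resampled with replacement. The effective sample
#' size of the weights is always reported; a warning is raised when it
#' falls below 1% of the proposal count.
#'
#' @param k11,k10,k01,k00 Joint counts: both tests significant / only A /
#'   only B / neither.
#' @param alpha1,alpha2 False-positive rates of the two tests.
#' @inheritParams prev_diff_between
#' @param proposal_factor Proposals drawn per retained sample.
#' @return An object of class `prev_diff`; see [prev_diff_between()].
#' @examples
#' d <- prev_diff_paired(5, 6, 1, 8, n_samples = 2000, seed = 1)
#' d$summary
#' @export
prev_diff_paired <- function(k11, k10, k01, k00, alpha1 = 0.05,
                             alpha2 = alpha1, n_samples = 10000, seed = NULL,
                             mass = 0.96, proposal_factor = 50) {
  counts <- c(k11, k10, k01, k00)
  if (length(counts) != 4 || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (sum(counts) < 1) stop("at least one participant is required", call. = FALSE)
  check_alpha(alpha1); check_alpha(alpha2)
  check_samples(n_samples)
  m <- as.integer(proposal_factor * n_samples)

  res <- with_optional_seed(seed, {
    # proposal: Dirichlet(counts + 1), the posterior pretending the tests
    # have no false positives; heavier-tailed than the target near the data
    shape <- counts + 1
    g <- matrix(rgamma(4L * m, shape = rep(shape, each = m)), m, 4)
    rho <- g / rowSums(g)
    cellp <- paired_cell_probs(rho, alpha1, alpha2)
    logw <- numeric(m)
    for (j in which(counts > 0))
      logw <- logw + counts[j] * (log(cellp[, j]) - log(rho[, j]))
    w <- exp(logw - max(logw))
    ess <- sum(w)^2 / sum(w^2)
    idx <- sample.int(m, n_samples, replace = TRUE, prob = w)
    list(delta = rho[idx, 2] - rho[idx, 3], ess = ess)
  })
  if (res$ess < 0.01 * m)
    warning(sprintf(paste0("SIR effective sample size is low (%.0f of %d ",
                           "proposals); summaries may be unstable"),
                    res$ess, m), call. = FALSE)
  new_prev_diff(res$delta, n_samples, seed, mass, method = "paired",
                ess = res$ess)
}

check_samples <- function(n_samples) {
  if (length(n_samples) != 1L || !is.finite(n_samples) || n_samples < 1)
    stop("n_samples must be a positive integer", call. = FALSE)
}

with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

new_prev_diff <- function(delta, n_samples, seed, mass, method, ess) {
  structure(list(draws = delta,
                 n_samples = as.integer(n_samples),
                 seed = seed,
                 summary = summarize_delta(delta, mass),
                 method = method,
                 ess = ess),
            class = "prev_diff")
}

# Equal-tail summary of difference draws. Central interval rather than a
# sample-based HPD: stable for skewed, bounded distributions.
summarize_delta <- function(delta, mass) {
  qs <- unname(quantile(delta, c((1 - mass) / 2, 1 - (1 - mass) / 2)))
  list(median = median(delta), lower = qs[1], upper = qs[2], mass = mass,
       p_greater = mean(delta > 0))
}

#' @export
print.prev_diff <- function(x, digits = 4, ...) {
  s <- x$summary
  cat(sprintf("Prevalence difference posterior (%s, %d draws)\n",
              x$method, x$n_samples))
  cat(sprintf("  median delta = %.*f; %g%% central interval [%.*f, %.*f]\n",
              digits, s$median, 100 * s$mass, digits, s$lower, digits,
              s$upper))
  cat(sprintf("  P(delta > 0) = %.3f\n", s$p_greater))
  if (is.finite(x$ess))
    cat(sprintf("  SIR effective sample size: %.0f\n", x$ess))
  invisible(x)
}
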