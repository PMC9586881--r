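#' Change of variables between prevalence and significance probability
#'
#' Under the prevalence model each tested participant yields a significant
#' result with probability `theta = alpha + gamma * (1 - alpha)`: participants
#' carrying the effect (population proportion `gamma`) are detected, and the
#' remainder trigger false positives at rate `alpha`. `theta_of_gamma` maps a
#' prevalence to the per-participant significance probability;
#' `gamma_of_theta` is its inverse.
#'
#' @param gamma Population prevalence, in \[0, 1\]. Vectorized.
#' @param theta Per-participant significance probability, in \[alpha, 1\].
#'   Vectorized.
#' @param alpha Within-participant false-positive rate, in (0, 1).
#' @return Numeric vector of probabilities (`theta_of_gamma`) or prevalences
#'   (`gamma_of_theta`).
#' @examples
#' theta_of_gamma(0.5, 0.05)   # 0.525
#' gamma_of_theta(0.525, 0.05) # 0.5
#' @export
theta_of_gamma <- function(gamma, alpha) {
  check_alpha(alpha)
  if (any(!is.finite(gamma)) || any(gamma < 0) || any(gamma > 1))
    stop("gamma must lie in [0, 1]", call. = FALSE)
  alpha + gamma * (1 - alpha)
}

#' @rdname theta_of_gamma
#' @export
gamma_of_theta <- function(theta, alpha) {
  check_alpha(alpha)
  if (any(!is.finite(theta)) || any(theta < alpha) || any(theta > 1))
    stop("theta must lie in [alpha, 1]", call. = FALSE)
  (theta - alpha) / (1 - alpha)
}

check_alpha <- function(alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  invisible(alpha)
}

# Shape parameters and truncation mass of the posterior on the theta scale.
# With a uniform prior on gamma, theta is uniform on [alpha, 1]; the binomial
# likelihood then gives a Beta(k + 1, n - k + 1) posterior on theta truncated
# to [alpha, 1]. log_z is the log of the truncation normalizer
# P(Beta(a, b) > alpha).
posterior_pars <- function(x) {
  a <- x$k + 1
  b <- x$n - x$k + 1
  list(a = a, b = b,
       log_z = pbeta(x$alpha, a, b, lower.tail = FALSE, log.p = TRUE))
}

#' Prevalence posterior distribution
#'
#' Density (`dprev`), distribution function (`pprev`), quantile function
#' (`qprev`) and random generation (`rprev`) for the Bayesian posterior over
#' population prevalence given `k` of `n` participants significant at
#' within-participant false-positive rate `alpha`, under a uniform prior.
#'
#' The model: a participant is significant with probability
#' `theta = alpha + gamma * (1 - alpha)`, so `k` is binomial(`n`, `theta`).
#' A uniform prior on the prevalence `gamma` induces a
#' Beta(`k + 1`, `n - k + 1`) posterior on `theta` truncated to
#' `[alpha, 1]`; the functions here express that posterior on the `gamma`
#' scale. All distribution-function work goes through the regularized
#' incomplete beta function (in log space for the truncation normalizer), so
#' results are stable for large `n`.
#'
#' @param gamma Prevalence values; density is zero outside \[0, 1\].
#' @param q Prevalence values for the CDF.
#' @param p Probabilities for the quantile function, in \[0, 1\].
#' @param m Number of random draws.
#' @param k Number of significant participants, or a [test_outcomes] object
#'   (in which case `n` and `alpha` are taken from it).
#' @param n Total participants tested.
#' @param alpha Within-participant false-positive rate.
#' @param seed Optional integer seed for `rprev`; when supplied the draws are
#'   reproducible and the caller's RNG state is left untouched.
#'
#' @return `dprev`: posterior density values; `pprev`: cumulative
#'   probabilities; `qprev`: prevalence quantiles; `rprev`: prevalence draws.
#' @examples
#' dprev(0.5, k = 6, n = 10)
#' pprev(0.5, k = 6, n = 10)
#' qprev(c(0.02, 0.98), k = 6, n = 10)
#' @export
dprev <- function(gamma, k, n = NULL, alpha = 0.05) {
  x <- as_outcomes(k, n, alpha)
  p <- posterior_pars(x)
  d <- numeric(length(gamma))
  ok <- is.finite(gamma) & gamma >= 0 & gamma <= 1
  th <- x$alpha + gamma[ok] * (1 - x$alpha)
  d[ok] <- exp(dbeta(th, p$a, p$b, log = TRUE) - p$log_z) * (1 - x$alpha)
  d[!is.finite(gamma)] <- NA_real_
  d
}

#' @rdname dprev
#' @export
pprev <- function(q, k, n = NULL, alpha = 0.05) {
  x <- as_outcomes(k, n, alpha)
  p <- posterior_pars(x)
  out <- numeric(length(q))
  out[q >= 1] <- 1
  mid <- is.finite(q) & q > 0 & q < 1
  th <- x$alpha + q[mid] * (1 - x$alpha)
  # P(Gamma <= g) = 1 - P(theta > theta(g)) / P(theta > alpha)
  upper <- exp(pbeta(th, p$a, p$b, lower.tail = FALSE, log.p = TRUE) - p$log_z)
  out[mid] <- pmin(pmax(1 - upper, 0), 1)
  out[!is.finite(q)] <- NA_real_
  out
}

#' @rdname dprev
#' @export
qprev <- function(p, k, n = NULL, alpha = 0.05) {
  x <- as_outcomes(k, n, alpha)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  pp <- posterior_pars(x)
  z <- exp(pp$log_z)
  th <- numeric(length(p))
  lo <- p <= 0.5
  # lower-tail form for small p, upper-tail form for p near 1: both sides of
  # the truncated distribution keep full relative precision
  th[lo] <- qbeta(pbeta(x$alpha, pp$a, pp$b) + p[lo] * z, pp$a, pp$b)
  th[!lo] <- qbeta((1 - p[!lo]) * z, pp$a, pp$b, lower.tail = FALSE)
  g <- (th - x$alpha) / (1 - x$alpha)
  pmin(pmax(g, 0), 1)
}

#' @rdname dprev
#' @export
rprev <- function(m, k, n = NULL, alpha = 0.05, seed = NULL) {
  x <- as_outcomes(k, n, alpha)
  if (length(m) != 1L || !is.finite(m) || m < 1)
    stop("m must be a positive integer", call. = FALSE)
  draw <- function() qprev(runif(m), x)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Maximum a posteriori prevalence estimate
#'
#' The mode of the prevalence posterior. On the significance-probability
#' scale the Beta(`k + 1`, `n - k + 1`) mode is the sample proportion `k / n`;
#' mapping back through `gamma = (theta - alpha) / (1 - alpha)` and clamping
#' to the unit interval gives the closed form
#' `clamp((k/n - alpha) / (1 - alpha), 0, 1)`. A sample proportion at or
#' below `alpha` is fully explained by false positives, so the MAP is 0
#' (valid evidence of low prevalence, not an error).
#'
#' @inheritParams dprev
#' @return The MAP prevalence estimate, a scalar in \[0, 1\].
#' @examples
#' prev_map(6, 10)        # 0.5789...
#' prev_map(0, 10)        # 0
#' @export
prev_map <- function(k, n = NULL, alpha = 0.05) {
  x <- as_outcomes(k, n, alpha)
  min(max((x$k / x$n - x$alpha) / (1 - x$alpha), 0), 1)
}

#' Highest posterior density interval for prevalence
#'
#' The shortest interval containing a stated posterior mass. The posterior is
#' unimodal, so the HPD interval is found by sliding a window of fixed
#' probability mass along the quantile function: the candidate with
#' lower-endpoint CDF value `t` is `[qprev(t), qprev(t + mass)]`, and the
#' width is minimized over `t` in `[0, 1 - mass]` by scalar optimization.
#' When the mode sits on a boundary the interval is one-sided: `[0,
#' qprev(mass)]` when the sample proportion does not exceed `alpha` (mode at
#' 0), and `[qprev(1 - mass), 1]` when every participant is significant
#' (mode at 1).
#'
#' @inheritParams dprev
#' @param mass Credible level of the interval, in (0, 1); e.g. 0.5 or 0.96.
#' @return An object of class `hpd_interval`: list with elements `lower`,
#'   `upper` and `mass`.
#' @examples
#' prev_hpdi(10, 20, mass = 0.96)  # roughly [0.25, 0.70]
#' @export
prev_hpdi <- function(k, n = NULL, alpha = 0.05, mass = 0.96) {
  x <- as_outcomes(k, n, alpha)
  if (length(mass) != 1L || !is.finite(mass) || mass <= 0 || mass >= 1)
    stop("mass must lie strictly between 0 and 1", call. = FALSE)
  if (x$k == x$n) {
    lo <- qprev(1 - mass, x); hi <- 1
  } else if (x$k / x$n <= x$alpha) {
    lo <- 0; hi <- qprev(mass, x)
  } else {
    width <- function(t) qprev(t + mass, x) - qprev(t, x)
    opt <- optimize(width, c(0, 1 - mass), tol = 1e-9)
    lo <- qprev(opt$minimum, x); hi <- qprev(opt$minimum + mass, x)
  }
  structure(list(lower = lo, upper = hi, mass = mass), class = "hpd_interval")
}

#' @export
print.hpd_interval <- function(x, digits = 4, ...) {
  cat(sprintf("%g%% HPDI: [%.*f, %.*f]\n", 100 * x$mass,
              digits, x$lower, digits, x$upper))
  invisible(x)
}

#' Full Bayesian prevalence summary
#'
#' One-stop summary of a within-participant testing campaign: MAP estimate,
#' HPD intervals at the requested credible levels, and the frequentist global
#' (prevalence = 0) and majority (prevalence < 0.5) null tests.
#'
#' @inheritParams dprev
#' @param masses Credible levels for the HPD intervals.
#' @return An object of class `prevalence_fit` with elements `outcomes`,
#'   `map`, `hpdi` (named list of [prev_hpdi] results) and the two null-test
#'   results `global_null` and `majority_null`.
#' @examples
#' prevalence(10, 20)
#' @export
prevalence <- function(k, n = NULL, alpha = 0.05, masses = c(0.5, 0.96)) {
  x <- as_outcomes(k, n, alpha)
  hp <- lapply(masses, function(m) prev_hpdi(x, mass = m))
  names(hp) <- sprintf("%g%%", 100 * masses)
  structure(list(outcomes = x,
                 map = prev_map(x),
                 hpdi = hp,
                 global_null = prev_test_global(x),
                 majority_null = prev_test(x, gamma0 = 0.5)),
            class = "prevalence_fit")
}

#' @export
print.prevalence_fit <- function(x, digits = 4, ...) {
  print(x$outcomes)
  cat(sprintf("MAP prevalence: %.*f\n", digits, x$map))
  for (h in x$hpdi)
    cat(sprintf("  %2g%% HPDI: [%.*f, %.*f]  (%d%% to %d%%)\n",
                100 * h$mass, digits, h$lower, digits, h$upper,
                round(100 * h$lower), round(100 * h$upper)))
  cat(sprintf("Global null (prevalence = 0):    -log10 p = %.1f\n",
              x$global_null$neg_log10_p))
  cat(sprintf("Majority null (prevalence < 0.5): -log10 p = %.1f\n",
              x$majority_null$neg_log10_p))
  invisible(x)
}
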