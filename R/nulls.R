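#' Frequentist tests of prevalence null hypotheses
#'
#' Exact binomial upper-tail tests of hypotheses about the population
#' prevalence. `prev_test_global` tests the global null that the prevalence
#' is 0 (no participant shows the effect), under which each participant is
#' significant with probability `alpha` alone; the p-value is
#' `P(X >= k)` for `X ~ Binomial(n, alpha)`. `prev_test` generalizes to any
#' null prevalence `gamma0`: the success probability becomes
#' `theta(gamma0) = alpha + gamma0 * (1 - alpha)`, and `gamma0 = 0.5` is the
#' majority null (prevalence below one half). A one-sided "at least k"
#' tail is used throughout, since the question is how surprising `k` or more
#' significant participants would be under the null.
#'
#' Tail probabilities are computed in log space, so `neg_log10_p` remains
#' accurate for p-values far below double-precision underflow of
#' intermediate terms.
#'
#' @inheritParams dprev
#' @param gamma0 Null prevalence, in \[0, 1).
#' @return An object of class `prev_null_test`: list with `p_value`,
#'   `neg_log10_p`, `null_prevalence`, and `outcomes`.
#' @examples
#' prev_test_global(6, 10)        # -log10 p about 5.56
#' prev_test(12, 12, gamma0 = 0.5)
#' @export
prev_test_global <- function(k, n = NULL, alpha = 0.05) {
  x <- as_outcomes(k, n, alpha)
  prev_test(x, gamma0 = 0)
}

#' @rdname prev_test_global
#' @export
prev_test <- function(k, n = NULL, alpha = 0.05, gamma0 = 0.5) {
  x <- as_outcomes(k, n, alpha)
  if (length(gamma0) != 1L || !is.finite(gamma0) || gamma0 < 0 || gamma0 >= 1)
    stop("gamma0 must lie in [0, 1)", call. = FALSE)
  theta0 <- x$alpha + gamma0 * (1 - x$alpha)
  lp <- pbinom(x$k - 1, x$n, theta0, lower.tail = FALSE, log.p = TRUE)
  structure(list(p_value = exp(lp),
                 neg_log10_p = -lp / log(10) + 0,  # + 0 drops negative zero
                 null_prevalence = gamma0,
                 outcomes = x),
            class = "prev_null_test")
}

#' @export
print.prev_null_test <- function(x, ...) {
  lab <- if (x$null_prevalence == 0) "global null (prevalence = 0)"
         else sprintf("prevalence null (gamma0 = %g)", x$null_prevalence)
  cat(sprintf("Binomial test of the %s: k = %d of n = %d, alpha = %g\n",
              lab, x$outcomes$k, x$outcomes$n, x$outcomes$alpha))
  cat(sprintf("  p = %.4g  (-log10 p = %.2f)\n", x$p_value, x$neg_log10_p))
  invisible(x)
}

#' Prevalence evidence surface over all (n, k) outcomes
#'
#' Tabulates, for every possible outcome `k` of each sample size in
#' `n_values`, the global-null and majority-null evidence (-log10 p), the MAP
#' prevalence estimate and the lower edge of the HPD interval at the given
#' mass. The long-format table reproduces the usual contour plots of
#' prevalence evidence against experiment size, and shows e.g. that 4/5,
#' 6/10, 10/20 and 22/50 significant all bound the prevalence below by about
#' 0.25 while greatly exceeding the usual -log10 p = 1.3 (p = 0.05) evidence
#' level for a population effect.
#'
#' @param n_values Integer vector of sample sizes.
#' @param alpha Within-participant false-positive rate.
#' @param mass Credible level for the HPD lower edge.
#' @return A data.frame with columns `n`, `k`, `neglog10p_global`,
#'   `neglog10p_majority`, `map`, `hpdi_lower`.
#' @examples
#' g <- prev_contour_grid(c(5, 10))
#' subset(g, n == 5 & k == 4)
#' @export
prev_contour_grid <- function(n_values, alpha = 0.05, mass = 0.96) {
  if (length(n_values) < 1L) stop("n_values must be nonempty", call. = FALSE)
  if (any(n_values < 1 | n_values != round(n_values)))
    stop("n_values must be positive integers", call. = FALSE)
  rows <- lapply(n_values, function(n) {
    ks <- 0:n
    data.frame(
      n = as.integer(n), k = ks,
      neglog10p_global = vapply(ks, function(k)
        prev_test_global(k, n, alpha)$neg_log10_p, 0),
      neglog10p_majority = vapply(ks, function(k)
        prev_test(k, n, alpha, gamma0 = 0.5)$neg_log10_p, 0),
      map = vapply(ks, function(k) prev_map(k, n, alpha), 0),
      hpdi_lower = vapply(ks, function(k)
        prev_hpdi(k, n, alpha, mass)$lower, 0))
  })
  do.call(rbind, rows)
}

#' Write a prevalence evidence grid as TSV
#'
#' @param grid A data.frame from [prev_contour_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contour_grid <- function(grid, path) {
  need <- c("n", "k", "neglog10p_global", "neglog10p_majority", "map",
            "hpdi_lower")
  if (!all(need %in% names(grid)))
    stop("grid is missing required columns", call. = FALSE)
  write.table(grid[need], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
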