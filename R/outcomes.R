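#' Summary of a within-participant testing campaign
#'
#' Bundles the three numbers that determine the prevalence posterior: how many
#' participants were individually significant (`k`), how many were tested
#' (`n`), and the false-positive rate `alpha` of the within-participant test.
#' `alpha` is the probability that a participant with no detectable effect
#' nevertheless comes out significant; it is a property of the test applied to
#' each participant (e.g. 0.05 for an uncorrected test, or the familywise
#' level of a corrected test).
#'
#' @param k Integer, number of significant participants, `0 <= k <= n`.
#' @param n Integer, total number of participants tested, `n >= 1`.
#' @param alpha Within-participant false-positive rate, in (0, 1).
#'
#' @return An object of class `test_outcomes`: a list with elements `k`, `n`
#'   and `alpha`.
#' @examples
#' test_outcomes(10, 20)
#' @export
test_outcomes <- function(k, n, alpha = 0.05) {
  if (length(k) != 1L || length(n) != 1L || length(alpha) != 1L)
    stop("k, n and alpha must be scalars", call. = FALSE)
  if (!is.finite(k) || !is.finite(n) || k != round(k) || n != round(n))
    stop("k and n must be finite integers", call. = FALSE)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  structure(list(k = as.integer(k), n = as.integer(n), alpha = alpha),
            class = "test_outcomes")
}

#' @export
print.test_outcomes <- function(x, ...) {
  cat(sprintf("Within-participant test outcomes: k = %d of n = %d significant (alpha = %g)\n",
              x$k, x$n, x$alpha))
  invisible(x)
}

# Normalize (k, n, alpha) arguments: the first argument may be a
# test_outcomes object, in which case n/alpha must be left at their defaults.
as_outcomes <- function(k, n = NULL, alpha = 0.05) {
  if (inherits(k, "test_outcomes")) return(k)
  if (is.null(n)) stop("n is required when k is not a test_outcomes object",
                       call. = FALSE)
  test_outcomes(k, n, alpha)
}
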