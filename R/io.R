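#' Read per-participant test results from CSV
#'
#' Reads a table of within-participant test results and reduces it to the
#' summary counts needed for prevalence inference. The file must have a
#' header of either `participant_id,p_value` (per-participant p-values; a
#' participant counts as significant when `p_value < alpha`) or
#' `participant_id,significant` (0/1 flags, taken as-is; `alpha` must then
#' be the false-positive rate at which those flags were obtained).
#'
#' @param path Path to a CSV file.
#' @param alpha Within-participant false-positive rate recorded in the
#'   returned outcomes (and used to threshold p-values).
#' @return A [test_outcomes] object.
#' @export
read_participant_table <- function(path, alpha = 0.05) {
  check_alpha(alpha)
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop(sprintf("malformed CSV '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  cols <- names(tab)
  ok_p <- identical(cols, c("participant_id", "p_value"))
  ok_s <- identical(cols, c("participant_id", "significant"))
  if (!ok_p && !ok_s)
    stop("header must be exactly 'participant_id,p_value' or 'participant_id,significant'",
         call. = FALSE)
  if (nrow(tab) == 0) stop("no participant rows in file", call. = FALSE)
  dup <- duplicated(tab$participant_id)
  if (any(dup))
    stop(sprintf("duplicate participant_id '%s' at row %d",
                 tab$participant_id[which(dup)[1]], which(dup)[1]),
         call. = FALSE)
  if (ok_p) {
    v <- tab$p_value
    bad <- !is.finite(v) | v < 0 | v > 1
    if (any(bad))
      stop(sprintf("p_value out of [0, 1] at row %d (participant '%s')",
                   which(bad)[1], tab$participant_id[which(bad)[1]]),
           call. = FALSE)
    k <- sum(v < alpha)
  } else {
    v <- tab$significant
    bad <- !is.finite(v) | !(v %in% c(0, 1))
    if (any(bad))
      stop(sprintf("significant must be 0 or 1 at row %d (participant '%s')",
                   which(bad)[1], tab$participant_id[which(bad)[1]]),
           call. = FALSE)
    k <- sum(v == 1)
  }
  test_outcomes(k, nrow(tab), alpha)
}
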