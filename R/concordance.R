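#' Harrell's concordance index for right-censored data
#'
#' The fraction of comparable pairs in which the model's risk ordering
#' agrees with the observed survival ordering. A pair `(i, j)` is
#' comparable iff the earlier of the two times is an observed event; ties
#' in time are not comparable. The pair is concordant when the subject with
#' the earlier event time has the higher risk score; ties in risk count
#' one half.
#'
#' @param time Observed times (event or censoring).
#' @param event 0/1 event indicator.
#' @param risk Numeric risk scores, higher = higher hazard.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(time, event, risk) {
  m <- length(time)
  stopifnot(length(event) == m, length(risk) == m,
            all(event %in% c(0, 1)))
  earlier <- outer(time, time, "<")          # (i,j): i strictly earlier
  comparable <- earlier & (event == 1)       # earlier one must be an event
  n_comp <- sum(comparable)
  if (n_comp == 0) stop("no comparable pairs")
  concordant <- sum(outer(risk, risk, ">") & comparable)
  tied <- sum(outer(risk, risk, "==") & comparable)
  (concordant + 0.5 * tied) / n_comp
}
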