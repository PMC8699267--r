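#' Target-decoy false-discovery-rate estimation
#'
#' Classical target-decoy counting: at score cutoff s the FDR estimate
#' is `#{decoys >= s} / max(1, #{targets >= s})` (higher score =
#' better). q-values are the running minimum of the FDR over decreasing
#' cutoffs, so they are monotone non-increasing in score; acceptance is
#' `q <= threshold` (inclusive).
#'
#' @param target_scores Numeric scores of target entries.
#' @param decoy_scores Numeric scores of decoy entries.
#' @param threshold Acceptance q-value cutoff (default 0.05).
#' @return data.frame of class `td_fdr` with one row per target in the
#'   input order: `score`, `fdr`, `qvalue`, `accepted`.
#' @export
target_decoy_fdr <- function(target_scores, decoy_scores,
                             threshold = 0.05) {
  stopifnot(length(target_scores) > 0, length(decoy_scores) > 0)
  ord <- order(target_scores, decreasing = TRUE)
  s <- target_scores[ord]
  n_target_ge <- seq_along(s)                      # ties handled below
  # with ties, all tied targets share the count at the lowest tied rank
  n_target_ge <- ave(n_target_ge, s, FUN = max)
  dec_sorted <- sort(decoy_scores)
  n_decoy_ge <- length(decoy_scores) -
    findInterval(s, dec_sorted, left.open = TRUE)
  fdr <- n_decoy_ge / pmax(1, n_target_ge)
  q <- rev(cummin(rev(pmin(fdr, Inf))))
  out <- data.frame(score = target_scores,
                    fdr = fdr[order(ord)],
                    qvalue = q[order(ord)])
  out$accepted <- out$qvalue <= threshold
  class(out) <- c("td_fdr", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "n_decoys") <- length(decoy_scores)
  out
}

#' @export
print.td_fdr <- function(x, ...) {
  cat(sprintf(
    "Target-decoy FDR: %d targets, %d decoys, %d accepted at q <= %g\n",
    nrow(x), attr(x, "n_decoys"), sum(x$accepted),
    attr(x, "threshold")))
  invisible(x)
}
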