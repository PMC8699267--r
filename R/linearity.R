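# Dilution-linearity branch: per-protein OLS of log2 intensity on log2
# amount, R-squared as the transfer-credibility score, column-shuffled
# decoys, classical target-decoy FDR.

#' Per-protein ordinary least squares over a dilution series
#'
#' Fits, for every row with at least 3 non-missing points, an OLS
#' regression of log2 intensity (response) on log2 amount (regressor)
#' and records the coefficient of determination R-squared as the score.
#' Rows with fewer than 3 points are returned unscored (`NA`) and
#' flagged.
#'
#' @param mat Numeric matrix of log2 intensities, proteins x dilution
#'   points (NA allowed).
#' @param amounts Loaded amounts (ng), one per column; log2-transformed
#'   internally as the regressor. Must have positive variance.
#' @return data.frame of class `linearity_fit`: `protein`, `slope`
#'   (log2 units per log2 ng), `intercept`, `r2`, `n_points`, `scored`.
#' @export
fit_linearity <- function(mat, amounts) {
  stopifnot(is.matrix(mat), ncol(mat) == length(amounts))
  x <- log2(amounts)
  if (stats::var(x) == 0) stop("zero-variance regressor (amounts)")
  ok <- !is.na(mat)
  n <- rowSums(ok)
  X <- matrix(rep(x, each = nrow(mat)), nrow(mat))
  X[!ok] <- NA
  sx <- rowSums(X, na.rm = TRUE)
  sy <- rowSums(mat, na.rm = TRUE)
  sxx <- rowSums(X^2, na.rm = TRUE)
  syy <- rowSums(mat^2, na.rm = TRUE)
  sxy <- rowSums(X * mat, na.rm = TRUE)
  Sxx <- sxx - sx^2 / n
  Syy <- syy - sy^2 / n
  Sxy <- sxy - sx * sy / n
  slope <- Sxy / Sxx
  intercept <- sy / n - slope * sx / n
  r2 <- ifelse(Syy > 0, Sxy^2 / (Sxx * Syy), NA_real_)
  r2 <- pmin(pmax(r2, 0), 1)
  scored <- n >= 3 & Sxx > 0 & !is.na(r2)
  slope[!scored] <- intercept[!scored] <- r2[!scored] <- NA_real_
  out <- data.frame(
    protein = if (!is.null(rownames(mat))) rownames(mat)
              else as.character(seq_len(nrow(mat))),
    slope = slope, intercept = intercept, r2 = r2,
    n_points = n, scored = scored, stringsAsFactors = FALSE)
  class(out) <- c("linearity_fit", "data.frame")
  out
}

#' Column-shuffled decoy matrix
#'
#' Within each dilution column independently, intensities are permuted
#' across proteins so every protein adopts another protein's value at
#' that dilution; the per-column intensity multiset is preserved
#' exactly. Permutations are re-drawn (up to 100 attempts per column)
#' until no protein keeps its own value; if a fixed-point-free
#' permutation is not found the last draw is accepted.
#'
#' @param mat Numeric matrix, proteins x dilution points (>= 2 rows).
#' @param seed Integer seed; fixed seed gives an identical decoy matrix.
#' @return Matrix of the same shape, rownames prefixed `decoy_`.
#' @export
make_shuffle_decoys <- function(mat, seed = 1L) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2)
    stop("cannot shuffle a single-protein matrix")
  set.seed(seed)
  n <- nrow(mat)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    for (attempt in 1:100) {
      p <- sample.int(n)
      if (!any(p == seq_len(n))) break
    }
    out[, j] <- mat[p, j]
  }
  rn <- if (!is.null(rownames(mat))) rownames(mat)
        else as.character(seq_len(n))
  rownames(out) <- paste0("decoy_", rn)
  out
}

#' Dilution-linearity target-decoy FDR procedure
#'
#' The full linearity branch as one call: fit per-protein OLS on the
#' target matrix, build a column-shuffled decoy matrix and fit it the
#' same way, then estimate q-values by target-decoy counting on the
#' R-squared scores and accept proteins at `q <= threshold`.
#'
#' @param mat Proteins x dilutions matrix of log2 intensities.
#' @param amounts Loaded amounts (ng) per column.
#' @param threshold Acceptance q-value cutoff (default 0.05).
#' @param seed Seed for the decoy shuffle.
#' @return Object of class `linearity_fdr`: `results` (data.frame
#'   protein, slope, intercept, r2, qvalue, accepted for scored
#'   targets), `unscored` (proteins with <3 points), `decoy_fit`,
#'   `threshold`.
#' @export
linearity_fdr <- function(mat, amounts, threshold = 0.05, seed = 1L) {
  fit_t <- fit_linearity(mat, amounts)
  decoys <- make_shuffle_decoys(mat, seed)
  fit_d <- fit_linearity(decoys, amounts)
  t_ok <- fit_t[fit_t$scored, ]
  d_ok <- fit_d[fit_d$scored, ]
  td <- target_decoy_fdr(t_ok$r2, d_ok$r2, threshold)
  res <- data.frame(protein = t_ok$protein, slope = t_ok$slope,
                    intercept = t_ok$intercept, r2 = t_ok$r2,
                    is_decoy = FALSE,
                    qvalue = td$qvalue, accepted = td$accepted,
                    stringsAsFactors = FALSE)
  structure(list(results = res,
                 unscored = fit_t$protein[!fit_t$scored],
                 decoy_fit = d_ok, threshold = threshold),
            class = "linearity_fdr")
}

#' @export
print.linearity_fdr <- function(x, ...) {
  cat(sprintf(
    "Linearity FDR: %d scored proteins (%d unscored), %d accepted at q <= %g\n",
    nrow(x$results), length(x$unscored), sum(x$results$accepted),
    x$threshold))
  cat(sprintf("  target median R2 %.4f, decoy median R2 %.4f\n",
              stats::median(x$results$r2),
              stats::median(x$decoy_fit$r2)))
  invisible(x)
}

#' @export
summary.linearity_fdr <- function(object, ...) {
  r <- object$results
  data.frame(n_scored = nrow(r), n_accepted = sum(r$accepted),
             median_r2 = stats::median(r$r2),
             median_slope = stats::median(r$slope),
             decoy_median_r2 = stats::median(object$decoy_fit$r2))
}

#' @export
plot.linearity_fdr <- function(x, ...) {
  br <- seq(0, 1, by = 0.02)
  ht <- graphics::hist(x$results$r2, breaks = br, plot = FALSE)
  hd <- graphics::hist(x$decoy_fit$r2, breaks = br, plot = FALSE)
  ylim <- c(0, max(ht$counts, hd$counts))
  graphics::plot(ht, col = grDevices::adjustcolor(4, 0.5), ylim = ylim,
       main = "Linearity score distributions", xlab = expression(R^2))
  graphics::plot(hd, col = grDevices::adjustcolor(2, 0.5), add = TRUE)
  graphics::legend("top", fill = grDevices::adjustcolor(c(4, 2), 0.5),
         legend = c("target", "decoy"), bty = "n")
  invisible(x)
}
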