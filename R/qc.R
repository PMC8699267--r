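# Quantitative QC: lognormal CV, dilution-median linearity, replicate
# correlation, abundance-decile grouping.

#' Lognormal coefficient of variation
#'
#' For multiplicative (lognormal) measurement error the CV of the
#' linear-scale intensities is `100 * sqrt(exp(s^2) - 1)` percent,
#' where `s` is the sample SD (n-1 denominator) of the natural-log
#' intensities. Accepts a vector (one protein) or a matrix (proteins x
#' replicates, NA allowed as long as >= 2 values remain).
#'
#' @param x Positive replicate intensities; vector or matrix.
#' @param log_base Set to 2 if `x` is already log2-transformed (the SD
#'   is then converted, `s_ln = s_log2 * ln 2`); default `NULL` means
#'   linear-scale input.
#' @return CV in percent (vector for matrix input).
#' @export
cv_lognormal <- function(x, log_base = NULL) {
  if (is.matrix(x)) return(apply(x, 1, cv_lognormal, log_base = log_base))
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  if (is.null(log_base)) {
    if (any(x <= 0)) stop("intensities must be positive")
    s <- stats::sd(log(x))
  } else {
    s <- stats::sd(x) * log(log_base)
  }
  100 * sqrt(exp(s^2) - 1)
}

#' Regression R of per-dilution intensity medians
#'
#' Per dilution point, the median of the log2 protein intensities; then
#' an OLS fit of these medians against log2 loaded amount. The Pearson
#' correlation coefficient R of that fit is the headline linearity
#' statistic of the dilution experiment.
#'
#' @param mat Proteins x dilution-points matrix. Linear intensities by
#'   default; set `log2_input = TRUE` if already log2.
#' @param amounts Loaded amounts (ng), one per column, >= 3 points.
#' @param log2_input Is `mat` already log2-transformed?
#' @return list: `r` (Pearson R of medians vs log2 amount), `slope`,
#'   `intercept`, `medians` (named by amount).
#' @export
dilution_median_linearity <- function(mat, amounts, log2_input = FALSE) {
  stopifnot(is.matrix(mat), ncol(mat) == length(amounts),
            length(amounts) >= 3)
  lg <- if (log2_input) mat else log2(mat)
  med <- apply(lg, 2, stats::median, na.rm = TRUE)
  if (any(is.na(med))) stop("dilution column with all values missing")
  x <- log2(amounts)
  fit <- stats::lm(med ~ x)
  list(r = stats::cor(med, x),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       medians = stats::setNames(med, amounts))
}

#' Rank proteins by intensity into balanced abundance groups
#'
#' Proteins are sorted by descending intensity (ties broken by
#' accession order) and split into `n_groups` contiguous groups whose
#' sizes differ by at most one, larger groups first. Group 1 holds the
#' most abundant proteins. If there are fewer proteins than groups,
#' `n_groups` is reduced with a warning so that no group is empty.
#'
#' @param intensity Named numeric vector (names = accessions).
#' @param n_groups Number of groups (default 10).
#' @return Named integer vector of group indices (1-based), same order
#'   as the input.
#' @export
abundance_groups <- function(intensity, n_groups = 10) {
  stopifnot(n_groups >= 1)
  n <- length(intensity)
  if (n == 0) stop("no proteins to group")
  if (n < n_groups) {
    warning("fewer proteins than groups; reducing n_groups to ", n)
    n_groups <- n
  }
  nm <- names(intensity)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  ord <- order(-intensity, nm)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra),
                                   rep(0L, n_groups - extra))
  grp_sorted <- rep.int(seq_len(n_groups), sizes)
  out <- integer(n)
  out[ord] <- grp_sorted
  stats::setNames(out, names(intensity))
}

#' Replicate Pearson correlation on the log2 scale
#'
#' Complete-case Pearson correlation of log2 intensities between two
#' replicate runs, over proteins quantified in both.
#'
#' @param a,b Named numeric vectors of linear intensities.
#' @return list: `r`, `n` (proteins in common).
#' @export
replicate_correlation <- function(a, b) {
  common <- intersect(names(a), names(b))
  common <- common[!is.na(a[common]) & !is.na(b[common])]
  if (length(common) < 3) stop("fewer than 3 proteins shared")
  list(r = stats::cor(log2(a[common]), log2(b[common])),
       n = length(common))
}

#' Assemble a QC report for a dilution or replicate experiment
#'
#' Per-protein lognormal CV across the replicates of each condition,
#' the median CV and the fraction of proteins with CV < 25% per
#' condition, and abundance-group indices from the mean intensity.
#'
#' @param mat Proteins x runs matrix of linear intensities.
#' @param conditions Vector (length `ncol(mat)`) assigning each run to
#'   a condition (e.g. dilution amount).
#' @param n_groups Abundance groups (default 10).
#' @return Object of class `qc_report`: `per_protein` (protein,
#'   condition, cv), `per_condition` (condition, median_cv,
#'   frac_cv_lt25, n), `groups` (named group index per protein).
#' @export
qc_report <- function(mat, conditions, n_groups = 10) {
  stopifnot(is.matrix(mat), length(conditions) == ncol(mat))
  per_protein <- do.call(rbind, lapply(unique(conditions), function(cd) {
    sub <- mat[, conditions == cd, drop = FALSE]
    data.frame(protein = rownames(sub), condition = cd,
               cv = cv_lognormal(sub), stringsAsFactors = FALSE)
  }))
  per_condition <- do.call(rbind, lapply(unique(conditions), function(cd) {
    v <- per_protein$cv[per_protein$condition == cd]
    v <- v[!is.na(v)]
    data.frame(condition = cd, median_cv = stats::median(v),
               frac_cv_lt25 = mean(v < 25), n = length(v),
               stringsAsFactors = FALSE)
  }))
  mean_int <- rowMeans(mat, na.rm = TRUE)
  grp <- abundance_groups(stats::setNames(mean_int, rownames(mat)),
                          min(n_groups, nrow(mat)))
  structure(list(per_protein = per_protein,
                 per_condition = per_condition, groups = grp),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  pc <- x$per_condition
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  condition %s: median CV %.2f%%, %.0f%% proteins CV<25%% (n=%d)\n",
                format(pc$condition[i]), pc$median_cv[i],
                100 * pc$frac_cv_lt25[i], pc$n[i]))
  invisible(x)
}
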