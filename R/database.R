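# The four-layer custom database: per-depletion-level identification
# sets (replicates merged by union), per-level protein intensities, and
# the minimal depletion level at which each protein was MS2-identified.

LEVEL_NAMES <- c("UNDEPLETED", "LOW_DEP", "MID_DEP", "DEEP_DEP")

#' Build the multilevel identification database
#'
#' Technical replicates within a level are merged by union: a protein
#' identified in at least one replicate belongs to the level. Per-level
#' protein intensity is the label-free rollup of that level's
#' identified features, averaged over replicate runs on the linear
#' scale. `min_level` is the minimum level at which a protein has an
#' MS2 identification; `unique_to_level` flags proteins seen at exactly
#' one level.
#'
#' @param ids Identification table covering the level runs.
#' @param features Feature table covering the same runs.
#' @param run_levels Named integer vector `run_id -> level` (1 =
#'   undepleted .. 4 = deep depletion). Level 1 must be present.
#' @param cfg A [transfer_config()] (tolerances for matching
#'   identifications to features).
#' @return Object of class `multilevel_db`.
#' @export
build_database <- function(ids, features, run_levels,
                           cfg = transfer_config()) {
  stopifnot(length(run_levels) > 0)
  if (!1L %in% run_levels) stop("UNDEPLETED (level 1) runs are required")
  if (anyDuplicated(names(run_levels)))
    stop("duplicate run_id in run_levels")
  ids <- ids[ids$run_id %in% names(run_levels), ]
  lev_of_id <- unname(run_levels[ids$run_id])

  levels_present <- sort(unique(unname(run_levels)))
  level_proteins <- lapply(1:4, function(lev)
    sort(unique(ids$protein[lev_of_id == lev])))
  min_level <- tapply(lev_of_id, ids$protein, min)
  n_levels_seen <- vapply(names(min_level), function(p)
    sum(vapply(level_proteins, function(s) p %in% s, TRUE)), 0L)

  # per-level protein intensity: attach ids to features, roll up, then
  # average over the level's replicate runs
  tol <- effective_link_tolerances(list(), cfg)
  pep <- NULL
  for (rn in intersect(unique(ids$run_id), unique(features$run_id))) {
    fi <- features[features$run_id == rn, ]
    ii <- ids[ids$run_id == rn, ]
    hit <- greedy_match_run(ii$mz, ii$rt, fi$mz, fi$rt,
                            rep(TRUE, nrow(fi)), tol$ppm, tol$rt)
    ok <- !is.na(hit)
    if (!any(ok)) next
    pep <- rbind(pep, data.frame(protein = ii$protein[ok],
                                 peptide = ii$peptide[ok],
                                 run_id = rn,
                                 intensity = fi$intensity[hit[ok]],
                                 stringsAsFactors = FALSE))
  }
  level_intensity <- matrix(NA_real_, length(min_level), 4,
                            dimnames = list(names(min_level),
                                            LEVEL_NAMES))
  if (!is.null(pep)) {
    roll <- rollup_protein_intensity(pep)
    roll$level <- unname(run_levels[roll$run_id])
    m <- tapply(roll$intensity,
                list(roll$protein, roll$level), mean)
    level_intensity[rownames(m), as.integer(colnames(m))] <- m
  }
  structure(list(proteins = names(min_level),
                 min_level = as.integer(min_level),
                 unique_to_level = n_levels_seen == 1L,
                 level_proteins = level_proteins,
                 level_intensity = level_intensity,
                 run_levels = run_levels,
                 levels_present = levels_present),
            class = "multilevel_db")
}

#' @export
print.multilevel_db <- function(x, ...) {
  cat(sprintf("Multilevel database: %d proteins over levels %s\n",
              length(x$proteins),
              paste(LEVEL_NAMES[x$levels_present], collapse = ", ")))
  tab <- table(factor(LEVEL_NAMES[x$min_level], levels = LEVEL_NAMES))
  cat("  minimal identification level:\n")
  for (nm in names(tab))
    cat(sprintf("    %-10s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' @export
summary.multilevel_db <- function(object, ...) {
  data.frame(level = LEVEL_NAMES,
             identified = vapply(object$level_proteins, length, 0L),
             min_level_here = as.integer(table(
               factor(object$min_level, levels = 1:4))),
             stringsAsFactors = FALSE)
}

#' Log2-transform, median-centre and group-filter an intensity matrix
#'
#' Intensities are log2-transformed, each run (column) is centred by
#' subtracting its median, and rows are kept only if they have at least
#' one valid (non-missing) value in every declared group. Missing
#' values stay missing; nothing is imputed.
#'
#' @param mat Numeric matrix, proteins x runs, positive or NA.
#' @param groups Optional factor/vector of length `ncol(mat)` declaring
#'   the group of each run (e.g. depletion level). `NULL` = single
#'   group.
#' @return Normalized matrix (possibly with fewer rows). Attribute
#'   `dropped` holds the rownames removed by the group filter.
#' @export
normalize_for_comparison <- function(mat, groups = NULL) {
  stopifnot(is.matrix(mat))
  if (any(mat[!is.na(mat)] <= 0))
    stop("intensities must be positive (or NA)")
  lg <- log2(mat)
  med <- apply(lg, 2, stats::median, na.rm = TRUE)
  if (any(is.na(med)))
    stop("run(s) with all values missing: ",
         paste(colnames(mat)[is.na(med)], collapse = ", "))
  lg <- sweep(lg, 2, med)
  if (is.null(groups)) groups <- rep(1L, ncol(mat))
  stopifnot(length(groups) == ncol(mat))
  keep <- rep(TRUE, nrow(lg))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    keep <- keep & rowSums(!is.na(lg[, cols, drop = FALSE])) >= 1
  }
  out <- lg[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(lg)[!keep]
  out
}

#' Abundance contrast across minimal-depletion-level categories
#'
#' Groups proteins by the minimal depletion level needed to identify
#' them, summarises undepleted log2 intensities per category (median,
#' 5th and 95th percentiles), and, when at least two categories have
#' two or more proteins, runs a one-way ANOVA with pairwise t-tests
#' (Holm-adjusted). The test is a reporting convenience, not part of
#' the transfer method itself.
#'
#' @param db A `multilevel_db`.
#' @param undepleted_intensity Named numeric vector of linear undepleted
#'   intensities (names = accessions).
#' @return list with `summary` (per-category data.frame), `anova`
#'   (fitted aov or NULL), `pairwise` (pairwise.htest or NULL),
#'   `excluded` (categories with <2 proteins).
#' @export
level_abundance_contrast <- function(db, undepleted_intensity) {
  stopifnot(inherits(db, "multilevel_db"))
  common <- intersect(db$proteins, names(undepleted_intensity))
  lev <- db$min_level[match(common, db$proteins)]
  y <- log2(undepleted_intensity[common])
  summ <- do.call(rbind, lapply(sort(unique(lev)), function(l) {
    v <- y[lev == l]
    data.frame(level = LEVEL_NAMES[l], n = length(v),
               median = stats::median(v),
               p5 = stats::quantile(v, 0.05, names = FALSE),
               p95 = stats::quantile(v, 0.95, names = FALSE),
               stringsAsFactors = FALSE)
  }))
  sizes <- table(lev)
  testable <- as.integer(names(sizes)[sizes >= 2])
  excluded <- LEVEL_NAMES[as.integer(names(sizes)[sizes < 2])]
  fit <- pw <- NULL
  if (length(testable) >= 2) {
    sel <- lev %in% testable
    g <- factor(LEVEL_NAMES[lev[sel]], levels = LEVEL_NAMES[testable])
    fit <- stats::aov(y[sel] ~ g)
    pw <- stats::pairwise.t.test(y[sel], g, p.adjust.method = "holm")
  }
  list(summary = summ, anova = fit, pairwise = pw, excluded = excluded)
}
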