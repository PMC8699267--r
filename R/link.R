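# Cross-run consensus feature linking. Linking is star-shaped around a
# designated reference run: every other run is matched against the
# reference features by greedy nearest-neighbour in (ppm distance,
# warped-RT distance) lexicographic order. Greedy with the mutual
# nearest tie-break is deterministic and near-optimal on sparse feature
# maps; each feature joins at most one consensus and a consensus holds
# at most one member per run.

#' Resolve effective linking tolerances
#'
#' When the configured link tolerances are `"auto"`, the effective
#' tolerance is the 95th percentile of the absolute anchor residuals of
#' the fitted warps, floored at 5 ppm and 0.2 min.
#'
#' @param warps List of `rt_warp` objects (may be empty).
#' @param cfg A [transfer_config()].
#' @return list(ppm =, rt =) numeric effective tolerances.
#' @export
effective_link_tolerances <- function(warps, cfg) {
  ppm <- cfg$link_ppm
  rt <- cfg$link_rt_tol
  if (identical(ppm, "auto") || identical(rt, "auto")) {
    ppm_res <- unlist(lapply(warps, function(w) w$anchors$ppm_residual))
    rt_res <- unlist(lapply(warps, function(w) w$rt_residual))
    if (identical(ppm, "auto"))
      ppm <- if (length(ppm_res))
        max(5, stats::quantile(abs(ppm_res), 0.95, names = FALSE)) else 5
    if (identical(rt, "auto"))
      rt <- if (length(rt_res))
        max(0.2, stats::quantile(abs(rt_res), 0.95, names = FALSE)) else 0.2
  }
  list(ppm = ppm, rt = rt)
}

# Greedy lexicographic matching of one target run against the reference
# features. Returns integer index into reference rows for each target
# row (NA when unmatched).
greedy_match_run <- function(tgt_mz, tgt_rt, ref_mz, ref_rt, ref_free,
                             ppm_tol, rt_tol) {
  ordr <- order(ref_mz)
  ref_mz_s <- ref_mz[ordr]
  lo <- findInterval(tgt_mz * (1 - ppm_tol * 1e-6), ref_mz_s) + 1L
  hi <- findInterval(tgt_mz * (1 + ppm_tol * 1e-6), ref_mz_s)
  cand_t <- cand_r <- integer(0)
  cand_ppm <- cand_rt <- numeric(0)
  for (i in seq_along(tgt_mz)) {
    if (lo[i] > hi[i]) next
    r <- ordr[lo[i]:hi[i]]
    drt <- abs(ref_rt[r] - tgt_rt[i])
    ok <- drt <= rt_tol & ref_free[r]
    if (!any(ok)) next
    r <- r[ok]
    cand_t <- c(cand_t, rep.int(i, length(r)))
    cand_r <- c(cand_r, r)
    cand_ppm <- c(cand_ppm, abs(ref_mz[r] - tgt_mz[i]) / tgt_mz[i] * 1e6)
    cand_rt <- c(cand_rt, drt[ok])
  }
  match_ref <- rep(NA_integer_, length(tgt_mz))
  if (!length(cand_t)) return(match_ref)
  ord <- order(cand_ppm, cand_rt, cand_t, cand_r)
  t_free <- rep(TRUE, length(tgt_mz))
  r_free <- ref_free
  for (k in ord) {
    ti <- cand_t[k]; ri <- cand_r[k]
    if (t_free[ti] && r_free[ri]) {
      match_ref[ti] <- ri
      t_free[ti] <- FALSE
      r_free[ri] <- FALSE
    }
  }
  match_ref
}

#' Link features across runs into consensus features
#'
#' @param features A feature table covering all runs (column `run_id`).
#' @param warps Named list mapping each non-reference `run_id` to its
#'   [estimate_rt_warp()] result. The reference run may be omitted or
#'   mapped to [identity_warp()].
#' @param cfg A [transfer_config()]. `"auto"` link tolerances resolve
#'   via [effective_link_tolerances()].
#' @param reference Reference `run_id`; default is the run with the
#'   most features (ties broken alphabetically).
#' @return Object of class `consensus_set`: `members` (consensus_id,
#'   run_id, feature_id, mz, rt, rt_warped, intensity, snr),
#'   `consensus` (consensus_id, mz_consensus, rt_consensus, n_members),
#'   `reference`, `tolerances`. Consensus m/z and RT are
#'   intensity-weighted means over members (RT in the reference frame).
#'   Features with S/N below `cfg$min_snr` may join a consensus but
#'   cannot seed one of their own.
#' @export
link_features <- function(features, warps, cfg = transfer_config(),
                          reference = NULL) {
  run_ids <- unique(features$run_id)
  if (is.null(reference)) {
    cnt <- table(features$run_id)
    reference <- names(cnt)[order(-cnt, names(cnt))][1]
  }
  stopifnot(reference %in% run_ids)
  others <- setdiff(run_ids, reference)
  missing_w <- setdiff(others, names(warps))
  if (length(missing_w))
    stop("missing warp for run(s): ", paste(missing_w, collapse = ", "))
  tol <- effective_link_tolerances(warps[others], cfg)

  ref <- features[features$run_id == reference, ]
  ref$rt_warped <- ref$rt
  # link order: larger runs first, then alphabetical (deterministic)
  cnt <- table(features$run_id)
  others <- others[order(-cnt[others], others)]

  member_list <- list()
  ref_consensus <- rep(NA_integer_, nrow(ref))
  next_id <- 0L
  seeds <- which(ref$snr >= cfg$min_snr)
  ref_consensus[seeds] <- seq_along(seeds)
  next_id <- length(seeds)

  for (rn in others) {
    tgt <- features[features$run_id == rn, ]
    tgt$rt_warped <- predict(warps[[rn]], tgt$rt)
    linkable <- !is.na(ref_consensus)  # only seeded reference features host
    m <- greedy_match_run(tgt$mz, tgt$rt_warped, ref$mz, ref$rt_warped,
                          linkable, tol$ppm, tol$rt)
    matched <- which(!is.na(m))
    tgt$consensus <- NA_integer_
    tgt$consensus[matched] <- ref_consensus[m[matched]]
    # unmatched high-S/N target features seed their own consensus
    solo <- which(is.na(tgt$consensus) & tgt$snr >= cfg$min_snr)
    if (length(solo)) {
      tgt$consensus[solo] <- next_id + seq_along(solo)
      next_id <- next_id + length(solo)
    }
    member_list[[rn]] <- tgt[!is.na(tgt$consensus), ]
  }
  ref$consensus <- ref_consensus
  member_list[[reference]] <- ref[!is.na(ref$consensus), ]
  members <- do.call(rbind, member_list)
  members <- members[order(members$consensus, members$run_id), ]
  members$consensus_id <- sprintf("C%06d", members$consensus)
  rownames(members) <- NULL

  w <- members$intensity
  cons <- data.frame(
    consensus_id = sort(unique(members$consensus_id)),
    stringsAsFactors = FALSE)
  agg <- function(v) rowsum(v * w, members$consensus_id)[, 1] /
    rowsum(w, members$consensus_id)[, 1]
  cons$mz_consensus <- agg(members$mz)
  cons$rt_consensus <- agg(members$rt_warped)
  cons$n_members <- as.integer(table(members$consensus_id))
  structure(list(members = members[, c("consensus_id", "run_id",
                                       "feature_id", "mz", "rt",
                                       "rt_warped", "intensity", "snr")],
                 consensus = cons, reference = reference,
                 tolerances = tol),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf(
    "Consensus set: %d consensus features over %d runs (reference %s)\n",
    nrow(x$consensus), length(unique(x$members$run_id)), x$reference))
  cat(sprintf("  effective tolerances: %.2f ppm, %.3f min\n",
              x$tolerances$ppm, x$tolerances$rt))
  cat("  members per consensus:",
      paste(names(table(x$consensus$n_members)),
            table(x$consensus$n_members), sep = "x", collapse = " "), "\n")
  invisible(x)
}

#' Align every run to a reference and link features
#'
#' Convenience wrapper: estimates one warp per non-reference run and
#' calls [link_features()].
#'
#' @inheritParams link_features
#' @return A list with `consensus` (the `consensus_set`) and `warps`.
#' @export
align_and_link <- function(features, cfg = transfer_config(),
                           reference = NULL) {
  run_ids <- unique(features$run_id)
  if (is.null(reference)) {
    cnt <- table(features$run_id)
    reference <- names(cnt)[order(-cnt, names(cnt))][1]
  }
  ref <- features[features$run_id == reference, ]
  warps <- lapply(setdiff(run_ids, reference), function(rn)
    estimate_rt_warp(features[features$run_id == rn, ], ref, cfg))
  names(warps) <- setdiff(run_ids, reference)
  list(consensus = link_features(features, warps, cfg, reference),
       warps = warps)
}
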