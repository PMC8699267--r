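# Transfer of peptide identities along consensus features, and
# label-free protein rollup.

# Attach peptide identifications to member features: an identification
# is assigned to the nearest feature of its own run within the linking
# tolerances (identifications are emitted at measured feature
# coordinates, so this is effectively exact).
match_ids_to_members <- function(members, ids, tol) {
  members$id_row <- NA_integer_
  for (rn in intersect(unique(ids$run_id), unique(members$run_id))) {
    mi <- which(members$run_id == rn)
    ii <- which(ids$run_id == rn)
    hit <- greedy_match_run(ids$mz[ii], ids$rt[ii],
                            members$mz[mi], members$rt[mi],
                            rep(TRUE, length(mi)), tol$ppm, tol$rt)
    ok <- !is.na(hit)
    members$id_row[mi[hit[ok]]] <- ii[ok]
  }
  members
}

#' Transfer peptide identifications along consensus features
#'
#' For every consensus feature carrying a peptide identity in at least
#' one run, members in runs where that peptide was not natively
#' identified receive the identity as a transfer; natively identified
#' members are flagged `native = TRUE`. A consensus whose members carry
#' two different peptide identities is a conflict error (never a vote).
#'
#' @param consensus A `consensus_set` from [link_features()].
#' @param ids An identification table ([read_id_table()] dialect).
#' @param run_levels Optional named integer vector mapping `run_id` to
#'   its depletion level (1 = undepleted .. 4 = deep depletion). When
#'   given, each transfer's `source_level` is the minimal level among
#'   the identified members of its consensus; when `NULL`,
#'   `source_level` is `NA`.
#' @param cfg A [transfer_config()] (used to re-resolve identification
#'   matching tolerances; defaults are fine when the consensus was
#'   built with defaults).
#' @return data.frame of class `transfer_records`: `consensus_id`,
#'   `protein`, `peptide`, `proteins` (list column), `run_id`,
#'   `source_level`, `intensity`, `native`. Scoring fields (Ii, Rank1,
#'   PDi, score, q-value) are filled by the FDR stage, not here.
#' @export
transfer_identifications <- function(consensus, ids, run_levels = NULL,
                                     cfg = transfer_config()) {
  stopifnot(inherits(consensus, "consensus_set"))
  members <- consensus$members
  tol <- consensus$tolerances
  members <- match_ids_to_members(members, ids, tol)
  has_id <- !is.na(members$id_row)
  id_of <- members$id_row

  # peptide identity per consensus; conflicts are an error
  idd <- members[has_id, c("consensus_id", "run_id")]
  idd$peptide <- ids$peptide[id_of[has_id]]
  if (nrow(idd)) {
    pep_per_cons <- tapply(idd$peptide, idd$consensus_id,
                           function(p) length(unique(p)))
    bad <- names(pep_per_cons)[pep_per_cons > 1]
    if (length(bad)) {
      b1 <- bad[1]
      peps <- unique(idd$peptide[idd$consensus_id == b1])
      stop("conflicting peptide identities in consensus ", b1, ": ",
           paste(peps, collapse = " vs "),
           if (length(bad) > 1)
             sprintf(" (and %d more conflicted consensus features)",
                     length(bad) - 1))
    }
  }
  cons_pep_row <- tapply(id_of[has_id], members$consensus_id[has_id],
                         function(r) r[1])
  identified_cons <- names(cons_pep_row)

  out <- members[members$consensus_id %in% identified_cons, ]
  rowi <- cons_pep_row[out$consensus_id]
  out$peptide <- ids$peptide[rowi]
  out$protein <- ids$protein[rowi]
  out$proteins <- ids$proteins[rowi]
  out$native <- !is.na(out$id_row)

  if (!is.null(run_levels)) {
    lev_member <- unname(run_levels[members$run_id])
    lev_id <- lev_member
    lev_id[!has_id] <- NA_integer_
    src <- tapply(lev_id, members$consensus_id, min, na.rm = TRUE)
    out$source_level <- as.integer(src[out$consensus_id])
  } else {
    out$source_level <- NA_integer_
  }
  out <- out[, c("consensus_id", "protein", "peptide", "proteins",
                 "run_id", "source_level", "intensity", "native")]
  out <- out[order(out$protein, out$peptide, out$run_id), ]
  rownames(out) <- NULL
  class(out) <- c("transfer_records", "data.frame")
  out
}

#' Roll peptide intensities up to protein intensities
#'
#' Protein intensity is the sum of member peptide intensities on the
#' linear scale, per run. Shared (razor) peptides, i.e. peptides whose
#' `proteins` list has more than one accession, are assigned entirely
#' to the accession with the larger total unique-peptide intensity;
#' ties break by lexicographic accession order.
#'
#' @param records data.frame with columns `peptide`, `run_id`,
#'   `intensity` and either a `proteins` list column or a `protein`
#'   column (treated as already-resolved assignment).
#' @return data.frame `protein`, `run_id`, `intensity`, ordered by
#'   protein then run.
#' @export
rollup_protein_intensity <- function(records) {
  if (nrow(records) == 0) stop("empty peptide group: nothing to roll up")
  if (!is.null(records$proteins)) {
    n_acc <- lengths(records$proteins)
    records$protein <- vapply(records$proteins, `[`, "", 1L)
    shared <- which(n_acc > 1)
    if (length(shared)) {
      uniq <- records[n_acc == 1, ]
      utot <- if (nrow(uniq))
        rowsum(uniq$intensity, uniq$protein)[, 1] else numeric(0)
      records$protein[shared] <- vapply(shared, function(i) {
        acc <- records$proteins[[i]]
        tot <- utot[acc]
        tot[is.na(tot)] <- 0
        acc[order(-tot, acc)][1]
      }, "")
    }
  }
  stopifnot(!is.null(records$protein))
  s <- rowsum(records$intensity,
              paste(records$protein, records$run_id, sep = "\r"))
  key <- rownames(s)
  out <- data.frame(protein = sub("\r.*$", "", key),
                    run_id = sub("^.*\r", "", key),
                    intensity = s[, 1], stringsAsFactors = FALSE)
  out <- out[order(out$protein, out$run_id), ]
  rownames(out) <- NULL
  out
}

#' Per-level fraction of identified proteins recovered in undepleted runs
#'
#' For each depleted level of the database, the fraction of its
#' identified proteins that either have at least one accepted transfer
#' into an undepleted run or were natively identified there. A level
#' with zero identified proteins yields `NA` (undefined), never 0.
#'
#' @param db A `multilevel_db` from [build_database()].
#' @param records `transfer_records`, after acceptance flags are set
#'   (an `accepted` column; native records count regardless).
#' @return Named numeric vector of fractions for levels 2..4 (NA where
#'   undefined).
#' @export
transfer_ratio <- function(db, records) {
  stopifnot(inherits(db, "multilevel_db"))
  undep <- names(db$run_levels)[db$run_levels == 1L]
  records <- records[records$run_id %in% undep, ]
  acc <- records$accepted
  if (is.null(acc)) acc <- rep(TRUE, nrow(records))
  recovered <- unique(records$protein[acc | records$native])
  out <- vapply(2:4, function(lev) {
    prots <- db$level_proteins[[lev]]
    if (length(prots) == 0) return(NA_real_)
    mean(prots %in% recovered)
  }, 0)
  names(out) <- c("LOW_DEP", "MID_DEP", "DEEP_DEP")
  out
}
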