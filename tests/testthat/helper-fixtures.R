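# Shared fixtures and independent oracles for the test suite.

# random feature table fixture (valid by construction)
random_feature_df <- function(n, run_id = "runA", seed = 1) {
  set.seed(seed)
  data.frame(run_id = run_id,
             feature_id = sprintf("f%04d", seq_len(n)),
             mz = round(runif(n, 350, 1500), 6),
             rt = round(runif(n, 5, 92), 4),
             charge = sample(2:4, n, replace = TRUE),
             intensity = round(2^runif(n, 18, 32), 3),
             snr = round(runif(n, 5, 500), 3),
             stringsAsFactors = FALSE)
}

write_feature_tsv <- function(df, path) {
  out <- data.frame(run_id = df$run_id, feature_id = df$feature_id,
                    mz = df$mz, rt_min = df$rt, charge = df$charge,
                    intensity = df$intensity, snr = df$snr)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# exhaustive minimum-total-distance matching oracle for two small runs:
# enumerates every injective assignment of target features to reference
# features over pairs within tolerance, keeps maximum-cardinality
# assignments, and among those minimizes total scaled distance.
brute_force_match <- function(tgt, ref, ppm_tol, rt_tol) {
  nt <- nrow(tgt); nr <- nrow(ref)
  allowed <- matrix(FALSE, nt, nr)
  dist <- matrix(Inf, nt, nr)
  for (i in seq_len(nt)) for (j in seq_len(nr)) {
    dppm <- abs(ref$mz[j] - tgt$mz[i]) / tgt$mz[i] * 1e6
    drt <- abs(ref$rt[j] - tgt$rt[i])
    if (dppm <= ppm_tol && drt <= rt_tol) {
      allowed[i, j] <- TRUE
      dist[i, j] <- dppm / ppm_tol + drt / rt_tol
    }
  }
  best <- NULL; best_card <- -1L; best_cost <- Inf
  # recursive enumeration over targets
  recurse <- function(i, used, assign, cost, card) {
    if (i > nt) {
      if (card > best_card ||
          (card == best_card && cost < best_cost)) {
        best <<- assign; best_card <<- card; best_cost <<- cost
      }
      return(invisible())
    }
    recurse(i + 1L, used, assign, cost, card)      # leave i unmatched
    for (j in which(allowed[i, ] & !used)) {
      used[j] <- TRUE; assign[i] <- j
      recurse(i + 1L, used, assign, cost + dist[i, j], card + 1L)
      used[j] <- FALSE; assign[i] <- NA_integer_
    }
  }
  recurse(1L, rep(FALSE, nr), rep(NA_integer_, nt), 0, 0L)
  best
}

# greedy matcher as exposed through link_features, reduced to an
# assignment vector (target row -> reference row or NA)
link_two_runs <- function(tgt, ref, ppm_tol, rt_tol) {
  tgt$run_id <- "tgt"; ref$run_id <- "ref"
  tgt$feature_id <- paste0("t", seq_len(nrow(tgt)))
  ref$feature_id <- paste0("r", seq_len(nrow(ref)))
  feats <- rbind(ref, tgt)
  cfg <- transfer_config(link_ppm = ppm_tol, link_rt_tol = rt_tol)
  cs <- link_features(feats, list(tgt = identity_warp()), cfg,
                      reference = "ref")
  m <- cs$members
  ref_m <- m[m$run_id == "ref", ]
  tgt_m <- m[m$run_id == "tgt", ]
  ref_of_cons <- setNames(ref_m$feature_id, ref_m$consensus_id)
  hit <- ref_of_cons[tgt_m$consensus_id]
  assign <- rep(NA_integer_, nrow(tgt))
  ok <- !is.na(hit)
  assign[as.integer(sub("^t", "", tgt_m$feature_id[ok]))] <-
    as.integer(sub("^r", "", hit[ok]))
  assign
}

# per-protein OLS oracle via stats::lm
lm_linearity_oracle <- function(mat, amounts) {
  x <- log2(amounts)
  t(apply(mat, 1, function(y) {
    ok <- !is.na(y)
    if (sum(ok) < 3) return(c(NA, NA, NA))
    f <- lm(y[ok] ~ x[ok])
    c(coef(f)[2], coef(f)[1], summary(f)$r.squared)
  }))
}

# direct-enumeration target-decoy FDR oracle
td_fdr_oracle <- function(target, decoy) {
  fdr <- sapply(target, function(s)
    sum(decoy >= s) / max(1, sum(target >= s)))
  q <- sapply(target, function(s) min(fdr[target <= s]))
  list(fdr = fdr, qvalue = q)
}
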