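# Synthetic LC-MS feature generators with known ground truth.
#
# The generators emulate the statistical structure MS1 transfer relies on:
# a 7-point dilution series with lognormal multiplicative noise, a
# depletion ladder in which progressively more high-abundance proteins are
# removed and low-abundance proteins become MS2-identifiable, smooth
# run-specific retention-time drift, ppm-scale mass error, and top-N
# MS2 censoring. They do not attempt chromatographic peak shapes, isotope
# envelopes, or missing-value mechanisms beyond censoring.

#' Simulation parameters
#'
#' @param n_proteins Number of simulated proteins.
#' @param amounts Loaded amounts (ng) of the dilution series, strictly
#'   decreasing. Default is the 7-point series 1000, 500, 200, 100, 40,
#'   20, 10 ng.
#' @param noise_sigma_ln Natural-log SD of multiplicative measurement
#'   noise between technical replicates. The default 0.08 puts the
#'   lognormal CV of replicates near 8%, inside the sub-10% band
#'   typical of well-behaved label-free experiments.
#' @param frac_nonlinear Fraction of proteins whose per-dilution
#'   intensities are drawn independently of the loaded amount
#'   (ground-truth non-linear profiles, used to stress the linearity
#'   FDR branch).
#' @param rt_drift_max Bound (minutes) on the smooth run-specific
#'   retention-time drift. The default 1.25 lets two runs drift apart
#'   by up to 2.5 min, inside the 3-min maximum shift the alignment
#'   assumes for runs from a single LC system.
#' @param ppm_sigma SD (ppm) of Gaussian mass error. Default 1.5 ppm,
#'   typical of recalibrated Orbitrap-class data (run-to-run mass
#'   differences then have SD ~2.1 ppm).
#' @param topN_ms2 Number of most-intense features per run granted an
#'   MS2 identification (DDA-style censoring).
#' @param depletion_removals Number of most-abundant proteins removed at
#'   the three depleted levels; default `c(7, 14, 60)` mirrors top7 and
#'   top14 immunodepletion and a SuperMix-style removal of ~50-60
#'   species.
#' @param n_replicates Technical replicates per condition for the
#'   depletion and plasma generators (the dilution series always uses
#'   triplicates).
#' @param frac_absent Plasma cohort only: fraction of database proteins
#'   absent from the undepleted samples (spiked false-transfer truth).
#' @param sample_sigma_ln Plasma cohort only: natural-log SD of
#'   per-sample biological variation around the shared abundance vector.
#' @param seed Integer RNG seed; every generator is bit-reproducible
#'   under a fixed seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 1250,
                       amounts = c(1000, 500, 200, 100, 40, 20, 10),
                       noise_sigma_ln = 0.08,
                       frac_nonlinear = 0,
                       rt_drift_max = 1.25,
                       ppm_sigma = 1.5,
                       topN_ms2 = 5000,
                       depletion_removals = c(7, 14, 60),
                       n_replicates = 2,
                       frac_absent = 0.15,
                       sample_sigma_ln = 0.5,
                       seed = 1L) {
  stopifnot(n_proteins >= 1, length(amounts) >= 2,
            all(diff(amounts) < 0), noise_sigma_ln >= 0,
            rt_drift_max >= 0, ppm_sigma >= 0, topN_ms2 >= 1,
            all(diff(depletion_removals) >= 0), n_replicates >= 1,
            sample_sigma_ln >= 0)
  if (frac_nonlinear < 0 || frac_nonlinear > 1)
    stop("frac_nonlinear must be in [0, 1]")
  if (frac_absent < 0 || frac_absent > 1)
    stop("frac_absent must be in [0, 1]")
  structure(list(n_proteins = as.integer(n_proteins), amounts = amounts,
                 noise_sigma_ln = noise_sigma_ln,
                 frac_nonlinear = frac_nonlinear,
                 rt_drift_max = rt_drift_max, ppm_sigma = ppm_sigma,
                 topN_ms2 = as.integer(topN_ms2),
                 depletion_removals = as.integer(depletion_removals),
                 n_replicates = as.integer(n_replicates),
                 frac_absent = frac_absent,
                 sample_sigma_ln = sample_sigma_ln,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Gradient span of the simulated LC runs (minutes).
RT_RANGE <- c(5, 92)
LOG2_ABUND_RANGE <- c(18, 38)  # ~6 orders of magnitude dynamic range

# Peptide catalog: 1-10 peptides per protein, each carrying a fixed
# fraction of the protein's intensity, a base RT, a true m/z and charge.
# The number of detectable peptide features rises with protein
# abundance (abundant proteins populate many more MS1 features), which
# is what lets immunodepletion free acquisition capacity for
# low-abundance proteins.
make_peptide_catalog <- function(n_proteins, abundance_pct = NULL) {
  accession <- sprintf("SP%05d", seq_len(n_proteins))
  n_pep <- if (is.null(abundance_pct))
    sample.int(10, n_proteins, replace = TRUE)
  else
    1L + stats::rbinom(n_proteins, 9L, 0.15 + 0.8 * abundance_pct)
  prot_idx <- rep.int(seq_len(n_proteins), n_pep)
  n_tot <- length(prot_idx)
  w_raw <- stats::runif(n_tot)
  weight <- w_raw / rep.int(rowsum(w_raw, prot_idx)[, 1], n_pep)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
          "S","T","V","W","Y")
  pep_len <- sample(8:20, n_tot, replace = TRUE)
  sequence <- vapply(pep_len, function(L)
    paste(sample(aa, L, replace = TRUE), collapse = ""), "")
  data.frame(pep_idx = seq_len(n_tot), prot_idx = prot_idx,
             protein = accession[prot_idx], peptide = sequence,
             weight = weight,
             base_rt = stats::runif(n_tot, RT_RANGE[1], RT_RANGE[2]),
             mz_true = stats::runif(n_tot, 350, 1500),
             charge = sample(2:4, n_tot, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Smooth monotone RT drift bounded by rt_drift_max: a natural cubic
# spline through 4 interior random knots, rescaled until t + drift(t)
# is strictly increasing over the gradient.
make_rt_drift <- function(rt_drift_max) {
  if (rt_drift_max <= 0) return(function(t) rep(0, length(t)))
  kx <- c(RT_RANGE[1], sort(stats::runif(4, RT_RANGE[1], RT_RANGE[2])),
          RT_RANGE[2])
  ky <- stats::runif(6, -rt_drift_max, rt_drift_max)
  f <- stats::splinefun(kx, ky, method = "natural")
  scale <- 1
  grid <- seq(RT_RANGE[1], RT_RANGE[2], length.out = 400)
  for (i in 1:20) {
    g <- grid + scale * pmax(pmin(f(grid), rt_drift_max), -rt_drift_max)
    if (all(diff(g) > 0)) break
    scale <- scale / 2
  }
  function(t) scale * pmax(pmin(f(t), rt_drift_max), -rt_drift_max)
}

# Per-run S/N: intensity over a run-adaptive noise floor (noise scales
# with total signal). Reported MS1 features sit mostly well above the
# S/N-5 detection threshold; the floor pins the 2nd percentile at 5.
assign_snr <- function(intensity) {
  floor_ <- stats::quantile(intensity, 0.02, names = FALSE) / 5
  intensity / floor_
}

# Assemble the per-run feature block for one run: measured RT, m/z,
# intensity, S/N for the catalog rows in `keep`.
run_features <- function(run_id, catalog, intensity, ppm_sigma,
                         drift_fun) {
  n <- nrow(catalog)
  rt <- catalog$base_rt + drift_fun(catalog$base_rt)
  mz <- catalog$mz_true *
    (1 + stats::rnorm(n, 0, ppm_sigma * 1e-6))
  data.frame(run_id = run_id,
             feature_id = paste0("P", catalog$pep_idx),
             mz = mz, rt = rt, charge = catalog$charge,
             intensity = intensity, snr = assign_snr(intensity),
             stringsAsFactors = FALSE)
}

# MS2 identifications for the topN most intense features of a run block.
ids_for_run <- function(block, catalog, topN) {
  keep <- order(block$intensity, decreasing = TRUE)[
    seq_len(min(topN, nrow(block)))]
  keep <- sort(keep)
  data.frame(run_id = block$run_id[keep],
             psm_id = paste0(block$run_id[keep], ":", block$feature_id[keep]),
             peptide = catalog$peptide[keep],
             charge = block$charge[keep],
             mz = block$mz[keep], rt = block$rt[keep],
             proteins = I(as.list(catalog$protein[keep])),
             protein = catalog$protein[keep],
             qvalue = stats::runif(length(keep), 0, 0.009),
             stringsAsFactors = FALSE)
}

#' Simulate a 7-point dilution series with technical triplicates
#'
#' Linear proteins have expected intensity proportional to the loaded
#' amount with multiplicative lognormal noise; a `frac_nonlinear`
#' subset receives per-dilution abundances drawn independently of the
#' amount (ground-truth non-linear profiles). Each run gets its own
#' smooth bounded RT drift and Gaussian ppm mass error. MS2
#' identifications are attached only to the `topN_ms2` most intense
#' features of the reference run (highest amount, replicate 1),
#' emulating deep DDA coverage of the undiluted standard.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `dilution_sim`: list with `features`
#'   (feature_table over all runs), `ids` (id_table for the reference
#'   run), `truth` (protein, true_log2_abundance, is_linear),
#'   `feature_truth` (run_id, feature_id, protein, peptide — the
#'   generator's own record of which peptide each feature is),
#'   `runs` (run_id, amount, replicate), `reference_run`, `params`.
#' @export
simulate_dilution_series <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_proteins
  base_log2 <- stats::runif(n, LOG2_ABUND_RANGE[1], LOG2_ABUND_RANGE[2])
  catalog <- make_peptide_catalog(n, rank(base_log2) / n)
  n_nl <- round(n * params$frac_nonlinear)
  if (params$frac_nonlinear > 0 && n_nl == 0)
    warning("frac_nonlinear > 0 but rounds to zero non-linear proteins")
  nonlinear <- rep(FALSE, n)
  if (n_nl > 0) nonlinear[sample.int(n, n_nl)] <- TRUE

  amounts <- params$amounts
  n_amt <- length(amounts)
  # per-(protein, dilution) scale: amount/max for linear proteins,
  # log-uniform over the same span, independent of amount, for
  # non-linear ones (shared across replicates within a dilution)
  scale_pd <- outer(rep(1, n), amounts / amounts[1])
  if (n_nl > 0) {
    lo <- log(min(amounts) / amounts[1])
    scale_pd[nonlinear, ] <- exp(stats::runif(n_nl * n_amt, lo, 0))
  }

  runs <- expand.grid(replicate = 1:3, amount = amounts,
                      KEEP.OUT.ATTRS = FALSE)[, 2:1]
  runs$run_id <- sprintf("dil%04d_r%d", runs$amount, runs$replicate)
  base_linear <- 2^base_log2
  pep_base <- base_linear[catalog$prot_idx] * catalog$weight

  blocks <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    d <- match(runs$amount[i], amounts)
    noise <- if (params$noise_sigma_ln > 0)
      exp(stats::rnorm(nrow(catalog), 0, params$noise_sigma_ln)) else 1
    intensity <- pep_base * scale_pd[catalog$prot_idx, d] * noise
    blocks[[i]] <- run_features(runs$run_id[i], catalog, intensity,
                                params$ppm_sigma,
                                make_rt_drift(params$rt_drift_max))
  }
  features <- do.call(rbind, blocks)
  reference_run <- runs$run_id[runs$amount == amounts[1] &
                                 runs$replicate == 1]
  ids <- id_table(ids_for_run(blocks[[match(reference_run, runs$run_id)]],
                              catalog, params$topN_ms2))
  truth <- data.frame(protein = sprintf("SP%05d", seq_len(n)),
                      true_log2_abundance = base_log2,
                      is_linear = !nonlinear, stringsAsFactors = FALSE)
  feature_truth <- data.frame(
    run_id = features$run_id, feature_id = features$feature_id,
    protein = catalog$protein[rep(seq_len(nrow(catalog)), nrow(runs))],
    peptide = catalog$peptide[rep(seq_len(nrow(catalog)), nrow(runs))],
    stringsAsFactors = FALSE)
  structure(list(features = feature_table(features), ids = ids,
                 truth = truth, feature_truth = feature_truth,
                 runs = runs[, c("run_id", "amount", "replicate")],
                 reference_run = reference_run, params = params),
            class = "dilution_sim")
}

#' Simulate a four-level depletion ladder
#'
#' Protein abundances are drawn log-uniformly over ~6 orders of
#' magnitude. At the three depleted levels the `depletion_removals`
#' most abundant proteins are removed and the remaining intensities are
#' rescaled to a constant total (constant column load). Top-N MS2
#' censoring per run then makes progressively more low-abundance
#' proteins identifiable with depletion depth; the minimal level at
#' which each protein receives an MS2 identity is recorded as
#' `level_detectable`.
#'
#' @param params A [sim_params()] object.
#' @return Object of class `depletion_sim`: `features`, `ids` (all
#'   runs), `truth` (protein, true_log2_abundance, level_detectable;
#'   NA when never identified), `feature_truth`, `runs` (run_id, level,
#'   replicate), `params`.
#' @export
simulate_depletion_runs <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (max(params$depletion_removals) >= params$n_proteins)
    stop("depletion_removals exceed n_proteins")
  set.seed(params$seed)
  n <- params$n_proteins
  base_log2 <- stats::runif(n, LOG2_ABUND_RANGE[1], LOG2_ABUND_RANGE[2])
  catalog <- make_peptide_catalog(n, rank(base_log2) / n)
  base_linear <- 2^base_log2
  removals <- c(0L, params$depletion_removals)
  abund_rank <- rank(-base_linear, ties.method = "first")
  total <- sum(base_linear)

  runs <- expand.grid(replicate = seq_len(params$n_replicates),
                      level = 1:4, KEEP.OUT.ATTRS = FALSE)[, 2:1]
  runs$run_id <- sprintf("lev%d_r%d", runs$level, runs$replicate)

  blocks <- id_blocks <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    lev <- runs$level[i]
    present <- abund_rank > removals[lev]
    scale <- total / sum(base_linear[present])
    keep_rows <- which(present[catalog$prot_idx])
    cat_i <- catalog[keep_rows, ]
    noise <- if (params$noise_sigma_ln > 0)
      exp(stats::rnorm(length(keep_rows), 0, params$noise_sigma_ln)) else 1
    intensity <- base_linear[cat_i$prot_idx] * cat_i$weight * scale * noise
    blocks[[i]] <- run_features(runs$run_id[i], cat_i, intensity,
                                params$ppm_sigma,
                                make_rt_drift(params$rt_drift_max))
    id_blocks[[i]] <- ids_for_run(blocks[[i]], cat_i, params$topN_ms2)
  }
  features <- do.call(rbind, blocks)
  ids <- do.call(rbind, id_blocks)
  # minimal depletion level at which each protein has an MS2 identity
  lev_of_run <- runs$level[match(ids$run_id, runs$run_id)]
  min_lev <- tapply(lev_of_run, ids$protein, min)
  accession <- sprintf("SP%05d", seq_len(n))
  truth <- data.frame(protein = accession,
                      true_log2_abundance = base_log2,
                      level_detectable =
                        as.integer(min_lev[accession]),
                      stringsAsFactors = FALSE)
  feature_truth <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    lev <- runs$level[i]
    present <- abund_rank > removals[lev]
    cat_i <- catalog[present[catalog$prot_idx], ]
    data.frame(run_id = b$run_id, feature_id = b$feature_id,
               protein = cat_i$protein, peptide = cat_i$peptide,
               stringsAsFactors = FALSE)
  }))
  structure(list(features = feature_table(features), ids = id_table(ids),
                 truth = truth, feature_truth = feature_truth,
                 runs = runs[, c("run_id", "level", "replicate")],
                 params = params),
            class = "depletion_sim")
}

#' Simulate an undepleted plasma cohort with spiked absent proteins
#'
#' Samples share a lognormal abundance vector (log2 intensities
#' Gaussian) with per-sample biological perturbation; the two technical
#' replicates per sample differ only by measurement noise. A
#' `frac_absent` subset of database proteins is truly absent from the
#' undepleted samples: their features are omitted entirely
#' (`true_transfer = FALSE`), providing clean ground truth for
#' false-transfer calibration. Each run also contains unidentified
#' background features drawn from the low-intensity end of the signal
#' distribution; a candidate-transfer table is emitted in which absent
#' proteins carry the intensity of a randomly linked background feature
#' (a wrong cross-run match), while present proteins carry their
#' rolled-up measured intensity.
#'
#' @param params A [sim_params()] object.
#' @param n_samples Number of cohort samples (default 10).
#' @return Object of class `plasma_sim`: `features` (all present-protein
#'   and background features, two replicate runs per sample), `truth`
#'   (protein, true_log2_abundance, true_transfer), `feature_truth`
#'   (owning protein per feature, empty for background), `candidates`
#'   (protein, run_id, intensity — one candidate transfer per database
#'   protein per sample), `reference` (accession, intensity for the
#'   truly present plasma proteins), `runs`, `params`.
#' @export
simulate_plasma_cohort <- function(params = sim_params(),
                                   n_samples = 10) {
  stopifnot(inherits(params, "sim_params"), n_samples >= 1)
  set.seed(params$seed)
  n <- params$n_proteins
  # detected plasma proteins are approximately lognormal in abundance
  base_log2 <- stats::rnorm(n, mean = 28, sd = 3)
  catalog <- make_peptide_catalog(n, rank(base_log2) / n)
  n_absent <- round(n * params$frac_absent)
  absent <- rep(FALSE, n)
  if (n_absent > 0) absent[sample.int(n, n_absent)] <- TRUE

  runs <- expand.grid(replicate = 1:2, sample = seq_len(n_samples),
                      KEEP.OUT.ATTRS = FALSE)[, 2:1]
  runs$run_id <- sprintf("smp%02d_r%d", runs$sample, runs$replicate)

  present_rows <- which(!absent[catalog$prot_idx])
  cat_p <- catalog[present_rows, ]
  base_linear <- 2^base_log2

  # per-sample biological effect, shared between replicates
  sample_eff <- matrix(
    exp(stats::rnorm(n * n_samples, 0, params$sample_sigma_ln)),
    nrow = n)

  n_bg <- max(20L, round(0.2 * nrow(cat_p)))
  bg_lo <- stats::quantile(base_log2, 0.02, names = FALSE)
  bg_hi <- stats::quantile(base_log2, 0.5, names = FALSE)

  blocks <- vector("list", nrow(runs))
  cand_list <- vector("list", n_samples)
  for (i in seq_len(nrow(runs))) {
    s <- runs$sample[i]
    noise <- if (params$noise_sigma_ln > 0)
      exp(stats::rnorm(nrow(cat_p), 0, params$noise_sigma_ln)) else 1
    intensity <- base_linear[cat_p$prot_idx] * cat_p$weight *
      sample_eff[cat_p$prot_idx, s] * noise
    block <- run_features(runs$run_id[i], cat_p, intensity,
                          params$ppm_sigma,
                          make_rt_drift(params$rt_drift_max))
    bg <- data.frame(
      run_id = runs$run_id[i],
      feature_id = sprintf("BG%05d", seq_len(n_bg)),
      mz = stats::runif(n_bg, 350, 1500),
      rt = stats::runif(n_bg, RT_RANGE[1], RT_RANGE[2]),
      charge = sample(2:4, n_bg, replace = TRUE),
      intensity = 2^stats::runif(n_bg, bg_lo, bg_hi),
      snr = NA_real_, stringsAsFactors = FALSE)
    block <- rbind(block, bg)
    block$snr <- assign_snr(block$intensity)
    blocks[[i]] <- block

    if (runs$replicate[i] == 1) {
      # candidate transfers for this sample: rolled-up intensity for
      # present proteins, a random background feature for absent ones
      prot_int <- rowsum(intensity, cat_p$prot_idx)
      cand_int <- rep(NA_real_, n)
      cand_int[as.integer(rownames(prot_int))] <- prot_int[, 1]
      cand_int[absent] <- sample(bg$intensity, n_absent, replace = TRUE)
      cand_list[[s]] <- data.frame(
        protein = sprintf("SP%05d", seq_len(n)),
        run_id = runs$run_id[i], intensity = cand_int,
        stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, blocks)
  feature_truth <- data.frame(
    run_id = features$run_id, feature_id = features$feature_id,
    protein = rep(c(cat_p$protein, rep("", n_bg)), nrow(runs)),
    stringsAsFactors = FALSE)
  truth <- data.frame(protein = sprintf("SP%05d", seq_len(n)),
                      true_log2_abundance = base_log2,
                      true_transfer = !absent, stringsAsFactors = FALSE)
  reference <- data.frame(accession = truth$protein[!absent],
                          intensity = base_linear[!absent],
                          stringsAsFactors = FALSE)
  structure(list(features = feature_table(features), truth = truth,
                 feature_truth = feature_truth,
                 candidates = do.call(rbind, cand_list),
                 reference = reference,
                 runs = runs[, c("run_id", "sample", "replicate")],
                 params = params),
            class = "plasma_sim")
}

#' Protein-by-run intensity matrix from a simulation's own provenance
#'
#' Rolls features up to proteins using the generator's ground-truth
#' feature-to-peptide record (sum of member feature intensities per
#' protein per run). This is the truth-side rollup used to build
#' regression matrices without running the transfer chain.
#'
#' @param sim A `dilution_sim` or `depletion_sim` object.
#' @return Numeric matrix, proteins x runs, NA where a protein has no
#'   features in a run.
#' @export
sim_protein_matrix <- function(sim) {
  ft <- sim$feature_truth
  stopifnot(!is.null(ft))
  run_ids <- sim$runs$run_id
  prot <- sort(unique(ft$protein))
  m <- matrix(NA_real_, length(prot), length(run_ids),
              dimnames = list(prot, run_ids))
  s <- rowsum(sim$features$intensity,
              paste(ft$protein, ft$run_id, sep = "\r"))
  key <- rownames(s)
  sp <- sub("\r.*$", "", key)
  sr <- sub("^.*\r", "", key)
  m[cbind(match(sp, prot), match(sr, run_ids))] <- s[, 1]
  m
}

#' Average log2 intensities over replicate runs of each dilution point
#'
#' @param mat Proteins x runs linear-intensity matrix (columns named by
#'   run_id).
#' @param runs data.frame with `run_id` and `amount` columns.
#' @return Proteins x dilution-points matrix of log2 intensities,
#'   columns named by amount in decreasing order.
#' @export
collapse_dilution_replicates <- function(mat, runs) {
  amounts <- sort(unique(runs$amount), decreasing = TRUE)
  out <- sapply(amounts, function(a) {
    cols <- runs$run_id[runs$amount == a]
    rowMeans(log2(mat[, cols, drop = FALSE]), na.rm = TRUE)
  })
  out[is.nan(out)] <- NA_real_
  colnames(out) <- as.character(amounts)
  out
}

#' @export
print.dilution_sim <- function(x, ...) {
  cat(sprintf(
    "Dilution-series simulation: %d proteins, %d runs (%d amounts x 3 reps), %d features\n",
    x$params$n_proteins, nrow(x$runs), length(x$params$amounts),
    nrow(x$features)))
  cat(sprintf("  non-linear proteins: %d; reference run: %s (%d MS2 ids)\n",
              sum(!x$truth$is_linear), x$reference_run, nrow(x$ids)))
  invisible(x)
}

#' @export
print.depletion_sim <- function(x, ...) {
  tab <- table(x$truth$level_detectable, useNA = "ifany")
  cat(sprintf("Depletion-ladder simulation: %d proteins, %d runs, %d features\n",
              x$params$n_proteins, nrow(x$runs), nrow(x$features)))
  cat("  minimal identification level:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
print.plasma_sim <- function(x, ...) {
  cat(sprintf("Plasma-cohort simulation: %d proteins (%d absent), %d runs, %d features\n",
              x$params$n_proteins, sum(!x$truth$true_transfer),
              nrow(x$runs), nrow(x$features)))
  invisible(x)
}
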