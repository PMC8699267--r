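# Generators: determinism, zero-noise closed forms, recovery of the
# generating model, and depletion-ladder structure.

test_that("zero-noise dilution intensities are exactly proportional to amount", {
  p <- sim_params(n_proteins = 40, noise_sigma_ln = 0, seed = 2)
  sim <- simulate_dilution_series(p)
  mat <- sim_protein_matrix(sim)
  hi <- mat[, "dil1000_r1"]
  lo <- mat[, "dil0010_r1"]
  expect_equal(unname(hi / lo), rep(100, length(hi)))
})

test_that("all three generators are bit-reproducible under a fixed seed", {
  p <- sim_params(n_proteins = 30, depletion_removals = c(2, 4, 8),
                  seed = 11)
  expect_identical(simulate_dilution_series(p)$features,
                   simulate_dilution_series(p)$features)
  expect_identical(simulate_depletion_runs(p)$features,
                   simulate_depletion_runs(p)$features)
  s1 <- simulate_plasma_cohort(p, n_samples = 2)
  s2 <- simulate_plasma_cohort(p, n_samples = 2)
  expect_identical(s1$features, s2$features)
  expect_identical(s1$candidates, s2$candidates)
  # different seed gives different draws
  p2 <- sim_params(n_proteins = 30, depletion_removals = c(2, 4, 8),
                   seed = 12)
  expect_false(identical(simulate_dilution_series(p2)$features$mz,
                         simulate_dilution_series(p)$features$mz))
})

test_that("per-protein regression on generated dilution data recovers slope 1", {
  p <- sim_params(n_proteins = 200, noise_sigma_ln = 0.2, seed = 4)
  sim <- simulate_dilution_series(p)
  lg <- collapse_dilution_replicates(sim_protein_matrix(sim), sim$runs)
  # independent oracle: stats::lm per protein
  slopes <- apply(lg, 1, function(y) {
    x <- log2(p$amounts)
    coef(lm(y ~ x))[2]
  })
  expect_lt(mean(abs(slopes - 1)), 0.1)
})

test_that("depletion ladder censors, rescales and never loses identifications with depth", {
  # censoring ratio mirrors the defaults (~2/3 of features identified)
  p <- sim_params(n_proteins = 400, topN_ms2 = 1600,
                  depletion_removals = c(7, 14, 60), seed = 6)
  sim <- simulate_depletion_runs(p)
  ids_per_level <- sapply(1:4, function(lev) {
    rr <- sim$runs$run_id[sim$runs$level == lev]
    length(unique(sim$ids$protein[sim$ids$run_id %in% rr]))
  })
  expect_true(all(diff(ids_per_level) >= 0))
  expect_gt(ids_per_level[4], ids_per_level[1])

  # the top 7 proteins contribute no features at the first depleted
  # level, so the most abundant protein present there ranks lower
  top7 <- sim$truth$protein[order(-sim$truth$true_log2_abundance)][1:7]
  ft2 <- sim$feature_truth[sim$feature_truth$run_id == "lev2_r1", ]
  expect_false(any(ft2$protein %in% top7))
  present2 <- unique(ft2$protein)
  expect_lt(max(sim$truth$true_log2_abundance[
    sim$truth$protein %in% present2]),
    max(sim$truth$true_log2_abundance))

  # level_detectable is the minimal level carrying an MS2 identity
  lev_of <- setNames(sim$runs$level, sim$runs$run_id)
  oracle <- tapply(lev_of[sim$ids$run_id], sim$ids$protein, min)
  got <- setNames(sim$truth$level_detectable, sim$truth$protein)
  expect_identical(got[names(oracle)],
                   setNames(as.integer(oracle), names(oracle)))

  # no censoring: every protein identified at every level it occurs in
  p2 <- sim_params(n_proteins = 50, topN_ms2 = 10000,
                   depletion_removals = c(2, 4, 8), seed = 6)
  sim2 <- simulate_depletion_runs(p2)
  expect_true(all(sim2$truth$level_detectable == 1L))

  # removals must leave at least one protein
  expect_error(simulate_depletion_runs(
    sim_params(n_proteins = 50, depletion_removals = c(7, 14, 60),
               seed = 1)), "exceed")
})

test_that("plasma cohort: absent proteins have no features, replicates correlate", {
  p <- sim_params(n_proteins = 150, noise_sigma_ln = 0.15,
                  frac_absent = 0.2, seed = 8)
  sim <- simulate_plasma_cohort(p, n_samples = 2)
  absent <- sim$truth$protein[!sim$truth$true_transfer]
  expect_length(absent, 30)
  # no feature in any undepleted run belongs to an absent protein
  expect_false(any(sim$feature_truth$protein %in% absent))
  # replicate correlation on rolled-up log2 intensities exceeds 0.9
  m1 <- sim$features[sim$features$run_id == "smp01_r1" &
                       !startsWith(sim$features$feature_id, "BG"), ]
  m2 <- sim$features[sim$features$run_id == "smp01_r2" &
                       !startsWith(sim$features$feature_id, "BG"), ]
  shared <- intersect(m1$feature_id, m2$feature_id)
  r <- cor(log2(m1$intensity[match(shared, m1$feature_id)]),
           log2(m2$intensity[match(shared, m2$feature_id)]))
  expect_gt(r, 0.9)

  # zero noise: replicate intensity tables identical
  p0 <- sim_params(n_proteins = 60, noise_sigma_ln = 0, seed = 8)
  s0 <- simulate_plasma_cohort(p0, n_samples = 1)
  own <- !startsWith(s0$features$feature_id, "BG")
  a <- s0$features[own & s0$features$run_id == "smp01_r1", ]
  b <- s0$features[own & s0$features$run_id == "smp01_r2", ]
  expect_equal(a$intensity[match(b$feature_id, a$feature_id)],
               b$intensity)
})
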