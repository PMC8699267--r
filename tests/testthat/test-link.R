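# Consensus feature linking: tolerance gates, greedy-vs-exhaustive
# equivalence, uniqueness and order invariance, recall/precision on
# simulated correspondence.

test_that("identical features in two runs form one two-member consensus", {
  f <- data.frame(run_id = c("a", "b"), feature_id = c("x", "x"),
                  mz = 500, rt = 30, charge = 2L,
                  intensity = 1000, snr = 50)
  cs <- link_features(feature_table(f), list(b = identity_warp()),
                      transfer_config(link_ppm = 10, link_rt_tol = 0.5),
                      reference = "a")
  expect_equal(nrow(cs$consensus), 1)
  expect_equal(cs$consensus$n_members, 2L)
  expect_equal(cs$consensus$mz_consensus, 500)
  expect_equal(cs$consensus$rt_consensus, 30)
})

test_that("features 16 ppm apart are not linked at a 10 ppm tolerance", {
  f <- data.frame(run_id = c("a", "b"), feature_id = c("x", "y"),
                  mz = c(500.0000, 500.0080), rt = 30, charge = 2L,
                  intensity = 1000, snr = 50)
  cs <- link_features(feature_table(f), list(b = identity_warp()),
                      transfer_config(link_ppm = 10, link_rt_tol = 0.5),
                      reference = "a")
  expect_equal(nrow(cs$consensus), 2)    # two singletons
  expect_true(all(cs$consensus$n_members == 1L))
  # 8 ppm apart links
  f$mz <- c(500.0000, 500.0040)
  cs2 <- link_features(feature_table(f), list(b = identity_warp()),
                       transfer_config(link_ppm = 10, link_rt_tol = 0.5),
                       reference = "a")
  expect_equal(nrow(cs2$consensus), 1)
})

test_that("greedy linking equals exhaustive minimum-distance matching on small instances", {
  ppm_tol <- 10; rt_tol <- 0.5
  for (sd in 1:25) {
    set.seed(sd)
    n <- sample(2:5, 1)
    # well-separated true positions, mild measurement jitter
    base_mz <- runif(n, 400, 1400) + seq_len(n)      # keep apart
    base_rt <- sort(runif(n, 10, 80))
    ref <- data.frame(run_id = "ref", feature_id = paste0("r", 1:n),
                      mz = base_mz * (1 + rnorm(n, 0, 1.5e-6)),
                      rt = base_rt + rnorm(n, 0, 0.05),
                      charge = 2L, intensity = runif(n, 1e5, 1e7),
                      snr = 50)
    tgt <- data.frame(run_id = "tgt", feature_id = paste0("t", 1:n),
                      mz = base_mz * (1 + rnorm(n, 0, 1.5e-6)),
                      rt = base_rt + rnorm(n, 0, 0.05),
                      charge = 2L, intensity = runif(n, 1e5, 1e7),
                      snr = 50)
    # drop a random feature from each side so some stay unmatched
    if (n > 2) {
      ref <- ref[-sample(n, 1), ]
      tgt <- tgt[-sample(n, 1), ]
    }
    got <- link_two_runs(tgt, ref, ppm_tol, rt_tol)
    oracle <- brute_force_match(tgt, ref, ppm_tol, rt_tol)
    expect_identical(got, oracle, label = paste("instance", sd))
  }
})

test_that("no feature joins two consensus features; run order does not matter", {
  p <- sim_params(n_proteins = 60, seed = 13)
  sim <- simulate_dilution_series(p)
  feats <- sim$features[sim$features$run_id %in%
                          c("dil1000_r1", "dil1000_r2", "dil0500_r1"), ]
  cfg <- transfer_config()
  ref <- feats[feats$run_id == "dil1000_r1", ]
  warps <- lapply(c(dil1000_r2 = "dil1000_r2", dil0500_r1 = "dil0500_r1"),
                  function(rn) estimate_rt_warp(
                    feats[feats$run_id == rn, ], ref, cfg))
  cs <- link_features(feats, warps, cfg, reference = "dil1000_r1")
  key <- paste(cs$members$run_id, cs$members$feature_id)
  expect_false(anyDuplicated(key) > 0)

  # permuting the block order of the input table leaves membership
  # partitions identical (consensus labels may differ)
  feats2 <- feats[order(feats$run_id, decreasing = TRUE), ]
  cs2 <- link_features(feature_table(feats2), warps, cfg,
                       reference = "dil1000_r1")
  part <- function(cs) {
    sp <- split(paste(cs$members$run_id, cs$members$feature_id),
                cs$members$consensus_id)
    sort(vapply(sp, function(g) paste(sort(g), collapse = "|"), ""))
  }
  expect_identical(unname(part(cs)), unname(part(cs2)))
})

test_that("linking recall and precision reach 0.95 on simulated correspondence", {
  p <- sim_params(n_proteins = 150, seed = 17)
  sim <- simulate_dilution_series(p)
  al <- align_and_link(sim$features, transfer_config(),
                       reference = sim$reference_run)
  m <- al$consensus$members
  ref_rows <- m$run_id == sim$reference_run
  ref_fid <- m$feature_id[ref_rows]
  ref_cons <- m$consensus_id[ref_rows]
  tgt <- m[!ref_rows, ]
  expected <- ref_cons[match(tgt$feature_id, ref_fid)]
  have <- !is.na(expected)
  recall <- mean(tgt$consensus_id[have] == expected[have])
  linked <- tgt$consensus_id %in% ref_cons
  precision <- mean((tgt$consensus_id == expected)[linked], na.rm = TRUE)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("missing warps and low-S/N seeds are handled per contract", {
  f <- rbind(random_feature_df(20, "a", 1), random_feature_df(20, "b", 1))
  expect_error(link_features(feature_table(f), list(),
                             transfer_config(), reference = "a"),
               "missing warp.*b")
  # a lone low-S/N feature cannot seed a consensus
  f2 <- data.frame(run_id = c("a", "b"), feature_id = c("x", "y"),
                   mz = c(500, 900), rt = c(30, 60), charge = 2L,
                   intensity = 1000, snr = c(50, 2))
  cs <- link_features(feature_table(f2), list(b = identity_warp()),
                      transfer_config(link_ppm = 10, link_rt_tol = 0.5),
                      reference = "a")
  expect_equal(nrow(cs$consensus), 1)    # only the S/N-50 singleton
})
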