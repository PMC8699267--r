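# Four-layer database construction, normalization, and the per-level
# abundance contrast.

mini_ids <- function(df) {
  df$psm_id <- paste0(df$run_id, "_", seq_len(nrow(df)))
  df$charge <- 2L
  df$qvalue <- 0.001
  df$proteins <- I(as.list(df$protein))
  id_table(df)
}

test_that("min_level is the minimal depletion level with an identification", {
  ids <- mini_ids(data.frame(
    run_id = c("u1", "d4a", "d4b"),
    peptide = c("AAA", "BBB", "CCC"),
    protein = c("P1", "P1", "P2"),
    mz = c(500, 600, 700), rt = c(10, 20, 30),
    stringsAsFactors = FALSE))
  feats <- feature_table(data.frame(
    run_id = c("u1", "d4a", "d4b"), feature_id = c("f1", "f2", "f3"),
    mz = c(500, 600, 700), rt = c(10, 20, 30), charge = 2L,
    intensity = c(1e5, 2e5, 3e5), snr = 50))
  rl <- c(u1 = 1L, d4a = 4L, d4b = 4L)
  db <- build_database(ids, feats, rl)
  # P2 only in SuperMix-style input -> DEEP_DEP; P1 seen undepleted
  expect_equal(db$min_level[db$proteins == "P2"], 4L)
  expect_equal(db$min_level[db$proteins == "P1"], 1L)
  expect_true(db$unique_to_level[db$proteins == "P2"])
  expect_error(build_database(ids, feats, c(d4a = 4L)), "UNDEPLETED")
})

test_that("database per-level counts match ground-truth detectability tallies", {
  p <- sim_params(n_proteins = 120, topN_ms2 = 260, seed = 29)
  sim <- simulate_depletion_runs(p)
  db <- build_database(sim$ids, sim$features,
                       setNames(sim$runs$level, sim$runs$run_id))
  truth_tally <- table(factor(sim$truth$level_detectable, levels = 1:4))
  got_tally <- table(factor(db$min_level, levels = 1:4))
  expect_equal(as.integer(got_tally), as.integer(truth_tally))

  # union merge of replicates: each level's set contains every protein
  # identified in at least one replicate of that level
  for (lev in 1:4) {
    rr <- sim$runs$run_id[sim$runs$level == lev]
    expect_setequal(db$level_proteins[[lev]],
                    unique(sim$ids$protein[sim$ids$run_id %in% rr]))
  }

  # merging is order-independent: shuffling id rows changes nothing
  set.seed(1)
  ids2 <- sim$ids[sample(nrow(sim$ids)), ]
  db2 <- build_database(ids2, sim$features,
                        setNames(sim$runs$level, sim$runs$run_id))
  expect_identical(db$min_level[order(db$proteins)],
                   db2$min_level[order(db2$proteins)])
})

test_that("normalization log2-transforms, centres medians, filters by group", {
  m <- matrix(c(4, 16, 64), 3, 1, dimnames = list(c("a", "b", "c"), "r1"))
  out <- normalize_for_comparison(m)
  expect_equal(unname(out[, 1]), c(-2, 0, 2))

  # idempotence: an already median-centred log2 matrix re-normalizes to
  # itself (feed back through on the linear scale)
  again <- normalize_for_comparison(2^out)
  expect_equal(again, out, ignore_attr = TRUE)

  # per-run medians are 0 afterwards
  set.seed(41)
  m2 <- matrix(2^runif(60, 10, 30), 15, 4,
               dimnames = list(sprintf("p%02d", 1:15), sprintf("r%d", 1:4)))
  m2[sample(60, 10)] <- NA
  out2 <- normalize_for_comparison(m2)
  meds <- apply(out2, 2, median, na.rm = TRUE)
  expect_true(all(abs(meds) < 1e-9))

  # a row missing in every run of one group is dropped
  m3 <- matrix(2^runif(12, 10, 30), 3, 4,
               dimnames = list(c("a", "b", "c"), sprintf("r%d", 1:4)))
  m3["b", 3:4] <- NA
  out3 <- normalize_for_comparison(m3, groups = c(1, 1, 2, 2))
  expect_identical(attr(out3, "dropped"), "b")
  expect_equal(rownames(out3), c("a", "c"))

  expect_error(normalize_for_comparison(matrix(c(1, -1), 1, 2)),
               "positive")
  m4 <- matrix(c(1, 2, NA, NA), 2, 2,
               dimnames = list(NULL, c("ok", "empty")))
  expect_error(normalize_for_comparison(m4), "all values missing")
})

test_that("abundance contrast orders categories and degrades gracefully", {
  # construct a database whose deeper-level proteins are less abundant
  set.seed(43)
  n_per <- 30
  prot <- sprintf("P%03d", 1:(4 * n_per))
  lev <- rep(1:4, each = n_per)
  intens <- 2^(rnorm(4 * n_per, mean = 34 - 3 * lev, sd = 0.5))
  db <- structure(list(proteins = prot, min_level = lev,
                       level_proteins = split(prot, lev),
                       run_levels = c(u = 1L)),
                  class = "multilevel_db")
  ctr <- level_abundance_contrast(db, setNames(intens, prot))
  expect_true(all(diff(ctr$summary$median) < 0))
  expect_lt(summary(ctr$anova)[[1]][["Pr(>F)"]][1], 0.001)

  # single category: summaries only, no test
  db1 <- structure(list(proteins = prot[1:10], min_level = rep(2L, 10),
                        level_proteins = list(character(0), prot[1:10],
                                              character(0), character(0)),
                        run_levels = c(u = 1L)),
                   class = "multilevel_db")
  ctr1 <- level_abundance_contrast(db1, setNames(intens[1:10], prot[1:10]))
  expect_null(ctr1$anova)
  expect_equal(nrow(ctr1$summary), 1)
})
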