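# Identity transfer along consensus features and label-free rollup.

# two-run fixture: features in "dep" (identified) and "undep"
# (unidentified), perfectly aligned so every pair links
two_run_fixture <- function(n_transfer = 20, n_native = 5, seed = 21) {
  set.seed(seed)
  n <- n_transfer + n_native
  mz <- runif(n, 400, 1400) + seq_len(n)
  rt <- sort(runif(n, 10, 80))
  dep <- data.frame(run_id = "dep", feature_id = paste0("d", 1:n),
                    mz = mz, rt = rt, charge = 2L,
                    intensity = runif(n, 1e5, 1e7), snr = 50)
  undep <- dep
  undep$run_id <- "undep"; undep$feature_id <- paste0("u", 1:n)
  ids_dep <- data.frame(run_id = "dep", psm_id = paste0("p", 1:n),
                        peptide = sprintf("PEPTIDE%02dK", 1:n),
                        charge = 2L, mz = mz, rt = rt,
                        proteins = I(as.list(sprintf("PR%03d", 1:n))),
                        qvalue = 0.001, stringsAsFactors = FALSE)
  # the last n_native peptides are natively identified in undep too
  nat <- seq_len(n)[seq_len(n) > n_transfer]
  ids <- ids_dep
  if (length(nat)) {
    ids_undep <- ids_dep[nat, ]
    ids_undep$run_id <- "undep"
    ids_undep$psm_id <- paste0("q", nat)
    ids <- rbind(ids_dep, ids_undep)
  }
  list(features = feature_table(rbind(dep, undep)),
       ids = id_table(ids),
       run_levels = c(dep = 4L, undep = 1L))
}

link_fixture <- function(fx) {
  link_features(fx$features, list(undep = identity_warp()),
                transfer_config(link_ppm = 10, link_rt_tol = 0.5),
                reference = "dep")
}

test_that("peptides identified only in a depleted run transfer with its level", {
  fx <- two_run_fixture(20, 5)
  cs <- link_fixture(fx)
  rec <- transfer_identifications(cs, fx$ids, fx$run_levels)
  transfers <- rec[!rec$native & rec$run_id == "undep", ]
  expect_equal(nrow(transfers), 20)          # counting oracle
  expect_true(all(transfers$source_level == 4L))
  natives <- rec[rec$native & rec$run_id == "undep", ]
  expect_equal(nrow(natives), 5)
  # natively identified consensus features emit no transfer into undep
  nat_pep <- natives$peptide
  expect_equal(sum(!rec$native & rec$run_id == "undep" &
                     rec$peptide %in% nat_pep), 0)
})

test_that("a native-only peptide yields native records and zero transfers", {
  fx <- two_run_fixture(0, 4)
  cs <- link_fixture(fx)
  rec <- transfer_identifications(cs, fx$ids, fx$run_levels)
  expect_equal(sum(!rec$native & rec$run_id == "undep"), 0)
  expect_equal(sum(rec$native & rec$run_id == "undep"), 4)
})

test_that("conflicting peptide identities in one consensus raise an error", {
  fx <- two_run_fixture(2, 0)
  ids <- fx$ids
  # second run claims a different peptide for the same linked feature
  extra <- ids[1, ]
  extra$run_id <- "undep"; extra$psm_id <- "clash"
  extra$peptide <- "DIFFERENTK"
  cs <- link_fixture(fx)
  expect_error(
    transfer_identifications(cs, id_table(rbind(ids, extra)),
                             fx$run_levels),
    "conflicting peptide identities.*PEPTIDE01K|DIFFERENTK")
})

test_that("rollup sums peptides, resolves razor peptides, conserves intensity", {
  # closed-form cases
  one <- data.frame(protein = "A", peptide = "X", run_id = "r",
                    intensity = 1000)
  expect_equal(rollup_protein_intensity(one)$intensity, 1000)
  two <- data.frame(protein = "A", peptide = c("X", "Y"), run_id = "r",
                    intensity = c(100, 200))
  expect_equal(rollup_protein_intensity(two)$intensity, 300)

  # razor: shared peptide goes to the protein with larger unique total
  shared <- data.frame(
    peptide = c("u1", "u2", "s"),
    proteins = I(list("A", "B", c("A", "B"))),
    run_id = "r", intensity = c(100, 500, 50), stringsAsFactors = FALSE)
  out <- rollup_protein_intensity(shared)
  expect_equal(out$intensity[out$protein == "B"], 550)
  expect_equal(out$intensity[out$protein == "A"], 100)
  # tie: lexicographically first accession wins
  tie <- shared
  tie$intensity <- c(100, 100, 50)
  out2 <- rollup_protein_intensity(tie)
  expect_equal(out2$intensity[out2$protein == "A"], 150)

  # conservation over a generated 50-protein fixture
  set.seed(31)
  n <- 300
  recs <- data.frame(protein = sample(sprintf("P%02d", 1:50), n, TRUE),
                     peptide = sprintf("pep%03d", 1:n),
                     run_id = sample(c("r1", "r2"), n, TRUE),
                     intensity = runif(n, 1e3, 1e7))
  roll <- rollup_protein_intensity(recs)
  expect_equal(sum(roll$intensity), sum(recs$intensity))
  expect_error(rollup_protein_intensity(recs[0, ]), "empty")
})

test_that("transfer fractions per level count recovered proteins, NA when empty", {
  p <- sim_params(n_proteins = 100, topN_ms2 = 220, seed = 19)
  sim <- simulate_depletion_runs(p)
  db <- build_database(sim$ids, sim$features,
                       setNames(sim$runs$level, sim$runs$run_id))
  # all proteins of each level recovered
  rec <- data.frame(protein = db$proteins,
                    run_id = "lev1_r1",
                    native = TRUE, accepted = TRUE,
                    stringsAsFactors = FALSE)
  expect_equal(unname(transfer_ratio(db, rec)), rep(1, 3))
  # 8 of 10 recovered
  lev2 <- db$level_proteins[[2]]
  rec2 <- data.frame(protein = lev2[seq_len(floor(0.8 * length(lev2)))],
                     run_id = "lev1_r1", native = FALSE, accepted = TRUE,
                     stringsAsFactors = FALSE)
  r <- transfer_ratio(db, rec2)
  expect_equal(unname(r["LOW_DEP"]),
               floor(0.8 * length(lev2)) / length(lev2))
  # a level with zero identified proteins reports NA, not 0
  ids3 <- sim$ids[sim$ids$run_id %in% c("lev1_r1", "lev2_r1"), ]
  db3 <- build_database(ids3, sim$features,
                        setNames(sim$runs$level, sim$runs$run_id))
  expect_true(is.na(transfer_ratio(db3, rec)["DEEP_DEP"]))
})
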