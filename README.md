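# ms1transfer

Match-between-runs transfer of peptide identifications at the MS1
level, with target–decoy validation of the transfers — for proteomics
researchers who want to identify low-abundance plasma proteins in
*undepleted* samples by borrowing MS2 evidence from immunodepleted
runs, and for anyone who needs a testbed for match-between-runs error
control.

## The method

Plasma spans ~10 orders of magnitude in protein concentration; DDA
acquisition of undepleted plasma identifies only the abundant end. The
workflow implemented here:

1. **Four-layer database.** Runs of undepleted plasma and of three
   depletion depths (top7, top14, SuperMix-style ≈ 60 proteins) are
   searched by MS2 upstream; identifications are merged by union over
   technical replicates and each protein records the minimal depletion
   level at which it became identifiable (`build_database()`).
2. **Alignment and linking.** Runs are aligned by a monotone RT warp
   fitted to mutually nearest anchor features (≤ 10 ppm, ≤ 3 min,
   S/N ≥ 5) and features are linked across runs into consensus
   features by greedy nearest-neighbour matching within data-adaptive
   tolerances (`estimate_rt_warp()`, `link_features()`).
3. **Transfer and quantification.** A peptide identified in a depleted
   run transfers its identity to the linked, unidentified feature in
   the undepleted run; protein intensity is the sum of its peptides'
   precursor intensities (`transfer_identifications()`,
   `rollup_protein_intensity()`).
4. **Error control.** Two target–decoy FDR procedures validate the
   transfers, both accepting at q ≤ 0.05:
   * *Dilution linearity* (`linearity_fdr()`): per-protein OLS of log2
     intensity on log2 loaded amount over a 7-point series
     (1000…10 ng); the R² is the score, decoys are column-wise
     intensity permutations, FDR(s) = #{decoys ≥ s}/#{targets ≥ s}.
   * *Empirical plasma score* (`empirical_fdr()`): score =
     (Rank1/N + PDi)/2 from the protein's intensity rank and its
     plasma probability PDi — a Laplace-smoothed reference CDF of
     known plasma-protein intensities; decoys are drawn from a
     Gaussian fitted to the candidates' log2 intensities.
5. **QC.** Lognormal CV (100·√(exp(s²)−1)), per-dilution median
   regression, replicate correlation, abundance deciles
   (`qc_report()`, `dilution_median_linearity()`,
   `abundance_groups()`).

Synthetic-data generators (`simulate_dilution_series()`,
`simulate_depletion_runs()`, `simulate_plasma_cohort()`) produce
feature tables with known ground truth — dilution structure, depletion
ladders, RT drift, ppm mass error, top-N MS2 censoring — so the whole
chain is testable end to end without instrument data.

## Worked example

```r
library(ms1transfer)

p   <- sim_params(n_proteins = 300, seed = 42)
sim <- simulate_dilution_series(p)
al  <- align_and_link(sim$features, transfer_config(),
                      reference = sim$reference_run)
al$consensus
#> Consensus set: 2522 consensus features over 21 runs (reference dil1000_r1)
#>   effective tolerances: 5.00 ppm, 0.200 min

rec  <- transfer_identifications(al$consensus, sim$ids)
roll <- rollup_protein_intensity(rec)
lg   <- collapse_dilution_replicates(intensity_long_to_matrix(roll),
                                     sim$runs)
dilution_median_linearity(lg, p$amounts, log2_input = TRUE)$r
#> [1] 0.9993448

linearity_fdr(lg, p$amounts, threshold = 0.05, seed = 43)
#> Linearity FDR: 299 scored proteins (0 unscored), 299 accepted at q <= 0.05
#>   target median R2 0.9996, decoy median R2 0.1791
```

The medians of the transferred protein intensities regress on the
loaded amount with R = 0.9993 — the transfer preserves quantitative
linearity over two orders of magnitude of input — and the target–decoy
procedure accepts the (here all truly linear) proteins while decoy
profiles score far below them. A `qc_report()` on the same matrix
shows per-dilution median CVs of 3–5% with ≥ 95% of proteins below
25% CV.

A command-line surface wrapping the same functions ships in
`inst/cli/ms1transfer.R`:

```sh
Rscript inst/cli/ms1transfer.R simulate-dilution --config cfg.txt --out-dir sim/
Rscript inst/cli/ms1transfer.R transfer --config cfg.txt \
  --features sim/features.tsv --ids sim/ids.tsv --out-dir out/
```

Subcommands: `simulate-dilution`, `simulate-plasma`, `align`,
`transfer`, `fdr-linearity`, `fdr-empirical`, `qc`. Every run writes a
parameter sidecar and is bit-reproducible under a fixed `--seed`.

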