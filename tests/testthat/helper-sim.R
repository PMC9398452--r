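# shared fixtures built in code

# a constant-value hmd track
const_track <- function(value, n_bins = 4000, chrom = "chr1", bin_size = 25) {
  hmd_track(rep(value, n_bins), chrom = chrom, bin_size = bin_size)
}

# run the estimation pipeline on a simulated data set
run_sim_pipeline <- function(config, threshold = 1) {
  ann <- sim_annotations(config)
  cov <- sim_coverage(ann, config)
  hmd <- lapply(cov$replicates, function(r)
    compute_hmd_track(r$chip, r$input,
                      spikein_enrichment(r$spikein_chip, r$spikein_input)))
  eff <- te_effect_table(hmd, ann$tes, threshold = threshold)
  list(annotations = ann, coverage = cov, hmd = hmd, effects = eff,
       averaged = average_te_effects(eff))
}

# expected extent averaged over a truth table's per-side decay lengths
truth_expected_extent <- function(truth, mean_input_coverage, n_mc = 100) {
  mapply(function(a, ll, lr) {
    (expected_extent_mc(a, ll, mean_input_coverage, n_mc = n_mc) +
       expected_extent_mc(a, lr, mean_input_coverage, n_mc = n_mc)) / 2
  }, truth$amplitude, truth$lambda_left, truth$lambda_right)
}
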