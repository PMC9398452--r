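test_that("local background is the pooled median of the 20-40 kb regions", {
  tr <- const_track(2, n_bins = 6000)  # 150 kb
  expect_equal(local_background(tr, 70000, 72000), 2)

  # TE near the chromosome start: only the right-side region contributes
  expect_equal(local_background(const_track(1, 6000), 5000, 7000), 1)

  # brute-force median oracle on a random instance
  set.seed(7)
  vals <- runif(6000, 0.5, 3)
  vals[sample(6000, 500)] <- NA
  tr2 <- hmd_track(vals, "chr1")
  got <- local_background(tr2, 70000, 72000)
  lo_idx <- which((seq_len(6000) - 0.5) * 25 >= 30000 &
                    (seq_len(6000) - 0.5) * 25 < 50000)
  hi_idx <- which((seq_len(6000) - 0.5) * 25 >= 92000 &
                    (seq_len(6000) - 0.5) * 25 < 112000)
  pool <- sort(vals[c(lo_idx, hi_idx)])
  expect_equal(got, median(pool))

  # all-missing background region: unestimable
  tr3 <- hmd_track(rep(NA_real_, 6000), "chr1")
  expect_true(is.na(local_background(tr3, 70000, 72000)))
})

test_that("window m-HMD is the median of background-normalized units", {
  v <- rep(1, 8000); v[floor(72000 / 25) + 1:40] <- 3
  tr <- hmd_track(v, "chr1")
  w <- window_mhmd(tr, 72000, "right", background = 1.5)
  expect_equal(w[1], 2)          # 40 units of 3.0 over background 1.5
  expect_equal(length(w), 20)

  # fewer than 10 non-missing units makes the window missing
  v2 <- rep(NA_real_, 8000); v2[floor(72000 / 25) + 1:9] <- 3
  w2 <- window_mhmd(hmd_track(v2, "chr1"), 72000, "right", background = 1)
  expect_true(is.na(w2[1]))

  # median oracle on unsorted values
  set.seed(5)
  v3 <- runif(8000, 0, 4)
  tr3 <- hmd_track(v3, "chr1")
  w3 <- window_mhmd(tr3, 72000, "right", background = 2)
  idx <- floor(72000 / 25) + 1:40
  expect_equal(w3[1], median(sort(v3[idx] / 2)))

  # background propagation and validation
  expect_true(all(is.na(window_mhmd(tr3, 72000, "right", NA))))
  expect_error(window_mhmd(tr3, 72000, "right", 0), "background")
})

test_that("magnitude averages the two first windows with one-sided fallback", {
  expect_equal(effect_magnitude(2, 3), 2.5)
  expect_equal(effect_magnitude(NA, 1.8), 1.8)
  expect_equal(effect_magnitude(1, 1), 1)
  expect_true(is.na(effect_magnitude(NA, NA)))
})

test_that("extent counts the consecutive above-threshold run from the TE", {
  expect_equal(effect_extent(c(1.4, 1.2, 0.9, 1.3)), 2)
  expect_equal(effect_extent(c(0.8, 1.5, 1.5)), 0)
  expect_equal(effect_extent(rep(1.5, 20)), 20)
  expect_true(is.na(effect_extent(c(NA, 1.5))))
  # non-increasing in the threshold (0.75 / 1.0 / 1.25 robustness sweep)
  set.seed(19)
  for (i in 1:50) {
    w <- runif(20, 0.5, 2)
    e <- vapply(c(0.75, 1, 1.25), function(th) effect_extent(w, th), 1)
    expect_true(all(diff(e) <= 0))
  }
})

test_that("magnitude is invariant to scaling the whole HMD track", {
  cfg <- sim_config(genome_length = 1e6, n_tes = 4, n_genes = 0,
                    mean_input_coverage = 30, min_te_spacing = 50000,
                    seed = 23)
  res <- run_sim_pipeline(cfg)
  scaled <- lapply(res$hmd, function(tracks)
    lapply(tracks, function(tr) hmd_track(tr$values * 3.7, tr$chrom)))
  eff2 <- te_effect_table(scaled, res$annotations$tes)
  expect_equal(eff2$magnitude, res$effects$magnitude, tolerance = 1e-12)
  expect_equal(eff2$extent, res$effects$extent)
})

test_that("replicate averaging uses the available replicate when one is missing", {
  eff <- data.frame(te_id = c("a", "a", "b", "b"), replicate = c(1, 2, 1, 2),
                    background = c(1, 1, 1, 1), mag_left = c(2, 4, NA, 3),
                    mag_right = c(2, 4, NA, 3), magnitude = c(2, 4, NA, 3),
                    extent_left = c(1, 3, NA, 2), extent_right = c(1, 3, NA, 2),
                    extent = c(1, 3, NA, 2))
  avg <- average_te_effects(eff)
  expect_equal(avg$magnitude[avg$te_id == "a"], 3)
  expect_equal(avg$magnitude[avg$te_id == "b"], 3)
  expect_equal(avg$extent[avg$te_id == "b"], 2)
})

test_that("two-genome estimates standardize by the homologous flank", {
  n <- 8000
  te <- data.frame(chrom = "chr1", start = 100000, end = 102000, id = "te1")
  base <- rep(1, n)
  focal <- base; alt <- base
  lidx <- floor(te$start / 25) - 39:0; ridx <- floor(te$end / 25) + 1:40
  focal[c(lidx, ridx)] <- 3
  alt[c(lidx, ridx)] <- 1.5
  hf <- list(chr1 = hmd_track(focal, "chr1"))
  ha <- list(chr1 = hmd_track(alt, "chr1"))
  got <- two_genome_effect(hf, ha, te)
  expect_equal(got$magnitude, 2)

  ident <- two_genome_effect(hf, hf, te)
  expect_equal(ident$magnitude, 1)
  expect_equal(ident$extent, 0)

  pk <- data.frame(chrom = "chr1", start = 99000, end = 103000)
  expect_equal(two_genome_effect(hf, ha, te, shared_peaks = pk)$excluded,
               "shared_peak")
  expect_equal(two_genome_effect(hf, ha, te,
                                 homology = function(pos, chrom) NA)$excluded,
               "unmapped")
  alt_tes <- data.frame(chrom = "chr1", start = 102500, end = 103500)
  expect_equal(two_genome_effect(hf, ha, te, alt_tes = alt_tes)$excluded,
               "alt_te_within_1kb")
})

test_that("side-asymmetry z-scores normalize by the SD of side differences", {
  z <- side_asymmetry_z(c(2, 1, -1, 1), c(0, 1, 1, 1))
  expect_equal(z$z[1], 2 / sd(c(2, 0, -2, 0)))  # 1.2247
  expect_equal(z$z[1], 1.224745, tolerance = 1e-6)

  allzero <- side_asymmetry_z(c(1, 1, 1), c(1, 1, 1))
  expect_true(all(allzero$z == 0))
  expect_error(side_asymmetry_z(2, 0), "at least two")
  expect_error(side_asymmetry_z(c(2, 2), c(0, 0)), "SD")
})

test_that("the genic side is the side of the nearest highly expressed gene", {
  tes <- data.frame(chrom = "chr1", start = c(50000, 80000),
                    end = c(52000, 82000), id = c("te1", "te2"))
  genes <- data.frame(chrom = "chr1", start = c(45000, 90000),
                      end = c(47000, 92000), id = c("gHi", "gLo"),
                      true_rpkm = c(50, 2))
  side <- te_genic_side(tes, genes, max_distance = 20000)
  expect_equal(side[1], "left")    # expressed gene 3 kb to the left
  expect_true(is.na(side[2]))      # only a lowly expressed gene within range
})

test_that("null simulations give magnitude ~1 and the Monte-Carlo false-run extent", {
  cfg <- sim_config(genome_length = 6e6, n_chromosomes = 2, n_tes = 60,
                    n_genes = 0, spread_amplitude = 0,
                    mean_input_coverage = 50, min_te_spacing = 80000,
                    seed = 29)
  res <- run_sim_pipeline(cfg)
  avg <- res$averaged
  expect_equal(mean(avg$magnitude, na.rm = TRUE), 1, tolerance = 0.03)
  # noise symmetry: per-replicate magnitudes exceed 1 about half the time
  per_rep <- res$effects$magnitude
  p <- binom.test(sum(per_rep > 1, na.rm = TRUE),
                  sum(!is.na(per_rep)))$p.value
  expect_gt(p, 0.01)
  null_extent <- expected_extent_mc(0, 2000, 50, n_mc = 400)
  expect_lt(abs(mean(avg$extent, na.rm = TRUE) - null_extent), 1)
})
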