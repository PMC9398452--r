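#' Simulate ChIP and input coverage with spike-in counts
#'
#' Draws per-bin fragment counts for ChIP and matching input samples such
#' that the spike-in-normalized ratio (chip/input)/E_si has, in expectation,
#' the configured HMD surface: a flat background plus, around every TE, an
#' exponential-decay excess A_i * exp(-d / lambda) measured from the TE
#' boundary. Within the TE body the excess is A_i. On the side of a TE whose
#' nearest gene (within 20 kb) has a true expression of at least
#' \code{high_rpkm}, lambda is multiplied by \code{genic_restraint_factor},
#' emulating restrained spreading toward active promoters.
#'
#' @param annotations Result of \code{\link{sim_annotations}}.
#' @param config The same \code{\link{sim_config}} used for the annotations.
#' @return A list with \code{replicates} (each with named per-chromosome
#'   integer vectors \code{chip} and \code{input}, plus scalar
#'   \code{spikein_chip}/\code{spikein_input} barcode counts), \code{truth}
#'   (per-TE amplitude, per-side decay lengths, true magnitude),
#'   \code{expected_hmd} (noise-free per-bin HMD per chromosome) and the
#'   \code{config}.
#' @export
sim_coverage <- function(annotations, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  tes <- annotations$tes
  genes <- annotations$genes
  bs <- config$bin_size
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  n_bins <- ceiling(config$genome_length / bs)

  # per-TE amplitudes
  n_te <- nrow(tes)
  if (n_te > 0 && config$spread_amplitude > 0 && config$amplitude_cv > 0) {
    shp <- 1 / config$amplitude_cv^2
    amp <- stats::rgamma(n_te, shape = shp,
                         scale = config$spread_amplitude / shp)
  } else {
    amp <- rep(config$spread_amplitude, n_te)
  }

  # per-side decay lengths: restrained toward nearby highly expressed genes
  lam <- config$decay_length
  lam_left <- rep(lam, n_te)
  lam_right <- rep(lam, n_te)
  if (n_te > 0 && nrow(genes) > 0 && config$genic_restraint_factor < 1) {
    hi <- genes[genes$true_rpkm >= config$high_rpkm, , drop = FALSE]
    for (i in seq_len(n_te)) {
      g <- hi[hi$chrom == tes$chrom[i], , drop = FALSE]
      if (!nrow(g)) next
      dl <- tes$start[i] - g$end   # genes entirely left of the TE
      dr <- g$start - tes$end[i]   # genes entirely right of the TE
      if (any(dl >= 0 & dl <= 20000))
        lam_left[i] <- lam * config$genic_restraint_factor
      if (any(dr >= 0 & dr <= 20000))
        lam_right[i] <- lam * config$genic_restraint_factor
    }
  }

  # expected HMD per bin (bin centers), per chromosome
  expected <- lapply(chroms, function(ch) {
    mu <- rep(config$background_hmd, n_bins)
    centers <- (seq_len(n_bins) - 0.5) * bs
    idx <- which(tes$chrom == ch)
    for (i in idx) {
      s <- tes$start[i]; e <- tes$end[i]
      inside <- centers >= s & centers < e
      mu[inside] <- mu[inside] + amp[i]
      left <- centers < s & centers >= s - 30000
      mu[left] <- mu[left] + amp[i] * exp(-(s - centers[left]) / lam_left[i])
      right <- centers >= e & centers < e + 30000
      mu[right] <- mu[right] + amp[i] * exp(-(centers[right] - e) / lam_right[i])
    }
    mu
  })
  names(expected) <- chroms

  replicates <- lapply(seq_len(config$n_replicates), function(r) {
    input <- lapply(expected, function(mu)
      sim_counts(length(mu), config$mean_input_coverage,
                 config$noise_dispersion))
    chip <- lapply(expected, function(mu)
      sim_counts(length(mu),
                 config$mean_input_coverage * mu * config$spikein_ratio,
                 config$noise_dispersion))
    names(input) <- chroms; names(chip) <- chroms
    list(chip = chip, input = input,
         spikein_input = stats::rpois(1, config$spikein_mean_input),
         spikein_chip = stats::rpois(1, config$spikein_mean_input *
                                       config$spikein_ratio))
  })

  truth <- data.frame(
    te_id = tes$id, chrom = tes$chrom, start = tes$start, end = tes$end,
    amplitude = amp, lambda_left = lam_left, lambda_right = lam_right,
    stringsAsFactors = FALSE)
  truth$true_magnitude <- if (n_te) {
    (expected_first_window_mhmd(amp, lam_left, config$background_hmd) +
       expected_first_window_mhmd(amp, lam_right, config$background_hmd)) / 2
  } else numeric()

  list(replicates = replicates, truth = truth, expected_hmd = expected,
       config = config)
}

#' Noise-free m-HMD of the first 1-kb flanking window
#'
#' The m-HMD of a window is the median of its background-normalized 25-bp
#' units; for a monotone exponential decay the noise-free median equals the
#' value at the median bin-center distance (~500 bp for a 1-kb window).
#'
#' @param amplitude Amplitude A (vectorized).
#' @param decay_length Decay length lambda in bp (vectorized).
#' @param background Background HMD.
#' @param window Window width in bp.
#' @param bin_size Bin size in bp.
#' @return Expected m-HMD of the window adjacent to the TE boundary.
#' @export
expected_first_window_mhmd <- function(amplitude, decay_length,
                                       background = 1, window = 1000,
                                       bin_size = 25) {
  d <- (seq_len(window / bin_size) - 0.5) * bin_size
  med_d <- stats::median(d)
  1 + amplitude * exp(-med_d / decay_length) / background
}

#' Mean HMD over the first flanking window under exponential decay
#'
#' Closed-form mean of background + A * exp(-d / lambda) over d in
#' (0, window): background + A * (lambda / window) * (1 - exp(-window/lambda)).
#'
#' @inheritParams expected_first_window_mhmd
#' @return Expected mean HMD over the window.
#' @export
expected_flank_mean_hmd <- function(amplitude, decay_length, background = 1,
                                    window = 1000) {
  background + amplitude * (decay_length / window) *
    (1 - exp(-window / decay_length))
}

#' Expected extent (run length) of detectable spreading, by Monte Carlo
#'
#' Simulates, from the generator's noise model alone (not the estimation
#' code), the m-HMD of each 1-kb flanking window -- the median of 40 ratios of
#' ChIP to input counts divided by the spike-in ratio -- and returns the
#' expected number of consecutive windows, starting at the TE boundary, whose
#' m-HMD exceeds the threshold. This is the ground-truth run length against
#' which the pipeline's estimated extent is compared.
#'
#' @param amplitude Amplitude A at the boundary (scalar).
#' @param decay_length Decay length lambda in bp (scalar).
#' @param mean_input_coverage Mean input fragment count per bin.
#' @param spikein_ratio True spike-in ratio.
#' @param background Background HMD.
#' @param threshold m-HMD threshold defining the run (default 1).
#' @param n_windows Number of 1-kb windows per side.
#' @param min_units Minimum non-missing units per window.
#' @param min_input Input count below which a bin is missing.
#' @param n_mc Monte-Carlo replicates.
#' @param dispersion Extra-Poisson dispersion (0 = Poisson).
#' @return Expected run length in kb (a scalar in [0, n_windows]).
#' @export
expected_extent_mc <- function(amplitude, decay_length,
                               mean_input_coverage = 20, spikein_ratio = 1,
                               background = 1, threshold = 1,
                               n_windows = 20, min_units = 10, min_input = 5,
                               n_mc = 200, dispersion = 0) {
  bs <- 25
  nb <- 1000 / bs
  medians <- matrix(NA_real_, n_mc, n_windows)
  for (w in seq_len(n_windows)) {
    d <- (w - 1) * 1000 + (seq_len(nb) - 0.5) * bs
    m <- background + amplitude * exp(-d / decay_length)
    mu_chip <- mean_input_coverage * (m / background) * spikein_ratio
    # note: HMD is chip/input/spikein and m-HMD divides by the background;
    # mu_chip above folds the background normalization into the mean.
    I <- matrix(sim_counts(n_mc * nb, mean_input_coverage, dispersion),
                n_mc, nb)
    C <- matrix(sim_counts(n_mc * nb, rep(mu_chip, each = n_mc), dispersion),
                n_mc, nb)
    ratio <- (C / I) / spikein_ratio
    ratio[I < min_input] <- NA
    medians[, w] <- apply(ratio, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < min_units) NA_real_ else stats::median(v)
    })
  }
  above <- !is.na(medians) & medians > threshold
  runs <- apply(above, 1, function(a) {
    r <- 0L
    for (x in a) { if (!x) break; r <- r + 1L }
    r
  })
  mean(runs)
}
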