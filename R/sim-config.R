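#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generator. The
#' generator emulates the statistical structure that the downstream estimators
#' assume: a flat euchromatic background of spike-in-normalized histone
#' modification density (HMD) around 1, exponential-decay enrichment of
#' H3K9me2 spreading outward from each TE boundary, restrained spreading on
#' the side of a TE that faces the promoter of a highly expressed gene, and
#' Poisson (optionally negative-binomial) fragment-count noise in both ChIP
#' and input tracks.
#'
#' @param genome_length Chromosome length in bp.
#' @param n_chromosomes Number of chromosomes.
#' @param n_tes Total number of TE insertions to place.
#' @param te_length_range Length range (bp) from which TE lengths are drawn.
#' @param n_genes Total number of genes to place.
#' @param gene_length Gene length in bp.
#' @param spread_amplitude Mean HMD excess A at the TE boundary (dimensionless).
#' @param amplitude_cv Coefficient of variation of the per-TE amplitude.
#'   Per-TE amplitudes are Gamma distributed with mean \code{spread_amplitude};
#'   0 makes every TE share the same amplitude.
#' @param decay_length Exponential decay length lambda of the spreading, bp.
#' @param genic_restraint_factor Multiplier in (0, 1] applied to
#'   \code{decay_length} on the side of a TE facing a gene whose true
#'   expression is at least \code{high_rpkm} RPKM.
#' @param high_rpkm RPKM cutoff defining a highly expressed gene.
#' @param background_hmd Background HMD level (dimensionless).
#' @param noise_dispersion Extra-Poisson dispersion; 0 gives Poisson counts,
#'   values > 0 give negative-binomial counts with size 1/noise_dispersion.
#' @param mean_input_coverage Mean fragment coverage per 25-bp bin in input.
#' @param spikein_ratio True ratio of spike-in barcode fragments, ChIP/input.
#' @param spikein_mean_input Expected barcode fragment count in the input.
#' @param bin_size Bin size in bp (25 matches the estimation pipeline).
#' @param n_replicates Number of ChIP/input replicates to simulate.
#' @param min_te_spacing Minimum distance in bp between placed TEs. Large
#'   values keep each TE's flanking windows and 20-40 kb background region
#'   free of signal from neighbouring TEs.
#' @param n_strains Number of population strains for presence/absence evidence.
#' @param singleton_fraction Fraction of TEs present only in the focal genome.
#' @param degraded_fraction Fraction of strain x TE evidence sets that are
#'   degraded (single boundary contig only), exercising the "missing" path.
#' @param seed Integer seed; identical seed and config give identical output.
#'
#' @return An object of class \code{"sim_config"} (a validated list).
#' @export
sim_config <- function(genome_length = 1e6,
                       n_chromosomes = 1,
                       n_tes = 10,
                       te_length_range = c(500, 5000),
                       n_genes = 10,
                       gene_length = 2000,
                       spread_amplitude = 2,
                       amplitude_cv = 0.5,
                       decay_length = 2000,
                       genic_restraint_factor = 0.5,
                       high_rpkm = 10,
                       background_hmd = 1,
                       noise_dispersion = 0,
                       mean_input_coverage = 20,
                       spikein_ratio = 1,
                       spikein_mean_input = 2000,
                       bin_size = 25,
                       n_replicates = 2,
                       min_te_spacing = 0,
                       n_strains = 20,
                       singleton_fraction = 0.5,
                       degraded_fraction = 0,
                       seed = 1L) {
  cfg <- list(genome_length = genome_length, n_chromosomes = n_chromosomes,
              n_tes = n_tes, te_length_range = te_length_range,
              n_genes = n_genes, gene_length = gene_length,
              spread_amplitude = spread_amplitude, amplitude_cv = amplitude_cv,
              decay_length = decay_length,
              genic_restraint_factor = genic_restraint_factor,
              high_rpkm = high_rpkm,
              background_hmd = background_hmd,
              noise_dispersion = noise_dispersion,
              mean_input_coverage = mean_input_coverage,
              spikein_ratio = spikein_ratio,
              spikein_mean_input = spikein_mean_input,
              bin_size = bin_size, n_replicates = n_replicates,
              min_te_spacing = min_te_spacing,
              n_strains = n_strains,
              singleton_fraction = singleton_fraction,
              degraded_fraction = degraded_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$genome_length > 0, cfg$n_chromosomes >= 1)
  if (cfg$spread_amplitude < 0) stop("spread_amplitude must be >= 0")
  if (cfg$decay_length <= 0) stop("decay_length must be > 0")
  if (cfg$genic_restraint_factor <= 0 || cfg$genic_restraint_factor > 1)
    stop("genic_restraint_factor must be in (0, 1]")
  if (cfg$background_hmd <= 0) stop("background_hmd must be > 0")
  if (cfg$mean_input_coverage < 5)
    stop("mean_input_coverage must be >= 5 on average")
  if (cfg$spikein_ratio <= 0) stop("spikein_ratio must be > 0")
  if (cfg$noise_dispersion < 0) stop("noise_dispersion must be >= 0")
  if (length(cfg$te_length_range) != 2L ||
      cfg$te_length_range[1] > cfg$te_length_range[2] ||
      cfg$te_length_range[1] <= 0)
    stop("te_length_range must be an increasing positive pair")
  if (cfg$singleton_fraction < 0 || cfg$singleton_fraction > 1 ||
      cfg$degraded_fraction < 0 || cfg$degraded_fraction > 1)
    stop("fractions must be in [0, 1]")
  invisible(cfg)
}

# draw counts under the configured noise model
sim_counts <- function(n, mu, dispersion = 0) {
  if (dispersion > 0) {
    stats::rnbinom(n, size = 1 / dispersion, mu = mu)
  } else {
    stats::rpois(n, mu)
  }
}
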