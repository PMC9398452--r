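#' Generate synthetic TE and gene annotations
#'
#' Places non-overlapping TE insertions and genes on the configured
#' chromosomes, together with a (whole-chromosome) euchromatin boundary file
#' and a per-gene true expression level. Coordinates are 0-based half-open
#' throughout.
#'
#' TEs are distributed round-robin over chromosomes and placed by rejection
#' sampling subject to no overlap and \code{min_te_spacing}. Genes are placed
#' afterwards in the remaining space, so TE-gene distances span the full range
#' from adjacent to tens of kb. True gene expression is drawn log-normally so
#' that a realistic minority of genes exceed the \code{high_rpkm} cutoff.
#'
#' @param config A \code{\link{sim_config}} object.
#' @return A list with elements \code{tes} (data.frame: chrom, start, end, id,
#'   family, class, strand, length), \code{genes} (data.frame: chrom, start,
#'   end, id, strand, true_rpkm), and \code{euchromatin} (data.frame of
#'   euchromatic intervals).
#' @export
sim_annotations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))

  n_te_per_chrom <- tabulate(rep(seq_len(config$n_chromosomes),
                                 length.out = config$n_tes),
                             nbins = config$n_chromosomes)
  n_gene_per_chrom <- tabulate(rep(seq_len(config$n_chromosomes),
                                   length.out = config$n_genes),
                               nbins = config$n_chromosomes)

  # capacity check before attempting placement
  need <- n_te_per_chrom * (config$te_length_range[2] + config$min_te_spacing) +
    n_gene_per_chrom * config$gene_length
  if (any(need > config$genome_length))
    stop("requested elements exceed genome capacity")

  te_rows <- list(); gene_rows <- list()
  te_i <- 0L; gene_i <- 0L
  families <- c("famA", "famB", "famC", "famD", "famE")
  classes <- c("TIR/DNA", "LTR", "non-LTR/LINE")

  for (ci in seq_len(config$n_chromosomes)) {
    placed <- matrix(numeric(0), ncol = 2)  # occupied intervals [start, end)
    # --- TEs, with spacing between TE copies
    for (k in seq_len(n_te_per_chrom[ci])) {
      len <- round(stats::runif(1, config$te_length_range[1],
                                config$te_length_range[2]))
      pos <- place_interval(placed, len, config$genome_length,
                            pad = config$min_te_spacing)
      if (is.null(pos)) stop("requested elements exceed genome capacity")
      placed <- rbind(placed, pos)
      te_i <- te_i + 1L
      te_rows[[te_i]] <- data.frame(
        chrom = chroms[ci], start = pos[1], end = pos[2],
        id = sprintf("te%04d", te_i),
        family = sample(families, 1),
        class = sample(classes, 1),
        strand = "+", stringsAsFactors = FALSE)
    }
    # --- genes, no spacing requirement
    for (k in seq_len(n_gene_per_chrom[ci])) {
      len <- config$gene_length
      pos <- place_interval(placed, len, config$genome_length, pad = 0)
      if (is.null(pos)) stop("requested elements exceed genome capacity")
      placed <- rbind(placed, pos)
      gene_i <- gene_i + 1L
      gene_rows[[gene_i]] <- data.frame(
        chrom = chroms[ci], start = pos[1], end = pos[2],
        id = sprintf("gene%04d", gene_i),
        strand = sample(c("+", "-"), 1),
        stringsAsFactors = FALSE)
    }
  }

  tes <- if (te_i) do.call(rbind, te_rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               id = character(), family = character(), class = character(),
               strand = character(), stringsAsFactors = FALSE)
  genes <- if (gene_i) do.call(rbind, gene_rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               id = character(), strand = character(),
               stringsAsFactors = FALSE)

  if (nrow(tes)) {
    tes <- tes[order(tes$chrom, tes$start), , drop = FALSE]
    tes$length <- tes$end - tes$start
    rownames(tes) <- NULL
  } else tes$length <- numeric()
  if (nrow(genes)) {
    genes$true_rpkm <- stats::rlnorm(nrow(genes), meanlog = log(5), sdlog = 1.5)
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  } else genes$true_rpkm <- numeric()

  euchromatin <- data.frame(chrom = chroms, start = 0,
                            end = config$genome_length,
                            stringsAsFactors = FALSE)
  list(tes = tes, genes = genes, euchromatin = euchromatin)
}

# rejection-sample a free interval of length len; pad applies on both sides
place_interval <- function(placed, len, genome_length, pad = 0,
                           max_tries = 2000L) {
  for (i in seq_len(max_tries)) {
    s <- floor(stats::runif(1, 0, genome_length - len))
    e <- s + len
    if (nrow(placed) == 0 ||
        all(e + pad <= placed[, 1] | placed[, 2] + pad <= s))
      return(c(s, e))
  }
  NULL
}
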