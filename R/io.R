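#' Read and write binned coverage/HMD tracks as bedGraph
#'
#' Tracks are stored 0-based half-open, one line per bin; missing bins are
#' omitted on export and come back as NA on import (an optional companion
#' mask can be written with \code{write_missing_mask}).
#'
#' @param track An \code{\link{hmd_track}} (or any per-bin numeric vector
#'   wrapped by it).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "hmd_track"))
  bs <- track$bin_size
  ok <- which(!is.na(track$values))
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = (ok - 1L) * bs + 1L, width = bs),
    score = track$values[ok])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_track_bedgraph
#' @param chrom Chromosome to extract.
#' @param n_bins Number of bins of the track (bins absent from the file are
#'   NA); inferred from the last covered bin when NULL.
#' @param bin_size Bin width in bp.
#' @export
read_track_bedgraph <- function(path, chrom, n_bins = NULL, bin_size = 25) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- as.data.frame(gr)
  df <- df[as.character(df$seqnames) == chrom, , drop = FALSE]
  idx <- (df$start - 1L) / bin_size + 1L
  if (is.null(n_bins)) n_bins <- max(idx)
  v <- rep(NA_real_, n_bins)
  v[idx] <- df$score
  hmd_track(v, chrom = chrom, bin_size = bin_size)
}

#' Read/write interval annotations as BED6
#'
#' Feature data.frames use 0-based half-open coordinates with columns chrom,
#' start, end, id, strand (BED name and strand fields); for TEs the family
#' travels in the score-less name field as "id|family".
#'
#' @param features data.frame with chrom, start, end, id, optional family
#'   and strand.
#' @param path File path.
#' @return \code{path} invisibly, or the imported data.frame.
#' @export
write_bed6 <- function(features, path) {
  name <- if (!is.null(features$family))
    paste(features$id, ifelse(is.na(features$family), ".", features$family),
          sep = "|") else features$id
  strand <- if (is.null(features$strand)) "+" else features$strand
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = strand, name = name, score = 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  df <- as.data.frame(rtracklayer::import(path, format = "BED"))
  nm <- strsplit(as.character(df$name), "|", fixed = TRUE)
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start - 1L, end = df$end,
                    id = vapply(nm, `[`, "", 1),
                    family = vapply(nm, function(x)
                      if (length(x) > 1) x[2] else NA_character_, ""),
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  out$family[out$family == "."] <- NA_character_
  out
}

#' Write a plain TSV (convenience wrapper)
#'
#' @param x data.frame.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
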