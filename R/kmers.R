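#' Count canonical k-mers in a set of reads
#'
#' Counts every k-long substring of each read, collapsing each k-mer with its
#' reverse complement into the lexicographically smaller (canonical) form so
#' that both strands contribute to the same entry. Reads shorter than k are
#' skipped; k-mers containing non-ACGT characters are ignored.
#'
#' @param reads Character vector of read sequences, or a
#'   \code{Biostrings::DNAStringSet}, or the path to a FASTA file.
#' @param k k-mer length (default 12).
#' @param normalizer Optional scalar normalizer (e.g. the number of uniquely
#'   mapped reads at MAPQ >= 30, supplied externally).
#' @return A list of class \code{"kmer_table"}: k, counts (named integer
#'   vector over canonical k-mers), normalizer.
#' @export
count_kmers <- function(reads, k = 12, normalizer = NA_real_) {
  if (k <= 0) stop("k must be positive")
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads)
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  reads <- toupper(reads)
  kmers <- unlist(lapply(reads, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1), k:L)
  }), use.names = FALSE)
  kmers <- kmers[grepl("^[ACGT]+$", kmers)]
  counts <- integer(0)
  if (length(kmers)) {
    canon <- canonical_kmer(kmers)
    tab <- table(canon)
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(k = k, counts = counts, normalizer = normalizer),
            class = "kmer_table")
}

# canonical form: min(kmer, reverse complement), elementwise
canonical_kmer <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table> k=%d, %d distinct canonical k-mers, %d total\n",
              x$k, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Identify enriched k-mers between IP and input
#'
#' A k-mer is enriched when its normalized count in the IP sample is at
#' least \code{fold} times its normalized count in the input (inclusive
#' threshold). k-mers present in the IP but absent from the input are
#' treated as infinitely enriched and included.
#'
#' @param ip,input \code{kmer_table}s with positive normalizers (e.g.
#'   uniquely mapped MAPQ >= 30 read counts).
#' @param fold Enrichment threshold (default 3).
#' @return Character vector of enriched canonical k-mers.
#' @export
enriched_kmers <- function(ip, input, fold = 3.0) {
  stopifnot(inherits(ip, "kmer_table"), inherits(input, "kmer_table"),
            ip$k == input$k)
  if (is.na(ip$normalizer) || is.na(input$normalizer) ||
      ip$normalizer <= 0 || input$normalizer <= 0)
    stop("both tables need a positive normalizer")
  in_counts <- input$counts[names(ip$counts)]
  in_counts[is.na(in_counts)] <- 0
  # cross-multiplied comparison avoids spurious exclusion of exact-fold
  # ratios through floating-point division
  lhs <- as.numeric(ip$counts) * input$normalizer
  rhs <- fold * as.numeric(in_counts) * ip$normalizer
  names(ip$counts)[in_counts == 0 | lhs >= rhs]
}

#' Normalized abundance of a repeat k-mer set
#'
#' Sum of the counts of the set's members divided by the normalizer
#' (typically the total read count of a PCR-free whole-genome library), so
#' abundance is comparable between libraries of different depth.
#'
#' @param counts A \code{kmer_table} (e.g. from whole-genome reads).
#' @param het_kmers Non-empty character vector of canonical k-mers (the
#'   heterochromatic repeat set).
#' @param normalizer Positive scalar; defaults to the table's normalizer.
#' @return Normalized abundance (counts per normalizer unit).
#' @export
repeat_abundance <- function(counts, het_kmers, normalizer = NULL) {
  stopifnot(inherits(counts, "kmer_table"))
  if (!length(het_kmers)) stop("empty k-mer set")
  if (is.null(normalizer)) normalizer <- counts$normalizer
  if (is.na(normalizer) || normalizer <= 0)
    stop("a positive normalizer is required")
  hits <- counts$counts[intersect(het_kmers, names(counts$counts))]
  sum(hits) / normalizer
}
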