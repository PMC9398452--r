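#' Link each TE to its nearest gene
#'
#' Distance is 0 for TEs overlapping a gene; ties between equidistant genes
#' are broken toward the lexicographically smaller gene id. Orientation is
#' strand-aware: a TE upstream of the transcription start site is 5', one
#' downstream of the gene is 3'; overlapping TEs get NA orientation.
#'
#' @param tes TE data.frame (chrom, start, end, id).
#' @param genes Gene data.frame (chrom, start, end, id, strand).
#' @return data.frame with te_id, gene_id, distance, orientation and the
#'   TE's location category. TEs on chromosomes without genes are omitted.
#' @export
nearest_gene_links <- function(tes, genes) {
  rows <- list()
  categories <- te_location_category(tes, genes)
  for (i in seq_len(nrow(tes))) {
    g <- genes[genes$chrom == tes$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- pmax(pmax(g$start - tes$end[i], tes$start[i] - g$end), 0)
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[order(g$id[best])][1L]
    gi <- g[best, , drop = FALSE]
    orientation <- NA_character_
    if (d[best] > 0) {
      te_left <- tes$end[i] <= gi$start  # TE entirely left of gene
      orientation <- if (gi$strand == "+") {
        if (te_left) "5'" else "3'"
      } else {
        if (te_left) "3'" else "5'"
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      te_id = tes$id[i], gene_id = gi$id, distance = d[best],
      orientation = orientation, location_category = categories[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(te_id = character(), gene_id = character(),
                      distance = numeric(), orientation = character(),
                      location_category = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Gene-body H3K9me2 enrichment
#'
#' Mean of the non-missing HMD bins over each gene body; genes overlapped by
#' any TE are excluded (their enrichment cannot be attributed to spreading
#' from a nearby TE).
#'
#' @param hmd Named list of \code{hmd_track}s.
#' @param genes Gene data.frame (chrom, start, end, id).
#' @param tes TE data.frame used for the exclusion rule.
#' @return data.frame with gene_id, genic_hmd (NA when excluded or when all
#'   bins are missing) and excluded flag.
#' @export
genic_hmd <- function(hmd, genes, tes) {
  out <- data.frame(gene_id = genes$id, genic_hmd = NA_real_,
                    excluded = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    hit <- any(tes$chrom == genes$chrom[i] &
                 tes$start < genes$end[i] & tes$end > genes$start[i])
    if (hit) { out$excluded[i] <- TRUE; next }
    tr <- hmd[[genes$chrom[i]]]
    if (is.null(tr)) next
    v <- tr$values[bins_in_range(tr, genes$start[i], genes$end[i])]
    v <- v[!is.na(v)]
    if (length(v)) out$genic_hmd[i] <- mean(v)
  }
  out
}

#' Replicate-averaged expression and expression ranks
#'
#' Averages RPKM over the two replicates, drops genes with 0 RPKM in both
#' replicates, optionally restricts to a shared-ortholog list, and ranks the
#' retained genes from the highest expressed (rank 1) downward with average
#' ranks for ties.
#'
#' @param rpkm_rep1,rpkm_rep2 Named numeric vectors (gene id -> RPKM) or
#'   two-column data.frames (gene_id, rpkm).
#' @param orthologs Optional character vector of gene ids to retain.
#' @return data.frame with gene_id, rpkm_rep1, rpkm_rep2, rpkm_mean,
#'   expression_rank.
#' @export
expression_ranks <- function(rpkm_rep1, rpkm_rep2, orthologs = NULL) {
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$rpkm, x$gene_id) else x
  }
  r1 <- as_named(rpkm_rep1); r2 <- as_named(rpkm_rep2)
  ids <- intersect(names(r1), names(r2))
  if (!length(ids)) stop("replicate tables share no gene ids")
  if (!is.null(orthologs)) ids <- intersect(ids, orthologs)
  out <- data.frame(gene_id = ids, rpkm_rep1 = r1[ids], rpkm_rep2 = r2[ids],
                    stringsAsFactors = FALSE)
  out <- out[!(out$rpkm_rep1 == 0 & out$rpkm_rep2 == 0), , drop = FALSE]
  out$rpkm_mean <- (out$rpkm_rep1 + out$rpkm_rep2) / 2
  out$expression_rank <- rank(-out$rpkm_mean, ties.method = "average")
  rownames(out) <- NULL
  out
}

#' Allele z-score for gene-body H3K9me2 between strains
#'
#' z = (mean of the TE-carrying allele's per-bin HMD - mean of the TE-free
#' homologous allele's) / SD of the combined per-bin values of both alleles.
#' Positive z: the TE-carrying allele is more enriched.
#'
#' @param hmd_with Per-bin HMD values of the allele adjacent to the TE.
#' @param hmd_without Homologous allele values in the strain without the TE.
#' @return The z-score.
#' @export
allele_z <- function(hmd_with, hmd_without) {
  hmd_with <- hmd_with[!is.na(hmd_with)]
  hmd_without <- hmd_without[!is.na(hmd_without)]
  if (length(hmd_with) < 2 || length(hmd_without) < 2)
    stop("need at least two non-missing bins per allele")
  s <- stats::sd(c(hmd_with, hmd_without))
  if (s == 0) stop("pooled SD is zero: z undefined")
  (mean(hmd_with) - mean(hmd_without)) / s
}

#' Allele z-score for expression rank between strains
#'
#' z = (mean rank with TE - mean rank without TE) / SD of the four
#' per-replicate rank values. Positive z: lower expression (larger rank) on
#' the TE-carrying allele.
#'
#' @param rank_with Per-replicate expression ranks of the TE-carrying allele
#'   (length 2).
#' @param rank_without Per-replicate ranks of the TE-free allele (length 2).
#' @return The z-score.
#' @examples
#' expression_allele_z(c(110, 130), c(90, 110))  # 20 / 16.33 = 1.2247
#' @export
expression_allele_z <- function(rank_with, rank_without) {
  if (anyNA(rank_with) || anyNA(rank_without) ||
      length(rank_with) != 2L || length(rank_without) != 2L)
    stop("two per-replicate ranks are required for each allele")
  s <- stats::sd(c(rank_with, rank_without))
  if (s == 0) stop("SD of rank values is zero: z undefined")
  (mean(rank_with) - mean(rank_without)) / s
}
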