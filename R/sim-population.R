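#' Simulate population presence/absence evidence for TEs
#'
#' For every TE and population strain, draws a true present/absent state and
#' emits contig-to-genome alignment rows with the geometry the caller
#' expects: present strains contribute two boundary contigs (each reaching 40
#' bp inside and 25 bp outside the TE), absent strains contribute a single
#' contig whose split alignment reaches 60 bp beyond both TE boundaries, and
#' degraded evidence sets contribute only one boundary contig (which should
#' be called missing).
#'
#' A configured fraction of TEs are singletons (absent from every population
#' strain); the remaining TEs are present in each strain with a per-TE
#' frequency drawn uniformly from (0.2, 0.9).
#'
#' @param tes TE annotation data.frame (chrom, start, end, id).
#' @param config A \code{\link{sim_config}}.
#' @return A list with \code{alignments} (data.frame: strain, te_id, contig,
#'   chrom, tstart, tend), \code{truth} (per TE x strain true state) and
#'   \code{frequency_truth} (per-TE class, "low" or "high").
#' @export
sim_population <- function(tes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n_te <- nrow(tes)
  strains <- sprintf("strain%02d", seq_len(config$n_strains))

  singleton <- stats::runif(n_te) < config$singleton_fraction
  freq <- ifelse(singleton, 0, stats::runif(n_te, 0.2, 0.9))

  rows <- vector("list", n_te * config$n_strains)
  truth <- vector("list", n_te * config$n_strains)
  k <- 0L
  for (i in seq_len(n_te)) {
    s <- tes$start[i]; e <- tes$end[i]; ch <- tes$chrom[i]; id <- tes$id[i]
    for (j in seq_len(config$n_strains)) {
      k <- k + 1L
      present <- stats::runif(1) < freq[i]
      degraded <- stats::runif(1) < config$degraded_fraction
      cid <- function(tag) sprintf("%s_%s_%s", id, strains[j], tag)
      if (degraded) {
        # one boundary contig only: not enough for any call
        aln <- data.frame(contig = cid("c1"), chrom = ch,
                          tstart = s - 25, tend = s + 40,
                          stringsAsFactors = FALSE)
        state <- "missing"
      } else if (present) {
        aln <- data.frame(contig = c(cid("c1"), cid("c2")), chrom = ch,
                          tstart = c(s - 25, e - 40),
                          tend = c(s + 40, e + 25),
                          stringsAsFactors = FALSE)
        state <- "present"
      } else {
        # split alignment of one spanning contig across the empty site
        aln <- data.frame(contig = cid("c3"), chrom = ch,
                          tstart = c(s - 60, e),
                          tend = c(s, e + 60),
                          stringsAsFactors = FALSE)
        state <- "absent"
      }
      aln$strain <- strains[j]; aln$te_id <- id
      rows[[k]] <- aln
      truth[[k]] <- data.frame(te_id = id, strain = strains[j],
                               state = state, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  # realized frequency class: high if truly present in >= 1 strain
  freq_class <- vapply(tes$id, function(id) {
    st <- truth$state[truth$te_id == id]
    if (any(st == "present")) "high" else "low"
  }, character(1))
  list(alignments = do.call(rbind, rows),
       truth = truth,
       frequency_truth = data.frame(te_id = tes$id, class = freq_class,
                                    stringsAsFactors = FALSE))
}
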