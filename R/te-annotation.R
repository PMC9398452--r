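#' Iterative family assignment from alignment hit tables
#'
#' Assigns each TE to a family when at least \code{min_frac} (default 80%) of
#' its covered query bases align to one and only one family. The reference
#' set grows between rounds: a subject may be either a family identifier or
#' the id of a TE assigned in an earlier round, so TEs diverged from the
#' reference families can be recruited through already-assigned copies.
#'
#' @param hits data.frame with columns te_id, subject, qstart, qend (query
#'   coordinates, 0-based half-open) and optionally evalue (rows with
#'   evalue > 1e-5 are dropped).
#' @param subject_families Optional named character vector mapping subject
#'   identifiers to family names; subjects not in the map and not an
#'   assigned TE id are taken to be family names themselves.
#' @param rounds Number of assignment rounds (default 4: the initial round
#'   plus three repeats).
#' @param min_frac Minimum fraction of covered query bases in a single
#'   family.
#' @return Named character vector: family per TE id (NA = unassigned).
#' @export
assign_families <- function(hits, subject_families = NULL, rounds = 4,
                            min_frac = 0.8) {
  if (!is.null(hits$evalue)) hits <- hits[hits$evalue <= 1e-5, , drop = FALSE]
  te_ids <- unique(hits$te_id)
  assigned <- stats::setNames(rep(NA_character_, length(te_ids)), te_ids)
  for (round in seq_len(rounds)) {
    changed <- FALSE
    prev <- assigned  # the reference set grows between rounds, not within
    for (id in te_ids[is.na(assigned)]) {
      h <- hits[hits$te_id == id, , drop = FALSE]
      fam <- resolve_family(h$subject, subject_families, prev)
      ok <- !is.na(fam)
      if (!any(ok)) next
      h <- h[ok, , drop = FALSE]; fam <- fam[ok]
      total <- union_length(h$qstart, h$qend)
      per_fam <- vapply(unique(fam), function(f) {
        sel <- fam == f
        union_length(h$qstart[sel], h$qend[sel])
      }, numeric(1))
      best <- which(per_fam >= min_frac * total)
      if (length(best) == 1L) {
        assigned[id] <- names(per_fam)[best]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  assigned
}

# subject -> family: explicit map first, then previously assigned TE ids,
# else the subject itself names a family
resolve_family <- function(subject, subject_families, assigned) {
  out <- rep(NA_character_, length(subject))
  if (!is.null(subject_families)) {
    m <- match(subject, names(subject_families))
    out[!is.na(m)] <- subject_families[m[!is.na(m)]]
  }
  te_hit <- is.na(out) & subject %in% names(assigned)
  out[te_hit] <- assigned[subject[te_hit]]
  plain <- is.na(out) & !(subject %in% names(assigned))
  if (is.null(subject_families)) {
    out[plain] <- subject[plain]
  } else {
    # with an explicit map, unmapped non-TE subjects are still family names
    out[plain] <- subject[plain]
  }
  out
}

# total length of the union of [start, end) intervals
union_length <- function(start, end) {
  if (!length(start)) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) cur_e <- max(cur_e, end[i])
    else { tot <- tot + cur_e - cur_s; cur_s <- start[i]; cur_e <- end[i] }
  }
  tot + cur_e - cur_s
}

#' Merge nearby same-family TEs and drop conflicting or excluded families
#'
#' Adjacent TEs within \code{gap} bp are merged into one record when they
#' share a family, and both removed when they belong to different families.
#' Chains are resolved left-to-right after coordinate sorting. Records whose
#' family is unassigned (NA) are neither merged nor removed, since family
#' identity cannot be compared. Afterwards, members of \code{drop_families}
#' (nearly fixed or telomere-restricted families) are removed.
#'
#' @param tes TE data.frame (chrom, start, end, id, family, ...).
#' @param gap Maximum gap in bp for merging/conflict (default 500).
#' @param drop_families Families removed outright.
#' @return The merged, filtered TE data.frame; merged records span their
#'   inputs and keep the left record's id, with length recomputed.
#' @export
merge_te_records <- function(tes, gap = 500,
                             drop_families = c("DINE-1", "HeT-A", "TART",
                                               "TAHRE")) {
  if (!nrow(tes)) return(tes)
  tes <- tes[order(tes$chrom, tes$start), , drop = FALSE]
  out <- list()
  cur <- NULL
  flush <- function(cur, out) { if (!is.null(cur)) out[[length(out) + 1]] <- cur; out }
  for (i in seq_len(nrow(tes))) {
    nxt <- tes[i, , drop = FALSE]
    if (is.null(cur)) { cur <- nxt; next }
    same_chrom <- cur$chrom == nxt$chrom
    close <- same_chrom && (nxt$start - cur$end <= gap)
    if (close && !is.na(cur$family) && !is.na(nxt$family)) {
      if (cur$family == nxt$family) {
        cur$end <- max(cur$end, nxt$end)           # merged span
      } else {
        cur <- NULL                                 # conflict: drop both
      }
    } else {
      out <- flush(cur, out)
      cur <- nxt
    }
  }
  out <- flush(cur, out)
  out <- do.call(rbind, out)
  if ("length" %in% names(out)) out$length <- out$end - out$start
  out <- out[is.na(out$family) | !(out$family %in% drop_families), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter TEs by length and euchromatin location
#'
#' Retains TEs of at least \code{min_length} bp lying entirely inside a
#' euchromatic interval; the heterochromatin-adjacent remainder is excluded
#' from all downstream analyses.
#'
#' @param tes TE data.frame (chrom, start, end, ...).
#' @param min_length Minimum TE length, bp (inclusive).
#' @param euchromatin data.frame of euchromatic intervals (chrom, start,
#'   end); required.
#' @return Filtered TE data.frame.
#' @export
filter_te_records <- function(tes, min_length = 500, euchromatin) {
  if (missing(euchromatin) || is.null(euchromatin))
    stop("euchromatin boundary intervals are required")
  keep <- (tes$end - tes$start) >= min_length
  inside <- vapply(seq_len(nrow(tes)), function(i) {
    any(euchromatin$chrom == tes$chrom[i] &
          euchromatin$start <= tes$start[i] &
          euchromatin$end >= tes$end[i])
  }, logical(1))
  out <- tes[keep & inside, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify TEs as full-length or truncated
#'
#' A TE is full-length when its length is at least \code{threshold} (default
#' 70%) of its family's canonical length; "unknown" when the family or its
#' canonical length is unavailable.
#'
#' @param length TE length(s), bp.
#' @param canonical_length Canonical family length(s), bp (NA = unknown).
#' @param threshold Fraction of the canonical length (inclusive).
#' @return Character vector: "full", "truncated" or "unknown".
#' @examples
#' classify_te_length(c(750, 500, 900), c(1000, 1000, NA))
#' @export
classify_te_length <- function(length, canonical_length, threshold = 0.7) {
  out <- ifelse(is.na(canonical_length), "unknown",
                ifelse(length >= threshold * canonical_length,
                       "full", "truncated"))
  as.character(out)
}

#' Categorize TE insertion locations relative to genes
#'
#' exonic if overlapping any exon, else intronic if within a gene span, else
#' intergenic (precedence exon > intron).
#'
#' @param tes TE data.frame (chrom, start, end).
#' @param genes Gene data.frame (chrom, start, end).
#' @param exons Optional exon data.frame; defaults to the gene bodies
#'   (single-exon gene models).
#' @return Character vector along rows of \code{tes}.
#' @export
te_location_category <- function(tes, genes, exons = NULL) {
  if (is.null(exons)) exons <- genes
  vapply(seq_len(nrow(tes)), function(i) {
    ex <- any(exons$chrom == tes$chrom[i] &
                exons$start < tes$end[i] & exons$end > tes$start[i])
    if (ex) return("exonic")
    gn <- any(genes$chrom == tes$chrom[i] &
                genes$start < tes$end[i] & genes$end > tes$start[i])
    if (gn) "intronic" else "intergenic"
  }, character(1))
}
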