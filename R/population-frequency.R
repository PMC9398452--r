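#' Calling parameters for TE presence/absence
#'
#' @param span_pad Minimum bp a spanning contig must reach beyond both TE
#'   boundaries for an absence call.
#' @param inside_min Minimum bp a boundary contig must align inside the TE.
#' @param outside_min Minimum bp a boundary contig must align outside the TE.
#' @param total_min Minimum total aligned length of a boundary contig.
#' @return A list of calling parameters.
#' @export
freq_call_params <- function(span_pad = 20, inside_min = 30,
                             outside_min = 20, total_min = 50) {
  list(span_pad = span_pad, inside_min = inside_min,
       outside_min = outside_min, total_min = total_min)
}

#' Call the presence/absence state of one TE in one strain
#'
#' Decision rules, applied to contig-to-genome alignments near the TE:
#' \itemize{
#'   \item absent: a single contig whose alignment(s) reach at least
#'     \code{span_pad} bp upstream of the TE start and \code{span_pad} bp
#'     downstream of the TE end (the contig spans the empty site);
#'   \item present: (a) two distinct contigs crossing the start and end
#'     boundary respectively, each with at least \code{inside_min} bp inside
#'     the TE, \code{outside_min} bp outside, and \code{total_min} bp aligned
#'     in total, or (b) one such boundary contig plus a different contig
#'     aligned wholly within the TE;
#'   \item missing: neither rule is met, or both rules are met
#'     (contradictory evidence).
#' }
#'
#' @param alignments data.frame of alignments near the TE, with columns
#'   contig, tstart, tend (target coordinates, 0-based half-open). Malformed
#'   rows (non-positive spans, NA coordinates) are rejected with a warning.
#' @param te_start,te_end TE boundaries.
#' @param params \code{\link{freq_call_params}}.
#' @return One of "present", "absent", "missing".
#' @export
call_te_state <- function(alignments, te_start, te_end,
                          params = freq_call_params()) {
  if (is.null(alignments) || nrow(alignments) == 0) return("missing")
  bad <- is.na(alignments$tstart) | is.na(alignments$tend) |
    alignments$tend <= alignments$tstart
  if (any(bad)) {
    warning(sum(bad), " malformed alignment row(s) rejected")
    alignments <- alignments[!bad, , drop = FALSE]
    if (!nrow(alignments)) return("missing")
  }
  p <- params
  # absence: one contig spanning beyond both boundaries
  reach <- tapply(seq_len(nrow(alignments)), alignments$contig, function(i) {
    c(min(alignments$tstart[i]), max(alignments$tend[i]))
  })
  absent_evidence <- any(vapply(reach, function(r)
    r[1] <= te_start - p$span_pad && r[2] >= te_end + p$span_pad,
    logical(1)))

  len <- alignments$tend - alignments$tstart
  cross_start <- alignments$tstart <= te_start - p$outside_min &
    alignments$tend >= te_start + p$inside_min & len >= p$total_min
  cross_end <- alignments$tend >= te_end + p$outside_min &
    alignments$tstart <= te_end - p$inside_min & len >= p$total_min
  internal <- alignments$tstart >= te_start & alignments$tend <= te_end

  c_start <- unique(alignments$contig[cross_start])
  c_end <- unique(alignments$contig[cross_end])
  c_int <- unique(alignments$contig[internal])
  both_boundaries <- length(c_start) && length(c_end) &&
    length(union(c_start, c_end)) >= 2
  boundary_plus_internal <- (length(c_start) || length(c_end)) &&
    length(setdiff(c_int, union(c_start, c_end))) >= 1
  present_evidence <- both_boundaries || boundary_plus_internal

  if (absent_evidence && present_evidence) return("missing")  # contradiction
  if (absent_evidence) return("absent")
  if (present_evidence) return("present")
  "missing"
}

#' Call TE states across all strains
#'
#' @param alignments data.frame with columns strain, te_id, contig, tstart,
#'   tend (as produced by \code{\link{sim_population}} or read from a TSV).
#' @param tes TE data.frame (id, start, end).
#' @param params \code{\link{freq_call_params}}.
#' @return data.frame with te_id, strain, state.
#' @export
call_population <- function(alignments, tes, params = freq_call_params()) {
  strains <- unique(alignments$strain)
  rows <- list()
  aln_split <- split(alignments, list(alignments$te_id, alignments$strain),
                     drop = TRUE)
  for (i in seq_len(nrow(tes))) {
    for (s in strains) {
      key <- paste(tes$id[i], s, sep = ".")
      a <- aln_split[[key]]
      rows[[length(rows) + 1L]] <- data.frame(
        te_id = tes$id[i], strain = s,
        state = call_te_state(a, tes$start[i], tes$end[i], params),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify the population frequency of a focal-genome TE
#'
#' "low" when the TE is absent from every population strain with a
#' non-missing call (a singleton of the focal genome), "high" when it is
#' present in at least one population strain, "unknown" when every
#' population call is missing.
#'
#' @param states Character vector of per-strain states
#'   ("present"/"absent"/"missing") for one TE.
#' @param focal_present The focal strain must carry the TE (definitionally
#'   TRUE for annotated insertions); FALSE is an input error.
#' @return "low", "high" or "unknown".
#' @export
classify_frequency <- function(states, focal_present = TRUE) {
  if (!isTRUE(focal_present))
    stop("focal strain must carry the TE")
  if (any(states == "present")) return("high")
  if (any(states == "absent")) return("low")
  "unknown"
}

#' Per-TE frequency classes from a call table
#'
#' @param calls Output of \code{\link{call_population}}.
#' @return data.frame with te_id and class.
#' @export
classify_frequencies <- function(calls) {
  ids <- unique(calls$te_id)
  data.frame(te_id = ids,
             class = vapply(ids, function(id)
               classify_frequency(calls$state[calls$te_id == id]),
               character(1)),
             stringsAsFactors = FALSE)
}
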