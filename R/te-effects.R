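#' Local background HMD around a TE
#'
#' Median of the non-missing 25-bp HMD values pooled from the regions 20-40 kb
#' upstream and downstream of the TE. Regions are truncated at chromosome
#' ends; if one side falls entirely off the chromosome the median of the
#' available side is used.
#'
#' @param track An \code{\link{hmd_track}} for the TE's chromosome.
#' @param te_start,te_end TE boundaries, 0-based half-open.
#' @param background_range Distances (bp) from the TE delimiting the
#'   background region, default c(20000, 40000).
#' @return Median background HMD, or NA if every bin in the region is missing
#'   (the TE is then unestimable).
#' @export
local_background <- function(track, te_start, te_end,
                             background_range = c(20000, 40000)) {
  lo <- background_range[1]; hi <- background_range[2]
  left <- bins_in_range(track, te_start - hi, te_start - lo)
  right <- bins_in_range(track, te_end + lo, te_end + hi)
  v <- track$values[c(left, right)]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  stats::median(v)
}

#' Per-kb m-HMD values along one flank of a TE
#'
#' Divides the flank into 1-kb windows outward from the TE boundary and
#' returns, for each window, the median of its non-missing
#' background-normalized 25-bp HMD units (the m-HMD). Windows with fewer
#' than \code{min_units} non-missing units, and windows truncated by the
#' chromosome end, are NA.
#'
#' @param track An \code{hmd_track}.
#' @param boundary TE boundary position (start for the left flank, end for
#'   the right flank).
#' @param side "left" or "right".
#' @param background Local background HMD (> 0).
#' @param n_windows Number of 1-kb windows.
#' @param min_units Minimum non-missing 25-bp units per window.
#' @param window Window width in bp.
#' @return Numeric vector of length \code{n_windows}, ordered outward.
#' @export
window_mhmd <- function(track, boundary, side = c("right", "left"),
                        background, n_windows = 20, min_units = 10,
                        window = 1000) {
  side <- match.arg(side)
  if (is.na(background)) return(rep(NA_real_, n_windows))
  if (background <= 0) stop("background must be > 0")
  full_per_window <- window / track$bin_size
  chrom_len <- length(track$values) * track$bin_size
  vapply(seq_len(n_windows), function(w) {
    if (side == "right") {
      lo <- boundary + (w - 1) * window; hi <- boundary + w * window
    } else {
      lo <- boundary - w * window; hi <- boundary - (w - 1) * window
    }
    if (lo < 0 || hi > chrom_len) return(NA_real_)  # partial terminal window
    v <- track$values[bins_in_range(track, lo, hi)]
    v <- v[!is.na(v)]
    if (length(v) < min_units) return(NA_real_)
    stats::median(v / background)
  }, numeric(1))
}

#' Magnitude of TE-mediated enrichment
#'
#' Mean of the two first-window m-HMD values (left and right flanks); if one
#' side is missing the other side alone is used.
#'
#' @param mhmd_left,mhmd_right Window vectors from \code{\link{window_mhmd}}
#'   (or scalar first-window values).
#' @return The magnitude, or NA when both sides are missing.
#' @examples
#' effect_magnitude(2, 3)   # 2.5
#' effect_magnitude(NA, 1.8)  # 1.8
#' @export
effect_magnitude <- function(mhmd_left, mhmd_right) {
  l <- mhmd_left[1]; r <- mhmd_right[1]
  if (is.na(l) && is.na(r)) return(NA_real_)
  mean(c(l, r), na.rm = TRUE)
}

#' Extent of TE-mediated enrichment along one flank
#'
#' Number of consecutive 1-kb windows, starting at the window adjacent to
#' the TE, whose m-HMD exceeds the threshold. The run stops at the first
#' window at or below the threshold (or at a missing window); a missing
#' first window makes the side extent missing.
#'
#' @param mhmd Window vector ordered outward from the TE boundary.
#' @param threshold m-HMD threshold (default 1: above local background).
#' @return Extent in kb (0 to length(mhmd)), or NA.
#' @examples
#' effect_extent(c(1.4, 1.2, 0.9, 1.3))  # 2
#' effect_extent(c(0.8, 1.5))            # 0
#' @export
effect_extent <- function(mhmd, threshold = 1) {
  if (!length(mhmd) || is.na(mhmd[1])) return(NA_real_)
  run <- 0L
  for (v in mhmd) {
    if (is.na(v) || v <= threshold) break
    run <- run + 1L
  }
  as.numeric(run)
}

#' Per-TE effect estimates for one or more replicates
#'
#' For each TE and replicate: the local background, per-side first-window
#' m-HMD, magnitude (average over sides), and per-side and side-averaged
#' extent. Flanking windows overlapping another annotated TE are retained but
#' flagged (\code{flank_overlaps_te}) for sensitivity analyses.
#'
#' @param hmd Either a named list of \code{hmd_track}s (a single replicate)
#'   or a list of such lists (one per replicate).
#' @param tes TE data.frame (chrom, start, end, id).
#' @param threshold Extent threshold on m-HMD.
#' @param n_windows Windows per side.
#' @param background_range Background region distances, bp.
#' @param min_units Minimum units per window.
#' @return data.frame with one row per TE per replicate.
#' @export
te_effect_table <- function(hmd, tes, threshold = 1, n_windows = 20,
                            background_range = c(20000, 40000),
                            min_units = 10) {
  if (length(hmd) && inherits(hmd[[1]], "hmd_track")) hmd <- list(hmd)
  reps <- seq_along(hmd)
  out <- list()
  for (r in reps) {
    tracks <- hmd[[r]]
    for (i in seq_len(nrow(tes))) {
      tr <- tracks[[tes$chrom[i]]]
      if (is.null(tr)) next
      bg <- local_background(tr, tes$start[i], tes$end[i], background_range)
      wl <- window_mhmd(tr, tes$start[i], "left", bg, n_windows, min_units)
      wr <- window_mhmd(tr, tes$end[i], "right", bg, n_windows, min_units)
      flank_bp <- n_windows * 1000
      overlaps <- any(tes$chrom == tes$chrom[i] & tes$id != tes$id[i] &
                        tes$start < tes$end[i] + flank_bp &
                        tes$end > tes$start[i] - flank_bp)
      out[[length(out) + 1L]] <- data.frame(
        te_id = tes$id[i], replicate = r, background = bg,
        mag_left = wl[1], mag_right = wr[1],
        magnitude = effect_magnitude(wl, wr),
        extent_left = effect_extent(wl, threshold),
        extent_right = effect_extent(wr, threshold),
        flank_overlaps_te = overlaps,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  ext <- cbind(out$extent_left, out$extent_right)
  both_na <- is.na(out$extent_left) & is.na(out$extent_right)
  out$extent <- ifelse(both_na, NA_real_, rowMeans(ext, na.rm = TRUE))
  rownames(out) <- NULL
  out
}

#' Average per-TE estimates across replicates
#'
#' Per-TE mean of each numeric estimate over replicates; a TE missing in one
#' replicate uses the other replicate alone.
#'
#' @param effects Output of \code{\link{te_effect_table}}.
#' @return One row per TE with replicate-averaged columns.
#' @export
average_te_effects <- function(effects) {
  num_cols <- c("background", "mag_left", "mag_right", "magnitude",
                "extent_left", "extent_right", "extent")
  ids <- unique(effects$te_id)
  rows <- lapply(ids, function(id) {
    sub <- effects[effects$te_id == id, , drop = FALSE]
    vals <- vapply(num_cols, function(cl) {
      v <- sub[[cl]][!is.na(sub[[cl]])]
      if (!length(v)) NA_real_ else mean(v)
    }, numeric(1))
    cbind(data.frame(te_id = id, n_replicates = nrow(sub),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-genome effect estimate for a single TE
#'
#' Standardizes the focal strain's flanking m-HMD by the m-HMD of the
#' homologous (TE-free) sequence in an alternative strain. The magnitude is
#' the ratio of side-averaged first-window m-HMDs; the extent per side is the
#' farthest consecutive 1-kb window in which the focal m-HMD exceeds the
#' alternative strain's, averaged over sides and capped at \code{n_windows}.
#'
#' TEs inside shared enrichment peaks, TEs whose homologous region is
#' unmapped, and TEs with an alternative-strain TE within 1 kb of the
#' homologous site are excluded with a recorded reason.
#'
#' @param hmd_focal,hmd_alt Named lists of \code{hmd_track}s for the focal
#'   and alternative strains.
#' @param te One-row TE data.frame (chrom, start, end, id) in focal
#'   coordinates.
#' @param homology Function mapping a focal position (pos, chrom) to the
#'   homologous alternative-strain position (NA if unmapped). Default:
#'   identity (collinear assemblies).
#' @param shared_peaks Optional data.frame (chrom, start, end) of shared
#'   enrichment peaks.
#' @param alt_tes Optional TE data.frame for the alternative strain.
#' @param n_windows,min_units,background_range As in
#'   \code{\link{te_effect_table}}.
#' @return A one-row data.frame with te_id, magnitude, extent and an
#'   \code{excluded} reason (NA when estimable).
#' @export
two_genome_effect <- function(hmd_focal, hmd_alt, te,
                              homology = function(pos, chrom) pos,
                              shared_peaks = NULL, alt_tes = NULL,
                              n_windows = 20, min_units = 10,
                              background_range = c(20000, 40000)) {
  res <- function(mag, ext, reason)
    data.frame(te_id = te$id, magnitude = mag, extent = ext,
               excluded = reason, stringsAsFactors = FALSE)
  if (!is.null(shared_peaks)) {
    hit <- shared_peaks$chrom == te$chrom &
      shared_peaks$start < te$end & shared_peaks$end > te$start
    if (any(hit)) return(res(NA, NA, "shared_peak"))
  }
  h_start <- homology(te$start, te$chrom)
  h_end <- homology(te$end, te$chrom)
  if (is.na(h_start) || is.na(h_end)) return(res(NA, NA, "unmapped"))
  if (!is.null(alt_tes)) {
    near <- alt_tes$chrom == te$chrom &
      alt_tes$start < h_end + 1000 & alt_tes$end > h_start - 1000
    if (any(near)) return(res(NA, NA, "alt_te_within_1kb"))
  }
  trf <- hmd_focal[[te$chrom]]; tra <- hmd_alt[[te$chrom]]
  bgf <- local_background(trf, te$start, te$end, background_range)
  bga <- local_background(tra, h_start, h_end, background_range)
  fl <- window_mhmd(trf, te$start, "left", bgf, n_windows, min_units)
  fr <- window_mhmd(trf, te$end, "right", bgf, n_windows, min_units)
  al <- window_mhmd(tra, h_start, "left", bga, n_windows, min_units)
  ar <- window_mhmd(tra, h_end, "right", bga, n_windows, min_units)
  mf <- effect_magnitude(fl, fr); ma <- effect_magnitude(al, ar)
  mag <- if (is.na(mf) || is.na(ma) || ma == 0) NA_real_ else mf / ma
  run_vs <- function(f, a) {
    if (!length(f) || is.na(f[1]) || is.na(a[1])) return(NA_real_)
    run <- 0L
    for (w in seq_along(f)) {
      if (is.na(f[w]) || is.na(a[w]) || f[w] <= a[w]) break
      run <- run + 1L
    }
    as.numeric(run)
  }
  el <- run_vs(fl, al); er <- run_vs(fr, ar)
  ext <- if (is.na(el) && is.na(er)) NA_real_ else mean(c(el, er), na.rm = TRUE)
  res(mag, ext, NA_character_)
}

#' Side-asymmetry z-scores between intergenic and genic flanks
#'
#' For each TE with an identified genic side, the normalized difference
#' z = (intergenic side - genic side) / SD(differences over all TEs).
#' Positive z means the effect (extent or magnitude) is more restricted on
#' the genic side.
#'
#' @param intergenic,genic Per-TE values (extent or magnitude) on the
#'   intergenic and genic sides, equal length.
#' @param te_id Optional TE identifiers.
#' @return data.frame with te_id, intergenic, genic, diff and z. TEs with a
#'   missing side are dropped before the SD is computed.
#' @examples
#' side_asymmetry_z(c(2, 1, -1, 1), c(0, 1, 1, 1))$z[1]  # 2 / sd = 1.2247
#' @export
side_asymmetry_z <- function(intergenic, genic, te_id = NULL) {
  stopifnot(length(intergenic) == length(genic))
  if (is.null(te_id)) te_id <- sprintf("te%d", seq_along(intergenic))
  ok <- !is.na(intergenic) & !is.na(genic)
  d <- intergenic[ok] - genic[ok]
  if (length(d) < 2) stop("need at least two TEs with both sides estimated")
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) z <- rep(0, length(d))  # no asymmetry anywhere
    else stop("zero SD of side differences: z undefined")
  } else z <- d / s
  data.frame(te_id = te_id[ok], intergenic = intergenic[ok],
             genic = genic[ok], diff = d, z = z,
             stringsAsFactors = FALSE)
}

#' Identify which side of each intergenic TE faces a gene
#'
#' The genic side is the side of the nearest gene with expression at least
#' \code{min_rpkm}. TEs overlapping a gene, or without such a gene on either
#' side within \code{max_distance}, get NA.
#'
#' @param tes TE data.frame (chrom, start, end, id).
#' @param genes Gene data.frame (chrom, start, end, id) with an expression
#'   column named by \code{rpkm_col}.
#' @param min_rpkm Expression cutoff for "highly expressed".
#' @param max_distance Maximum TE-gene distance considered, bp.
#' @param rpkm_col Name of the expression column in \code{genes}.
#' @return Character vector ("left"/"right"/NA) along rows of \code{tes},
#'   plus the distance to that gene as an attribute "distance".
#' @export
te_genic_side <- function(tes, genes, min_rpkm = 10, max_distance = Inf,
                          rpkm_col = "true_rpkm") {
  hi <- genes[genes[[rpkm_col]] >= min_rpkm, , drop = FALSE]
  side <- rep(NA_character_, nrow(tes))
  dist <- rep(NA_real_, nrow(tes))
  for (i in seq_len(nrow(tes))) {
    g <- hi[hi$chrom == tes$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    if (any(g$start < tes$end[i] & g$end > tes$start[i])) next  # genic TE
    dl <- tes$start[i] - g$end; dl <- dl[dl >= 0]
    dr <- g$start - tes$end[i]; dr <- dr[dr >= 0]
    best_l <- if (length(dl)) min(dl) else Inf
    best_r <- if (length(dr)) min(dr) else Inf
    if (min(best_l, best_r) > max_distance) next
    if (best_l < best_r) { side[i] <- "left"; dist[i] <- best_l }
    else if (best_r < best_l) { side[i] <- "right"; dist[i] <- best_r }
    # equidistant on both sides: side stays NA (no single genic side)
  }
  attr(side, "distance") <- dist
  side
}
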