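#' Spike-in enrichment ratio
#'
#' Ratio of spike-in barcode fragment counts in the ChIP sample over the
#' matched input sample. This scalar standardizes the per-locus ChIP/input
#' ratio so that histone modification density (HMD) is comparable between
#' samples sequenced at different depths or immunoprecipitation efficiencies.
#'
#' @param chip_barcode_fragments Barcode fragment count in the ChIP sample.
#' @param input_barcode_fragments Barcode fragment count in the input sample.
#' @return The enrichment ratio E_si (a positive scalar).
#' @examples
#' spikein_enrichment(400, 100)  # 4
#' @export
spikein_enrichment <- function(chip_barcode_fragments,
                               input_barcode_fragments) {
  stopifnot(chip_barcode_fragments >= 0, input_barcode_fragments >= 0)
  if (input_barcode_fragments == 0)
    stop("undefined spike-in ratio: zero barcode fragments in input")
  if (chip_barcode_fragments == 0)
    stop("degenerate spike-in: zero barcode fragments in ChIP")
  chip_barcode_fragments / input_barcode_fragments
}

#' HMD track constructor
#'
#' A per-chromosome sequence of fixed-width bins carrying spike-in-normalized
#' HMD values; missing bins are NA.
#'
#' @param values Numeric vector of per-bin HMD (NA = missing).
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp; bin i covers [bin_size*(i-1), bin_size*i).
#' @return An object of class \code{"hmd_track"}.
#' @export
hmd_track <- function(values, chrom, bin_size = 25) {
  stopifnot(is.numeric(values), bin_size > 0)
  if (any(values < 0, na.rm = TRUE)) stop("HMD values must be >= 0")
  structure(list(chrom = chrom, bin_size = bin_size,
                 values = as.numeric(values)),
            class = "hmd_track")
}

#' @export
print.hmd_track <- function(x, ...) {
  cat(sprintf("<hmd_track> %s: %d bins of %d bp, %.1f%% missing\n",
              x$chrom, length(x$values), x$bin_size,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Compute a spike-in-normalized HMD track
#'
#' Per bin, HMD = (chip / input) / e_si. Bins whose input fragment coverage
#' is below \code{min_input_fragments} are flagged missing (NA), since the
#' ratio is unreliable at low input depth.
#'
#' @param chip Numeric vector of per-bin ChIP fragment coverage, or a named
#'   list of such vectors (one per chromosome).
#' @param input Matching input coverage (same shape as \code{chip}).
#' @param e_si Spike-in enrichment from \code{\link{spikein_enrichment}}.
#' @param chrom Chromosome name (ignored when \code{chip} is a list, in which
#'   case list names are used).
#' @param bin_size Bin width in bp.
#' @param min_input_fragments Missing-data cutoff on input coverage.
#' @return An \code{hmd_track}, or a named list of them.
#' @examples
#' tr <- compute_hmd_track(c(20, 10), c(5, 5), e_si = 2)
#' tr$values  # 2.0, 1.0
#' @export
compute_hmd_track <- function(chip, input, e_si, chrom = "chr",
                              bin_size = 25, min_input_fragments = 5) {
  if (is.list(chip)) {
    if (!setequal(names(chip), names(input)))
      stop("chip and input cover different chromosome sets")
    out <- lapply(names(chip), function(ch)
      compute_hmd_track(chip[[ch]], input[[ch]], e_si, chrom = ch,
                        bin_size = bin_size,
                        min_input_fragments = min_input_fragments))
    names(out) <- names(chip)
    return(out)
  }
  if (length(chip) != length(input))
    stop("chip and input tracks cover different spans")
  stopifnot(e_si > 0)
  v <- (chip / input) / e_si
  v[input < min_input_fragments] <- NA_real_
  hmd_track(v, chrom = chrom, bin_size = bin_size)
}

# indices of bins whose centers fall in [lo, hi), clipped to the track
bins_in_range <- function(track, lo, hi) {
  bs <- track$bin_size
  n <- length(track$values)
  first <- max(1L, floor(lo / bs) + 1L)
  last <- min(n, ceiling(hi / bs))
  if (first > last) return(integer(0))
  idx <- first:last
  centers <- (idx - 0.5) * bs
  idx[centers >= lo & centers < hi]
}

#' TE-centered average HMD metaprofile
#'
#' Averages HMD over all TE flanks as a function of distance from the TE
#' boundary, with a pointwise 95% confidence interval from the per-distance
#' standard error and a LOESS smooth (local linear regression with tricube
#' weights) at the given span.
#'
#' @param hmd Named list of \code{hmd_track} objects (one per chromosome).
#' @param tes TE data.frame with columns chrom, start, end.
#' @param flank Flank width in bp.
#' @param loess_span LOESS span as a fraction of the data.
#' @return A data.frame with distance (bp from the TE boundary, bin centers),
#'   mean, se, lower, upper and smoothed columns; zero rows if \code{tes}
#'   is empty.
#' @export
te_metaprofile <- function(hmd, tes, flank = 20000, loess_span = 0.15) {
  if (inherits(hmd, "hmd_track")) hmd <- stats::setNames(list(hmd), hmd$chrom)
  nb <- floor(flank / hmd[[1]]$bin_size)
  bs <- hmd[[1]]$bin_size
  if (nrow(tes) == 0)
    return(data.frame(distance = numeric(), mean = numeric(), se = numeric(),
                      lower = numeric(), upper = numeric(),
                      smoothed = numeric()))
  rows <- list()
  for (i in seq_len(nrow(tes))) {
    tr <- hmd[[tes$chrom[i]]]
    if (is.null(tr)) next
    n <- length(tr$values)
    # right flank: offsets outward from the end boundary
    ridx <- floor((tes$end[i] + (seq_len(nb) - 0.5) * bs) / bs) + 1L
    rv <- ifelse(ridx >= 1 & ridx <= n, tr$values[pmin(pmax(ridx, 1L), n)], NA)
    # left flank
    lidx <- floor((tes$start[i] - (seq_len(nb) - 0.5) * bs) / bs) + 1L
    lv <- ifelse(lidx >= 1 & lidx <= n, tr$values[pmin(pmax(lidx, 1L), n)], NA)
    rows[[length(rows) + 1L]] <- rv
    rows[[length(rows) + 1L]] <- lv
  }
  mat <- do.call(rbind, rows)
  mu <- colMeans(mat, na.rm = TRUE)
  nn <- colSums(!is.na(mat))
  se <- apply(mat, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nn, 1))
  d <- (seq_len(nb) - 0.5) * bs
  out <- data.frame(distance = d, mean = mu, se = se,
                    lower = mu - 1.96 * se, upper = mu + 1.96 * se)
  fit <- stats::loess(mean ~ distance, data = out, span = loess_span,
                      degree = 1, family = "gaussian")
  out$smoothed <- stats::predict(fit, newdata = out)
  out
}
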