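#' On-diagonal observed/expected pileup at anchor sites
#'
#' Averages the (2f+1) x (2f+1) O/E submatrix centered on each anchor bin
#' (f = flank in bins), ignoring missing pixels — the meta-plot used to
#' visualize flames and local insulation around strong rex sites. Anchors
#' are mapped to the bin containing the interval midpoint; anchors within
#' one flank of a chromosome end are dropped and counted in the result's
#' attributes. Strand is ignored (rex barriers are bidirectional).
#'
#' @param oe_map observed/expected [contact_map()].
#' @param anchors data.frame `chrom,start,end` (bp, 0-based half-open), e.g.
#'   rex sites.
#' @param flank flank in bp on each side of the anchor bin (default 250 kb).
#' @return (2f+1) x (2f+1) numeric matrix of mean O/E, with attributes
#'   `n_used` and `n_dropped`.
#' @export
on_diagonal_pileup <- function(oe_map, anchors, flank = 2.5e5) {
  stopifnot(inherits(oe_map, "contact_map"))
  bins <- oe_map$bins
  f <- as.integer(round(flank / bins$bin_width))
  sz <- 2L * f + 1L
  acc <- matrix(0, sz, sz)
  cnt <- matrix(0, sz, sz)
  used <- 0L; dropped <- 0L
  for (r in seq_len(nrow(anchors))) {
    cn <- anchors$chrom[r]
    mid <- (anchors$start[r] + anchors$end[r]) / 2
    b <- bin_index(bins, cn, mid)
    cr <- chrom_bin_range(bins, cn)
    if (b - f < cr[1] || b + f > cr[length(cr)]) {
      dropped <- dropped + 1L
      next
    }
    sub <- oe_map$values[(b - f):(b + f), (b - f):(b + f)]
    ok <- !is.na(sub)
    acc[ok] <- acc[ok] + sub[ok]
    cnt <- cnt + ok
    used <- used + 1L
  }
  if (used == 0) stop("no usable anchors (all dropped or none given)")
  out <- matrix(NA_real_, sz, sz)
  out[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  attr(out, "n_used") <- used
  attr(out, "n_dropped") <- dropped
  out
}
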