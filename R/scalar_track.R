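#' Per-bin genomic signal track
#'
#' Container for binned 1D signal (ChIP enrichment, insulation, occupancy,
#' compartment eigenvector, tiled statistics): a [bin_table()] plus one
#' numeric value (or `NA`) per bin.
#'
#' @param bins a [bin_table()].
#' @param values numeric vector, one value per bin.
#' @return object of class `scalar_track`.
#' @export
scalar_track <- function(bins, values) {
  stopifnot(inherits(bins, "bin_table"))
  if (length(values) != n_bins(bins))
    stop("values length must equal bin count")
  structure(list(bins = bins, values = as.numeric(values)),
            class = "scalar_track")
}

#' @export
print.scalar_track <- function(x, ...) {
  cat(sprintf("<scalar_track> %d bins of %s bp, %d missing\n",
              n_bins(x$bins), format(x$bins$bin_width),
              sum(is.na(x$values))))
  invisible(x)
}

#' Convert a scalar track to a data.frame / GRanges
#'
#' @param x a [scalar_track()].
#' @param ... unused.
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @export
as.data.frame.scalar_track <- function(x, ...) {
  cbind(x$bins$bins, value = x$values)
}

track_granges <- function(x) {
  df <- as.data.frame(x)
  df <- df[!is.na(df$value), ]
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end),
                         score = df$value,
                         seqlengths = x$bins$chrom_lengths)
}

#' Write a scalar track as bedGraph
#'
#' Missing bins are omitted. A comment header records the bin width (and the
#' insulation window for insulation tracks).
#'
#' @param track a [scalar_track()].
#' @param path output file.
#' @param extra_header optional character vector of extra `#` header lines.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, extra_header = NULL) {
  hdr <- c(sprintf("# bin_width=%d", track$bins$bin_width), extra_header)
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  df <- as.data.frame(track)
  df <- df[!is.na(df$value), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, append = TRUE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file onto a bin table
#'
#' Intervals are averaged into the target bins weighted by overlap length;
#' uses the standard bedGraph parser underneath.
#'
#' @param path bedGraph file.
#' @param bins target [bin_table()].
#' @return a [scalar_track()].
#' @export
read_bedgraph <- function(path, bins) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   value = gr$score)
  vals <- rep(NA_real_, n_bins(bins))
  wsum <- rep(0, n_bins(bins))
  acc <- rep(0, n_bins(bins))
  bw <- bins$bin_width
  for (r in seq_len(nrow(df))) {
    if (!df$chrom[r] %in% bins$chrom_names) next
    b0 <- floor(df$start[r] / bw); b1 <- floor((df$end[r] - 1) / bw)
    for (b in b0:b1) {
      gi <- bins$offsets[[df$chrom[r]]] + b + 1L
      if (gi > n_bins(bins)) next
      ov <- min(df$end[r], (b + 1) * bw) - max(df$start[r], b * bw)
      acc[gi] <- acc[gi] + ov * df$value[r]
      wsum[gi] <- wsum[gi] + ov
    }
  }
  vals[wsum > 0] <- acc[wsum > 0] / wsum[wsum > 0]
  scalar_track(bins, vals)
}
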