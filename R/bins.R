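#' Genomic bin table
#'
#' A `bin_table` partitions a genome into fixed-width bins, the coordinate
#' scaffold shared by contact maps and signal tracks. Coordinates are 0-based,
#' half-open; bins tile each chromosome contiguously, the last bin of a
#' chromosome may be short, and bin indices are genome-global (chromosomes
#' concatenated in the declared order).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp; the
#'   names fix the chromosome order.
#' @param bin_width bin width in bp (positive integer).
#' @return An object of class `bin_table` with elements `chrom_names`,
#'   `chrom_lengths`, `bin_width`, `n_bins_per_chrom`, `offsets` (0-based
#'   global index of each chromosome's first bin) and `bins`, a data.frame
#'   with columns `chrom`, `start`, `end` (one row per bin).
#' @examples
#' bt <- bin_table(c(chrI = 1e6, chrX = 5e5), bin_width = 1e5)
#' n_bins(bt)
#' @export
bin_table <- function(chrom_lengths, bin_width) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  bin_width <- as.integer(bin_width)
  if (is.na(bin_width) || bin_width < 1) stop("bin_width must be >= 1")
  nb <- stats::setNames(as.integer(ceiling(chrom_lengths / bin_width)),
                        names(chrom_lengths))
  offsets <- c(0L, cumsum(nb))[seq_along(nb)]
  names(offsets) <- names(chrom_lengths)
  bins <- do.call(rbind, lapply(names(chrom_lengths), function(cn) {
    starts <- seq.int(0L, by = bin_width, length.out = nb[[cn]])
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + bin_width, chrom_lengths[[cn]]),
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  structure(list(chrom_names = names(chrom_lengths),
                 chrom_lengths = chrom_lengths,
                 bin_width = bin_width,
                 n_bins_per_chrom = stats::setNames(nb, names(chrom_lengths)),
                 offsets = offsets,
                 bins = bins),
            class = "bin_table")
}

#' Total number of bins in a bin table
#' @param bins a [bin_table()].
#' @return integer bin count.
#' @export
n_bins <- function(bins) nrow(bins$bins)

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("<bin_table> %d chromosomes, %d bins of %s bp\n",
              length(x$chrom_names), n_bins(x), format(x$bin_width)))
  invisible(x)
}

#' Map genomic positions to global bin indices
#'
#' @param bins a [bin_table()].
#' @param chrom chromosome name(s), recycled against `pos`.
#' @param pos position(s) in bp, 0-based.
#' @return 1-based global bin indices.
#' @export
bin_index <- function(bins, chrom, pos) {
  if (!all(chrom %in% bins$chrom_names)) {
    bad <- setdiff(unique(chrom), bins$chrom_names)
    stop("unknown chromosome: ", paste(bad, collapse = ", "))
  }
  lens <- bins$chrom_lengths[chrom]
  if (any(pos < 0 | pos >= lens))
    stop("position out of chromosome bounds")
  as.integer(bins$offsets[chrom] + floor(pos / bins$bin_width) + 1L)
}

#' Chromosome of each bin
#' @param bins a [bin_table()].
#' @return character vector, one chromosome name per bin.
#' @export
bin_chroms <- function(bins) bins$bins$chrom

# 1-based global index range of a chromosome's bins
chrom_bin_range <- function(bins, chrom) {
  off <- bins$offsets[[chrom]]
  nb <- bins$n_bins_per_chrom[[chrom]]
  seq.int(off + 1L, off + nb)
}

same_bins <- function(a, b) {
  identical(a$chrom_names, b$chrom_names) &&
    isTRUE(all.equal(unname(a$chrom_lengths), unname(b$chrom_lengths))) &&
    a$bin_width == b$bin_width
}

#' Read a chromsizes file
#'
#' Two tab-separated columns, chromosome name and length in bp.
#'
#' @param path file path.
#' @return named numeric vector of lengths.
#' @export
read_chromsizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$length, df$chrom)
}
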