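#' Contact map container
#'
#' A chromosome-resolved symmetric matrix of raw counts or balanced contact
#' frequencies, with per-bin balancing weights. Missing pixels and invalid
#' bins are `NA`.
#'
#' @param bins a [bin_table()].
#' @param values square numeric matrix, `n_bins(bins)` on a side. If only the
#'   upper (or lower) triangle is filled the other triangle is mirrored;
#'   conflicting non-equal entries are an error.
#' @param weights per-bin balancing weights (`NA` = invalid bin), or `NULL`
#'   for a raw map.
#' @param balanced logical flag; `TRUE` for maps in balanced-frequency
#'   convention.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(bins, values, weights = NULL, balanced = FALSE) {
  stopifnot(inherits(bins, "bin_table"))
  n <- n_bins(bins)
  values <- as.matrix(values)
  if (nrow(values) != n || ncol(values) != n)
    stop(sprintf("values must be %d x %d to match the bin table", n, n))
  lo <- lower.tri(values)
  tv <- t(values)
  both <- !is.na(values) & !is.na(tv)
  if (any(abs(values[both] - tv[both]) > 1e-9 * (abs(values[both]) + 1)))
    stop("values matrix is not symmetric")
  values[lo & is.na(values)] <- tv[lo & is.na(values)]
  up <- upper.tri(values)
  tv <- t(values)
  values[up & is.na(values)] <- tv[up & is.na(values)]
  if (!is.null(weights)) {
    if (length(weights) != n) stop("weights length must equal bin count")
    if (any(!is.na(weights) & weights <= 0)) stop("weights must be > 0 where valid")
  }
  structure(list(bins = bins, values = values, weights = weights,
                 balanced = isTRUE(balanced)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d bins (%s), %s\n", n_bins(x$bins),
              paste(x$bins$chrom_names, collapse = ","),
              if (x$balanced) "balanced" else "raw counts"))
  invisible(x)
}

#' Read a contact map
#'
#' Reads the plain-text COO format: three tab-separated columns
#' `bin1 bin2 count` with 0-based global bin indices (upper triangle is
#' sufficient; records are mirrored), accompanied by a chromsizes sidecar.
#' HDF5-based single-resolution (cool-style) containers are not supported by
#' this reader; convert to COO text first.
#'
#' @param path COO text file.
#' @param chromsizes path to a chromsizes file, or a named numeric vector.
#' @param bin_width bin width in bp.
#' @return a raw [contact_map()].
#' @export
read_contacts <- function(path, chromsizes, bin_width) {
  if (grepl("\\.(cool|h5|hdf5|mcool)$", path, ignore.case = TRUE))
    stop("HDF5 (cool-style) input is not supported; export to COO text ",
         "(bin1<TAB>bin2<TAB>count) and retry")
  if (is.character(chromsizes)) chromsizes <- read_chromsizes(chromsizes)
  bins <- bin_table(chromsizes, bin_width)
  n <- n_bins(bins)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("bin1", "bin2", "count"))
  if (any(df$count < 0)) stop("negative count in COO input")
  if (any(df$bin1 < 0 | df$bin1 >= n | df$bin2 < 0 | df$bin2 >= n))
    stop("bin index out of range for declared bin table")
  m <- matrix(0, n, n)
  i <- df$bin1 + 1L; j <- df$bin2 + 1L
  m[cbind(i, j)] <- m[cbind(i, j)] + df$count
  mirror <- i != j
  m[cbind(j[mirror], i[mirror])] <- m[cbind(j[mirror], i[mirror])] + df$count[mirror]
  contact_map(bins, m)
}

#' Write a contact map as COO text plus chromsizes sidecar
#'
#' Non-missing, nonzero upper-triangle (including diagonal) pixels are
#' written as `bin1<TAB>bin2<TAB>count` with 0-based indices.
#'
#' @param map a [contact_map()].
#' @param path output COO path; the chromsizes sidecar is written to
#'   `paste0(path, ".chromsizes")` unless `chromsizes_path` is given.
#' @param chromsizes_path optional sidecar path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(map, path, chromsizes_path = NULL) {
  v <- map$values
  keep <- which(upper.tri(v, diag = TRUE) & !is.na(v) & v != 0, arr.ind = TRUE)
  df <- data.frame(bin1 = keep[, 1] - 1L, bin2 = keep[, 2] - 1L,
                   count = v[keep])
  df <- df[order(df$bin1, df$bin2), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (is.null(chromsizes_path)) chromsizes_path <- paste0(path, ".chromsizes")
  utils::write.table(
    data.frame(chrom = map$bins$chrom_names,
               length = unname(map$bins$chrom_lengths[map$bins$chrom_names])),
    chromsizes_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Shift a bin table to accommodate an ectopic insertion
#'
#' Builds the bin table of an insertion genome from the wild-type one, so
#' that wild-type maps and tracks can be compared bin-for-bin against data
#' mapped to the insertion genome. The insertion is quantized to whole bins:
#' `ceil(length / bin_width)` new bins are inserted before the bin containing
#' `position`, and the chromosome grows by that bin-quantized amount.
#' Inserted bins carry no wild-type data.
#'
#' @param bins_wt wild-type [bin_table()].
#' @param chrom,position,length chromosome, insertion point (bp, 0-based,
#'   must lie within the chromosome) and inserted length in bp (`>= 0`).
#' @return list with `bins` (the insertion-genome bin table), `mapping`
#'   (integer vector: for each wild-type bin, its 1-based index in the new
#'   table) and `inserted` (indices of the new, data-free bins).
#' @export
remap_for_insertion <- function(bins_wt, chrom, position, length) {
  stopifnot(inherits(bins_wt, "bin_table"))
  if (!chrom %in% bins_wt$chrom_names) stop("unknown chromosome: ", chrom)
  if (length < 0) stop("insertion length must be >= 0")
  if (position < 0 || position > bins_wt$chrom_lengths[[chrom]])
    stop("insertion position beyond chromosome end")
  bw <- bins_wt$bin_width
  n_ins <- as.integer(ceiling(length / bw))
  lens <- bins_wt$chrom_lengths
  lens[[chrom]] <- lens[[chrom]] + n_ins * bw
  new_bins <- bin_table(lens, bw)
  k <- bins_wt$offsets[[chrom]] + floor(position / bw) + 1L  # first shifted bin
  mapping <- seq_len(n_bins(bins_wt))
  shift <- mapping >= k
  mapping[shift] <- mapping[shift] + n_ins
  inserted <- if (n_ins > 0) seq.int(k, k + n_ins - 1L) else integer(0)
  list(bins = new_bins, mapping = mapping, inserted = inserted)
}

#' Project a wild-type contact map onto an insertion genome
#'
#' @param map wild-type [contact_map()].
#' @param remap result of [remap_for_insertion()] built from `map$bins`.
#' @return a [contact_map()] on the insertion-genome bins; inserted bins are
#'   all-`NA`.
#' @export
remap_contact_map <- function(map, remap) {
  if (n_bins(map$bins) != length(remap$mapping))
    stop("remap was built for a different bin table")
  n_new <- n_bins(remap$bins)
  v <- matrix(NA_real_, n_new, n_new)
  v[remap$mapping, remap$mapping] <- map$values
  w <- rep(NA_real_, n_new)
  if (!is.null(map$weights)) w[remap$mapping] <- map$weights
  contact_map(remap$bins, v,
              weights = if (is.null(map$weights)) NULL else w,
              balanced = map$balanced)
}
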