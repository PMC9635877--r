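# ChIP-style track normalization, X/A rescaling, consensus peaks, rex-site
# signal ratios, and domain-level expression aggregation.

#' ChIP / input ratio track
#'
#' `(chip + pseudocount) / (control + pseudocount)`, optionally log2 — the
#' standard input normalization for ChIP coverage. Missing where the control
#' is missing, or zero with no pseudocount.
#'
#' @param chip,control [scalar_track()]s of depth-normalized coverage on the
#'   same bins.
#' @param pseudocount added to both tracks (default 0).
#' @param log2 return log2 of the ratio (default `FALSE`).
#' @return [scalar_track()].
#' @export
ratio_track <- function(chip, control, pseudocount = 0, log2 = FALSE) {
  stopifnot(inherits(chip, "scalar_track"), inherits(control, "scalar_track"))
  if (n_bins(chip$bins) != n_bins(control$bins) ||
      !same_bins(chip$bins, control$bins))
    stop("tracks are on different bin tables")
  r <- (chip$values + pseudocount) / (control$values + pseudocount)
  if (log2) r <- base::log2(r)
  r[!is.finite(r)] <- NA_real_
  scalar_track(chip$bins, r)
}

chrom_group_of <- function(chroms, x_chrom = "chrX", excluded = "chrII") {
  ifelse(chroms %in% x_chrom, "chrX",
         ifelse(chroms %in% excluded, "excluded", "autosome"))
}

#' X/A rescaling of a ChIP signal track
#'
#' Rescales input-normalized signal x_i to x_f = (x_i - A) / (X - A), where
#' A is the mean signal over autosomes excluding chrII and X is the mean
#' over chrX. This anchors the autosomal (condensin-DC-free) background at 0
#' and the X-chromosome mean at 1, absorbing the X-versus-autosome read
#' allocation variability of DPY-27 ChIP experiments; chrII is left out of
#' the baseline because it is the chromosome carrying ectopic rex
#' insertions.
#'
#' @param track [scalar_track()] of input-normalized signal.
#' @param grouping named character vector mapping each chromosome to one of
#'   `"autosome_nonII"`, `"chrII"`, `"chrX"`; default inferred from the
#'   chromosome names (`chrX` is X, `chrII` excluded, the rest baseline
#'   autosomes).
#' @return list with `track` (the rescaled [scalar_track()]) and `stats`
#'   (class `chrom_group_stats`: the means `A` and `X`).
#' @export
rescale_xa <- function(track, grouping = NULL) {
  stopifnot(inherits(track, "scalar_track"))
  chroms <- bin_chroms(track$bins)
  if (is.null(grouping)) {
    grp <- chrom_group_of(chroms)
  } else {
    g <- grouping[chroms]
    if (any(is.na(g))) stop("grouping must cover every chromosome")
    grp <- ifelse(g == "chrX", "chrX",
                  ifelse(g == "chrII", "excluded", "autosome"))
  }
  v <- track$values
  A_bins <- grp == "autosome" & !is.na(v)
  X_bins <- grp == "chrX" & !is.na(v)
  if (!any(A_bins) || !any(X_bins)) stop("empty autosome or chrX group")
  A <- mean(v[A_bins]); X <- mean(v[X_bins])
  if (X == A) stop("degenerate rescaling: X and autosome means are equal")
  stats <- structure(list(A = A, X = X), class = "chrom_group_stats")
  list(track = scalar_track(track$bins, (v - A) / (X - A)), stats = stats)
}

#' Per-chromosome signal summary with X/A rescaling
#'
#' Summarizes a track (mean signal) or a peak set (peak count) per
#' chromosome, then applies the same affine convention to the per-chromosome
#' values: the mean of the baseline autosomes (excluding chrII) maps to 0
#' and the chrX value to 1.
#'
#' @param x a [scalar_track()] (`mode = "mean"`) or a peak data.frame
#'   `chrom,start,end` (`mode = "peak_count"`).
#' @param mode `"mean"` or `"peak_count"`.
#' @param chrom_names chromosome names when `x` is a peak set (defaults to
#'   those present plus nothing else).
#' @param x_chrom,excluded names of the X chromosome and of the excluded
#'   (experimental) chromosome.
#' @return data.frame `chrom`, `value` (raw summary), `rescaled`.
#' @export
chrom_summary <- function(x, mode = c("mean", "peak_count"),
                          chrom_names = NULL, x_chrom = "chrX",
                          excluded = "chrII") {
  mode <- match.arg(mode)
  if (mode == "mean") {
    stopifnot(inherits(x, "scalar_track"))
    chrom_names <- x$bins$chrom_names
    vals <- vapply(chrom_names, function(cn) {
      v <- x$values[chrom_bin_range(x$bins, cn)]
      mean(v, na.rm = TRUE)
    }, numeric(1))
  } else {
    if (is.null(chrom_names)) chrom_names <- sort(unique(x$chrom))
    vals <- vapply(chrom_names, function(cn) sum(x$chrom == cn), numeric(1))
  }
  grp <- chrom_group_of(chrom_names, x_chrom, excluded)
  if (sum(grp == "autosome") < 2)
    stop("need at least 2 autosomes besides the excluded chromosome")
  if (!any(grp == "chrX")) stop("no X chromosome found")
  A <- mean(vals[grp == "autosome"])
  X <- mean(vals[grp == "chrX"])
  if (X == A) stop("degenerate rescaling: X and autosome summaries are equal")
  data.frame(chrom = chrom_names, value = unname(vals),
             rescaled = unname((vals - A) / (X - A)),
             row.names = NULL)
}

peaks_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

#' Majority-rule consensus peaks
#'
#' Keeps a pooled-data peak iff it overlaps (by at least 1 bp) a peak in
#' strictly more than half of the replicate peak sets; coordinates come from
#' the pooled set. With two replicates, both must support a peak.
#'
#' @param replicate_peaks list of peak data.frames `chrom,start,end`
#'   (0-based half-open), one per replicate.
#' @param pooled_peaks peak data.frame from the pooled (merged) data.
#' @return the supported subset of `pooled_peaks`.
#' @export
consensus_peaks <- function(replicate_peaks, pooled_peaks) {
  if (length(replicate_peaks) < 1) stop("need at least one replicate set")
  if (nrow(pooled_peaks) == 0) return(pooled_peaks)
  pooled_gr <- peaks_granges(pooled_peaks)
  support <- rep(0L, nrow(pooled_peaks))
  for (rep_df in replicate_peaks) {
    if (nrow(rep_df) == 0) next
    hits <- GenomicRanges::countOverlaps(pooled_gr, peaks_granges(rep_df))
    support <- support + (hits > 0)
  }
  pooled_peaks[support > length(replicate_peaks) / 2, , drop = FALSE]
}

site_window_mean <- function(track, chrom, midpoint, width) {
  bw <- track$bins$bin_width
  half <- width / 2
  lo <- midpoint - half; hi <- midpoint + half
  if (lo < 0 || hi > track$bins$chrom_lengths[[chrom]])
    stop("signal window truncated by chromosome end")
  b0 <- bin_index(track$bins, chrom, lo)
  b1 <- bin_index(track$bins, chrom, hi - 1)
  mean(track$values[b0:b1], na.rm = TRUE)
}

#' Signal at a rex site relative to reference rex sites
#'
#' Mean signal in a fixed-width window centered on the site midpoint,
#' divided by the mean of the same statistic over a set of reference sites
#' (e.g. the endogenous strong rex sites on the X). Width defaults to the
#' 400 bp used for inserted-rex comparisons.
#'
#' @param track [scalar_track()] (typically fine-binned rescaled ChIP).
#' @param site one-row data.frame `chrom,start,end` for the query site.
#' @param reference_sites data.frame `chrom,start,end` of reference sites.
#' @param width window width in bp (default 400).
#' @return scalar ratio.
#' @export
rex_signal_ratio <- function(track, site, reference_sites, width = 400) {
  stopifnot(inherits(track, "scalar_track"))
  q <- site_window_mean(track, site$chrom[1],
                        (site$start[1] + site$end[1]) / 2, width)
  refs <- vapply(seq_len(nrow(reference_sites)), function(r)
    site_window_mean(track, reference_sites$chrom[r],
                     (reference_sites$start[r] + reference_sites$end[r]) / 2,
                     width),
    numeric(1))
  q / mean(refs)
}

#' Domain-level aggregation of expression changes
#'
#' Assigns each gene to the bin containing its TSS and averages log2
#' fold-changes per bin — the domain-level view in which weak, chromosome- or
#' domain-wide repression becomes detectable even when individual genes are
#' not significantly changed. Bins with no genes are `NA`.
#'
#' @param gene_table data.frame `gene, chrom, tss, log2fc` (TSS in bp,
#'   0-based).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param bin_size aggregation bin in bp (200 kb and 500 kb are the usual
#'   domain scales).
#' @return [scalar_track()] of per-bin mean log2fc, with attribute
#'   `chrom_means` (per-chromosome mean over genes) and `n_genes` per bin in
#'   attribute `n_genes`.
#' @export
domain_expression_change <- function(gene_table, chrom_lengths,
                                     bin_size = 2e5) {
  if (nrow(gene_table) == 0) stop("empty gene table")
  bins <- bin_table(chrom_lengths, bin_size)
  gi <- bin_index(bins, gene_table$chrom, gene_table$tss)
  sums <- tapply(gene_table$log2fc, gi, sum)
  cnts <- tapply(rep(1, nrow(gene_table)), gi, sum)
  vals <- rep(NA_real_, n_bins(bins))
  ng <- rep(0, n_bins(bins))
  idx <- as.integer(names(sums))
  vals[idx] <- sums / cnts
  ng[idx] <- cnts
  out <- scalar_track(bins, vals)
  attr(out, "n_genes") <- ng
  attr(out, "chrom_means") <- tapply(gene_table$log2fc, gene_table$chrom, mean)
  out
}

#' Permutation test for domain-level repression
#'
#' Compares the mean log2 fold-change of genes inside a domain against the
#' null distribution obtained by shuffling gene labels, giving a one-sided
#' p-value for repression (domain mean lower than expected).
#'
#' @param gene_table data.frame `gene, chrom, tss, log2fc`.
#' @param domain one-row data.frame `chrom,start,end` (bp, 0-based
#'   half-open).
#' @param n_perm number of label shuffles (default 10000).
#' @return list with `observed` (domain mean log2fc), `p_value`, `n_genes`.
#' @export
domain_repression_test <- function(gene_table, domain, n_perm = 10000) {
  inside <- gene_table$chrom == domain$chrom[1] &
    gene_table$tss >= domain$start[1] & gene_table$tss < domain$end[1]
  k <- sum(inside)
  if (k == 0) stop("no genes in domain")
  obs <- mean(gene_table$log2fc[inside])
  null <- replicate(n_perm, mean(sample(gene_table$log2fc, k)))
  list(observed = obs,
       p_value = (sum(null <= obs) + 1) / (n_perm + 1),
       n_genes = k)
}

#' Read a BED file of intervals
#'
#' @param path BED file (0-based half-open, as standard).
#' @return data.frame `chrom,start,end` plus `name`/`score`/`strand` when
#'   present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- gr$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  df
}
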