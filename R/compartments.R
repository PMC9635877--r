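# A/B compartment analysis: leading eigenvector of the O/E correlation
# matrix, quantile saddle aggregation, and windowed (local) strength.

# O/E of a cis submatrix using its own per-diagonal means
oe_submatrix <- function(m) {
  nb <- nrow(m)
  d <- abs(col(m) - row(m))
  ev <- vapply(0:(nb - 1), function(k) {
    v <- m[d == k]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  e <- matrix(ev[d + 1L], nb, nb)
  e[!is.na(e) & e == 0] <- NA_real_
  m / e
}

# leading eigenvector of the correlation matrix of an O/E submatrix;
# NA for bins with insufficient data
ev1_of_oe <- function(oe, min_finite = 3) {
  nb <- nrow(oe)
  valid <- colSums(!is.na(oe)) >= min_finite
  out <- rep(NA_real_, nb)
  if (sum(valid) < 2) return(out)
  cm <- suppressWarnings(stats::cor(oe[valid, valid, drop = FALSE],
                                    use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  eg <- eigen(cm, symmetric = TRUE)
  v <- eg$vectors[, which.max(eg$values)]
  out[valid] <- v / sqrt(sum(v^2))
  out
}

#' Leading compartment eigenvector (EV1)
#'
#' EV1 of the correlation matrix of the observed/expected submatrix over a
#' region (typically a chromosome's center region, where the A/B
#' checkerboard lives). The eigenvector is unit-norm over valid bins and its
#' sign is fixed by positive correlation with a reference track such as gene
#' density or active-chromatin coverage, so that positive values mean the A
#' (active) compartment.
#'
#' @param map balanced [contact_map()].
#' @param region chromosome name, or a one-row data.frame
#'   `chrom,start,end` (bp, 0-based half-open).
#' @param reference_track [scalar_track()] on the same bins (or a numeric
#'   vector over the region's bins) used to orient the sign; `NULL` leaves a
#'   deterministic but arbitrary orientation (largest-|value| bin positive).
#' @return object of class `eigen_track`: list with `values` (full-length
#'   per-bin vector, `NA` outside the region), `bins`, `region`.
#' @export
compute_ev1 <- function(map, region, reference_track = NULL) {
  stopifnot(inherits(map, "contact_map"))
  bins <- map$bins
  idx <- region_bin_indices(bins, region)
  if (length(idx) < 10) stop("region must cover at least 10 bins")
  oe <- oe_submatrix(map$values[idx, idx, drop = FALSE])
  v <- ev1_of_oe(oe)
  if (all(is.na(v))) stop("degenerate matrix: no EV1 over region")
  ref <- NULL
  if (!is.null(reference_track)) {
    ref <- if (inherits(reference_track, "scalar_track"))
      reference_track$values[idx] else as.numeric(reference_track)
    if (length(ref) != length(idx))
      stop("reference track does not match the region")
    if (all(is.na(ref))) stop("reference track all-missing over region")
    cc <- suppressWarnings(stats::cor(v, ref, use = "complete.obs"))
    if (!is.na(cc) && cc < 0) v <- -v
  } else {
    if (v[which.max(abs(v))] < 0) v <- -v
  }
  values <- rep(NA_real_, n_bins(bins))
  values[idx] <- v
  structure(list(values = values, bins = bins, region = region),
            class = "eigen_track")
}

region_bin_indices <- function(bins, region) {
  if (is.character(region)) return(chrom_bin_range(bins, region))
  stopifnot(is.data.frame(region), nrow(region) == 1)
  i0 <- bin_index(bins, region$chrom, region$start)
  i1 <- bin_index(bins, region$chrom, region$end - 1)
  seq.int(i0, i1)
}

# pixel-pooled within/across means over EV1 halves (or k quantiles) of an
# O/E matrix restricted to the given bin indices
saddle_of <- function(oe, ev1_vals, k = 2, ignore_diags = 2) {
  valid <- which(!is.na(ev1_vals))
  if (length(valid) < k) return(NULL)
  q <- as.integer(cut(rank(ev1_vals[valid], ties.method = "first"), k,
                      labels = FALSE))
  sub <- oe[valid, valid, drop = FALSE]
  d_ok <- abs(col(sub) - row(sub)) >= max(1, ignore_diags)
  S <- matrix(NA_real_, k, k)
  within_vals <- c(); across_vals <- c()
  for (p in seq_len(k)) for (qq in seq_len(k)) {
    pix <- sub[q == p, q == qq, drop = FALSE]
    sel <- d_ok[q == p, q == qq, drop = FALSE] & !is.na(pix)
    if (any(sel)) S[p, qq] <- mean(pix[sel])
  }
  extremes <- c(1L, k)
  for (p in extremes) for (qq in extremes) {
    pix <- sub[q == p, q == qq, drop = FALSE]
    sel <- d_ok[q == p, q == qq, drop = FALSE] & !is.na(pix)
    if (p == qq) within_vals <- c(within_vals, pix[sel])
    else across_vals <- c(across_vals, pix[sel])
  }
  if (length(within_vals) == 0 || length(across_vals) == 0) return(NULL)
  list(matrix = S, strength = mean(within_vals) / mean(across_vals), k = k)
}

#' Saddle aggregation and compartment strength
#'
#' Bins are ranked by EV1 and split into `k` equal-size quantiles (default
#' halves: B = bottom, A = top). Saddle cell (p, q) is the mean O/E over
#' pixel pairs with one bin in quantile p and the other in q, excluding the
#' first `ignore_diags` diagonals. Compartment strength (k = 2) is the
#' pooled mean O/E within the extreme quantiles (AA and BB pixels) divided
#' by the pooled mean across them (AB pixels); it is invariant to flipping
#' the sign of EV1.
#'
#' @param oe_map observed/expected [contact_map()] (see
#'   [observed_over_expected()]).
#' @param ev1 an `eigen_track` from [compute_ev1()], or a numeric per-bin
#'   vector.
#' @param k number of quantiles (default 2).
#' @param ignore_diags diagonals excluded from the aggregation (default 2).
#' @return object of class `saddle_result`: list with `matrix` (k x k),
#'   `strength`, `k`.
#' @export
saddle_strength <- function(oe_map, ev1, k = 2, ignore_diags = 2) {
  stopifnot(inherits(oe_map, "contact_map"))
  if (k < 2) stop("k must be >= 2")
  ev <- if (inherits(ev1, "eigen_track")) ev1$values else as.numeric(ev1)
  if (length(ev) != n_bins(oe_map$bins))
    stop("EV1 length does not match the map")
  res <- saddle_of(oe_map$values, ev, k = k, ignore_diags = ignore_diags)
  if (is.null(res)) stop("fewer valid bins than quantiles")
  structure(res, class = "saddle_result")
}

#' @export
print.saddle_result <- function(x, ...) {
  cat(sprintf("<saddle_result> k=%d, strength=%.4f\n", x$k, x$strength))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Local compartment strength in non-overlapping windows
#'
#' Each chromosome is tiled into `window`-bp submatrices; within each tile
#' the O/E, EV1 and saddle strength are recomputed from the tile alone,
#' yielding one strength value per tile. Tiles with fewer than 10 valid bins
#' are `NA`.
#'
#' @param map balanced [contact_map()].
#' @param window tile size in bp; must cover at least 20 bins.
#' @param ignore_diags diagonals excluded within each tile (default 2).
#' @return [scalar_track()] on a `window`-width bin table (one value per
#'   tile).
#' @export
local_strength_profile <- function(map, window, ignore_diags = 2) {
  stopifnot(inherits(map, "contact_map"))
  bins <- map$bins
  wb <- as.integer(window / bins$bin_width)
  if (wb < 20) stop("window must cover at least 20 bins")
  tiles <- bin_table(stats::setNames(bins$chrom_lengths, bins$chrom_names),
                     as.integer(window))
  vals <- rep(NA_real_, n_bins(tiles))
  for (cn in bins$chrom_names) {
    cidx <- chrom_bin_range(bins, cn)
    tidx <- chrom_bin_range(tiles, cn)
    for (t in seq_along(tidx)) {
      lo <- (t - 1L) * wb + 1L
      hi <- min(t * wb, length(cidx))
      sub <- map$values[cidx[lo:hi], cidx[lo:hi], drop = FALSE]
      if (sum(colSums(!is.na(sub)) > 0) < 10) next
      oe <- oe_submatrix(sub)
      ev <- ev1_of_oe(oe)
      res <- saddle_of(oe, ev, k = 2, ignore_diags = ignore_diags)
      if (!is.null(res)) vals[tidx[t]] <- res$strength
    }
  }
  scalar_track(tiles, vals)
}

#' Ratio of two tiled (or binned) tracks between conditions
#'
#' Elementwise `a / b`; missing values propagate. Used to compare local
#' compartment strength (or any per-tile statistic) between conditions.
#'
#' @param track_a,track_b [scalar_track()]s on the same tiling.
#' @return [scalar_track()] of ratios.
#' @export
compare_conditions <- function(track_a, track_b) {
  stopifnot(inherits(track_a, "scalar_track"),
            inherits(track_b, "scalar_track"))
  if (n_bins(track_a$bins) != n_bins(track_b$bins) ||
      !same_bins(track_a$bins, track_b$bins))
    stop("tracks are on different tilings")
  scalar_track(track_a$bins, track_a$values / track_b$values)
}
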