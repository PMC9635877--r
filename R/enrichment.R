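# Quantification of extrusion signatures on O/E maps: flames ('+' pattern at
# a loading site), the secondary anti-diagonal (two-sided point-loading
# signature), and corner peaks (stable anchored loops between two sites).

site_bin <- function(oe_map, chrom, pos) bin_index(oe_map$bins, chrom, pos)

#' Anti-diagonal (secondary perpendicular diagonal) enrichment at a site
#'
#' Two-sided extrusion from a point source puts both legs at symmetric
#' separations, enriching pixels `(b - k, b + k)` — a ridge perpendicular to
#' the main diagonal. The ridge mean over `k_range` is compared against the
#' matched-separation background of the surrounding quadrant (rows within
#' `halfwidth` bins of the ridge, excluding the ridge itself), which
#' separates a true ridge from the blocky quadrant-wide enrichment that
#' co-loaded one-sided extruders produce.
#'
#' @param oe_map observed/expected [contact_map()].
#' @param chrom,pos site chromosome and position (bp).
#' @param k_range half-separations (in bins) along the ridge (default 5:60).
#' @param halfwidth background band half-width in bins (default 30).
#' @return list with `score` (ridge mean O/E), `bg95` (95th percentile of
#'   matched-separation local background pixels), `background` (the pixels).
#' @export
antidiagonal_enrichment <- function(oe_map, chrom, pos, k_range = 5:60,
                                    halfwidth = 30) {
  b <- site_bin(oe_map, chrom, pos)
  v <- oe_map$values
  cr <- chrom_bin_range(oe_map$bins, chrom)
  lo <- cr[1]; hi <- cr[length(cr)]
  ks <- k_range[b - k_range >= lo & b + k_range <= hi]
  if (length(ks) == 0) stop("site too close to the chromosome end")
  ridge <- v[cbind(b - ks, b + ks)]
  bg <- unlist(lapply(ks, function(k) {
    offs <- setdiff(seq(-halfwidth, halfwidth), -2:2)
    i <- b - k + offs
    i <- i[i >= lo & i + 2 * k <= hi]
    v[cbind(i, i + 2 * k)]
  }))
  list(score = mean(ridge, na.rm = TRUE),
       bg95 = stats::quantile(bg, 0.95, na.rm = TRUE, names = FALSE),
       background = bg)
}

#' Flame (stripe) enrichment at a site
#'
#' One-sided extrusion anchored at a loading site enriches the row and
#' column through the site (a '+' pattern). The flame mean over pixels
#' `(b, b + s)` and `(b - s, b)` is compared against the 95th percentile of
#' bootstrap means of randomly placed matched-separation pixel sets on the
#' same chromosome.
#'
#' @param oe_map observed/expected [contact_map()].
#' @param chrom,pos site chromosome and position (bp).
#' @param k_range separations (in bins) along the flame (default 10:120).
#' @param n_boot bootstrap draws for the background (default 300; uses the
#'   current RNG stream).
#' @return list with `score`, `bg95`.
#' @export
flame_enrichment <- function(oe_map, chrom, pos, k_range = 10:120,
                             n_boot = 300) {
  b <- site_bin(oe_map, chrom, pos)
  v <- oe_map$values
  cr <- chrom_bin_range(oe_map$bins, chrom)
  lo <- cr[1]; hi <- cr[length(cr)]
  ks <- k_range[k_range <= hi - lo]
  obs <- vapply(ks, function(s) {
    px <- c(if (b + s <= hi) v[b, b + s],
            if (b - s >= lo) v[b - s, b])
    mean(px, na.rm = TRUE)
  }, numeric(1))
  boot <- vapply(seq_len(n_boot), function(t) {
    mean(vapply(ks, function(s) {
      i <- sample(seq.int(lo, hi - s), 1)
      v[i, i + s]
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  list(score = mean(obs, na.rm = TRUE),
       bg95 = stats::quantile(boot, 0.95, na.rm = TRUE, names = FALSE))
}

#' Corner-peak enrichment between two sites
#'
#' Mean O/E in the 3x3 neighborhood of the pair pixel of two loci (e.g. two
#' rex sites), compared with the 95th percentile of single pixels at the
#' same separation (within one bin) on that chromosome — focal 'dot'
#' enrichment marking a stable anchored loop.
#'
#' @param oe_map observed/expected [contact_map()].
#' @param chrom chromosome of both sites.
#' @param pos_a,pos_b site positions (bp).
#' @return list with `score`, `bg95`.
#' @export
corner_enrichment <- function(oe_map, chrom, pos_a, pos_b) {
  ba <- site_bin(oe_map, chrom, pos_a)
  bb <- site_bin(oe_map, chrom, pos_b)
  if (ba > bb) { tmp <- ba; ba <- bb; bb <- tmp }
  v <- oe_map$values
  cr <- chrom_bin_range(oe_map$bins, chrom)
  lo <- cr[1]; hi <- cr[length(cr)]
  nb <- v[max(lo, ba - 1):min(hi, ba + 1), max(lo, bb - 1):min(hi, bb + 1)]
  sep <- bb - ba
  bg <- unlist(lapply((sep - 1):(sep + 1), function(s) {
    i <- seq.int(lo, hi - s)
    v[cbind(i, i + s)]
  }))
  list(score = mean(nb, na.rm = TRUE),
       bg95 = stats::quantile(bg, 0.95, na.rm = TRUE, names = FALSE))
}
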