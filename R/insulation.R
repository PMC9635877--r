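#' Diamond insulation score
#'
#' For each bin i, the diamond mean D(i) is the mean valid balanced contact
#' frequency between the `w` bins upstream and the `w` bins downstream of
#' the boundary between bins i-1 and i (the window `[i-w, i) x [i, i+w)`).
#' The score is `log2(D(i) / geometric mean of D over the chromosome)`, so
#' non-missing scores average zero per chromosome and dips (negative
#' values) mark insulating boundaries such as rex sites. Bins within `w`
#' of a chromosome end, or whose diamond is fully missing, are `NA`. The
#' score is invariant to a global rescaling of the matrix.
#'
#' @param map balanced [contact_map()].
#' @param window diamond half-width in bp (default 500 kb); must cover at
#'   least 3 bins.
#' @return [scalar_track()] of log2 insulation scores; the window size is
#'   kept in attribute `window`.
#' @export
insulation_score <- function(map, window = 5e5) {
  stopifnot(inherits(map, "contact_map"))
  bins <- map$bins
  w <- as.integer(round(window / bins$bin_width))
  if (w < 3) stop("window must cover at least 3 bins")
  scores <- rep(NA_real_, n_bins(bins))
  for (cn in bins$chrom_names) {
    idx <- chrom_bin_range(bins, cn)
    m <- map$values[idx, idx, drop = FALSE]
    nb <- length(idx)
    D <- rep(NA_real_, nb)
    if (nb > 2 * w) {
      for (i in (w + 1):(nb - w)) {
        block <- m[(i - w):(i - 1), i:(i + w - 1)]
        if (!all(is.na(block))) D[i] <- mean(block, na.rm = TRUE)
      }
    }
    ok <- !is.na(D) & D > 0
    if (any(ok)) {
      gm <- exp(mean(log(D[ok])))
      sc <- rep(NA_real_, nb)
      sc[ok] <- log2(D[ok] / gm)
      scores[idx] <- sc
    }
  }
  out <- scalar_track(bins, scores)
  attr(out, "window") <- w * bins$bin_width
  out
}

#' Difference of two insulation tracks
#'
#' `a - b` per bin, missing propagating — the quantitative object behind
#' insertion-versus-wild-type comparisons (project the wild-type map through
#' [remap_for_insertion()] / [remap_contact_map()] first so both tracks live
#' on the insertion genome; inserted bins, missing in wild type, difference
#' to `NA`).
#'
#' @param track_a,track_b [scalar_track()]s on the same bins.
#' @return [scalar_track()] of differences.
#' @export
differential_insulation <- function(track_a, track_b) {
  stopifnot(inherits(track_a, "scalar_track"),
            inherits(track_b, "scalar_track"))
  if (n_bins(track_a$bins) != n_bins(track_b$bins) ||
      !same_bins(track_a$bins, track_b$bins))
    stop("insulation tracks are on different bin tables")
  scalar_track(track_a$bins, track_a$values - track_b$values)
}
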