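#' Contact probability versus genomic separation, P(s)
#'
#' Mean balanced contact frequency as a function of separation, with
#' separations pooled into geometric (log-spaced) bins. Only pixels whose
#' both ends lie inside the region set contribute; when a region set spans
#' several chromosomes, separations are pooled by pixel-weighted mean.
#'
#' @param map balanced [contact_map()].
#' @param regions region set: a character vector of chromosome names, or a
#'   data.frame `chrom,start,end` (bp, 0-based half-open) of sub-regions.
#'   Default: all chromosomes.
#' @param log_bin_factor geometric spacing of separation bins (> 1); default
#'   `2^(1/8)`.
#' @param ignore_diags smallest separation (in bins) included; default 2.
#' @return object of class `ps_profile`: data.frame with columns `s` (bp,
#'   geometric bin center), `P` (mean contact frequency; `NA` where no valid
#'   pixels), `n_pixels`; `bin_width` kept as an attribute.
#' @export
compute_ps <- function(map, regions = NULL, log_bin_factor = 2^(1/8),
                       ignore_diags = 2) {
  stopifnot(inherits(map, "contact_map"))
  if (log_bin_factor <= 1) stop("log_bin_factor must be > 1")
  bins <- map$bins
  if (is.null(regions)) regions <- bins$chrom_names
  if (is.character(regions))
    regions <- data.frame(chrom = regions, start = 0,
                          end = unname(bins$chrom_lengths[regions]))
  sum_d <- numeric(0); n_d <- numeric(0)
  for (r in seq_len(nrow(regions))) {
    i0 <- bin_index(bins, regions$chrom[r], regions$start[r])
    i1 <- bin_index(bins, regions$chrom[r], regions$end[r] - 1)
    idx <- seq.int(i0, i1)
    if (length(idx) < 3) stop("region smaller than 3 bins")
    m <- map$values[idx, idx, drop = FALSE]
    ut <- upper.tri(m)
    d <- (col(m) - row(m))[ut]
    val <- m[ut]
    sel <- d >= max(1, ignore_diags)
    d <- d[sel]; val <- val[sel]
    nb <- length(idx)
    if (length(sum_d) < nb) {
      sum_d <- c(sum_d, rep(0, nb - length(sum_d)))
      n_d <- c(n_d, rep(0, nb - length(n_d)))
    }
    ok <- !is.na(val)
    if (any(ok)) {
      t1 <- tapply(val[ok], d[ok], sum)
      di <- as.integer(names(t1))
      sum_d[di] <- sum_d[di] + t1
      t2 <- tapply(rep(1, sum(ok)), d[ok], sum)
      n_d[di] <- n_d[di] + t2
    }
  }
  d_min <- max(1, ignore_diags)
  d_max <- length(sum_d)
  if (d_max < d_min) stop("no separations available")
  # geometric separation-bin edges in units of bins
  edges <- d_min
  while (edges[length(edges)] <= d_max)
    edges <- c(edges, edges[length(edges)] * log_bin_factor)
  edges <- unique(floor(edges))
  edges <- edges[edges <= d_max + 1]
  if (edges[length(edges)] <= d_max) edges <- c(edges, d_max + 1)
  ds <- seq.int(d_min, d_max)
  grp <- findInterval(ds, edges, rightmost.closed = FALSE)
  P <- s_mid <- n_pix <- numeric(max(grp))
  for (g in seq_len(max(grp))) {
    dd <- ds[grp == g]
    n_pix[g] <- sum(n_d[dd])
    # bin center: pixel-weighted log-centroid of the integer separations,
    # which reduces to the separation itself for single-separation bins
    w <- n_d[dd]
    if (sum(w) == 0) w <- rep(1, length(dd))
    s_mid[g] <- exp(stats::weighted.mean(log(dd), w)) * bins$bin_width
    P[g] <- if (n_pix[g] > 0) sum(sum_d[dd]) / n_pix[g] else NA_real_
  }
  out <- data.frame(s = s_mid, P = P, n_pixels = n_pix)
  attr(out, "bin_width") <- bins$bin_width
  attr(out, "log_bin_factor") <- log_bin_factor
  class(out) <- c("ps_profile", "data.frame")
  out
}

#' Log-log derivative of a P(s) profile
#'
#' Central finite differences of log10 P versus log10 s, after optional
#' Gaussian smoothing of log10 P along log10 s. The slope curve is the
#' loop-size readout: a local maximum (shoulder) marks the mean loop size.
#'
#' @param ps a `ps_profile` from [compute_ps()].
#' @param smooth_sigma Gaussian kernel width in log10(s) units applied to
#'   log10 P before differencing; 0 disables smoothing. Default 0.1.
#' @return object of class `derivative_profile`: data.frame `s`, `slope`;
#'   `smooth_sigma` kept as an attribute.
#' @export
log_derivative <- function(ps, smooth_sigma = 0.1) {
  ok <- !is.na(ps$P) & ps$P > 0
  if (sum(ok) < 3) stop("need at least 3 non-missing P(s) points")
  x <- log10(ps$s[ok])
  y <- log10(ps$P[ok])
  if (smooth_sigma > 0) {
    # local linear kernel regression: design-adaptive, so a pure power law
    # (linear in log-log) passes through unchanged even though the
    # log-binned points are unevenly spaced
    y <- vapply(seq_along(x), function(i) {
      w <- stats::dnorm(x - x[i], sd = smooth_sigma)
      xb <- sum(w * x) / sum(w)
      yb <- sum(w * y) / sum(w)
      sxx <- sum(w * (x - xb)^2)
      b <- if (sxx > 0) sum(w * (x - xb) * (y - yb)) / sxx else 0
      yb + b * (x[i] - xb)
    }, numeric(1))
  }
  n <- length(x)
  slope <- rep(NA_real_, n)
  slope[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  slope[1] <- (y[2] - y[1]) / (x[2] - x[1])
  slope[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  out <- data.frame(s = ps$s[ok], slope = slope)
  attr(out, "smooth_sigma") <- smooth_sigma
  class(out) <- c("derivative_profile", "data.frame")
  out
}

#' Infer the mean loop size from a slope profile
#'
#' Returns the separation at the most prominent local maximum of the
#' log-derivative curve within `search_range` — the standard loop-extrusion
#' readout in which the shoulder of P(s) marks the mean extruded loop
#' length. A monotone slope (no interior local maximum) yields `NA`.
#'
#' @param deriv a `derivative_profile` from [log_derivative()].
#' @param search_range numeric length-2 vector, separation range in bp to
#'   search; default the full profile support.
#' @param min_prominence smallest peak prominence (in slope units) counted
#'   as a shoulder; peaks below it are treated as numerical wiggle
#'   (default 0.02).
#' @return loop size in bp, or `NA_real_` if the slope has no local maximum
#'   of at least `min_prominence`.
#' @export
infer_loop_size <- function(deriv, search_range = NULL,
                            min_prominence = 0.02) {
  s <- deriv$s; sl <- deriv$slope
  ok <- !is.na(sl)
  s <- s[ok]; sl <- sl[ok]
  if (is.null(search_range)) search_range <- range(s)
  sel <- s >= search_range[1] & s <= search_range[2]
  if (!any(sel)) stop("empty search range")
  n <- length(sl)
  if (n < 3) return(NA_real_)
  # interior local maxima (plateaus resolve toward smaller s)
  peaks <- which(vapply(2:(n - 1), function(i)
    sl[i] > sl[i - 1] && sl[i] >= sl[i + 1], logical(1))) + 1L
  peaks <- peaks[sel[peaks]]
  if (length(peaks) == 0) return(NA_real_)
  prominence <- vapply(peaks, function(p) {
    lmin <- Inf
    i <- p - 1
    while (i >= 1 && sl[i] <= sl[p]) { lmin <- min(lmin, sl[i]); i <- i - 1 }
    rmin <- Inf
    i <- p + 1
    while (i <= n && sl[i] <= sl[p]) { rmin <- min(rmin, sl[i]); i <- i + 1 }
    sl[p] - max(min(lmin, sl[p]), min(rmin, sl[p]))
  }, numeric(1))
  peaks <- peaks[prominence >= min_prominence]
  prominence <- prominence[prominence >= min_prominence]
  if (length(peaks) == 0) return(NA_real_)
  best <- peaks[prominence == max(prominence)]
  s[best[1]]  # ties broken toward smaller s
}
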