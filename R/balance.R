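#' Iterative correction (ICE) of a raw contact map
#'
#' Matrix balancing by iterative correction: low/high-coverage bins are
#' invalidated by a median-absolute-deviation filter on log10 marginals
#' (per chromosome), the first `ignore_diags` diagonals are excluded from the
#' marginal sums, and per-bin weights are iterated until the variance of the
#' scaled valid marginals falls below `tol`. Balanced values are
#' `w_i * w_j * raw_ij`, rescaled so that valid-bin marginals average 1.
#'
#' @param map raw [contact_map()].
#' @param max_iters maximum iterations (default 500).
#' @param mad_max invalidate bins whose log10 marginal deviates from the
#'   chromosome median by more than this many MADs (default 5).
#' @param ignore_diags number of diagonals (starting at the main diagonal)
#'   excluded from marginal sums (default 2).
#' @param tol convergence threshold on the variance of scaled valid
#'   marginals. The default 1e-9 keeps the post-hoc coefficient of variation
#'   of the marginals well below 1e-4.
#' @return balanced [contact_map()] with `weights` filled; attribute
#'   `converged` reports whether `tol` was reached within `max_iters`.
#' @export
balance_ice <- function(map, max_iters = 500, mad_max = 5, ignore_diags = 2,
                        tol = 1e-9) {
  stopifnot(inherits(map, "contact_map"))
  if (max_iters < 1) stop("max_iters must be >= 1")
  v <- map$values
  v[is.na(v)] <- 0
  n <- nrow(v)
  keep <- abs(row(v) - col(v)) >= ignore_diags
  vm <- v * keep  # pixels contributing to marginals

  marg0 <- rowSums(vm)
  valid <- marg0 > 0
  for (cn in map$bins$chrom_names) {
    idx <- chrom_bin_range(map$bins, cn)
    ok <- idx[valid[idx]]
    if (length(ok) == 0) next
    lm <- log10(marg0[ok])
    dev <- lm - stats::median(lm)
    madv <- stats::median(abs(dev))
    if (madv > 0) valid[ok[abs(dev) > mad_max * madv]] <- FALSE
  }
  if (!any(valid)) stop("no valid bins after coverage filtering")

  vm[!valid, ] <- 0
  vm[, !valid] <- 0
  b <- rep(1, n)
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    s <- b * (vm %*% b)[, 1]
    sv <- s[valid]
    ms <- mean(sv)
    if (stats::var(sv / ms) < tol) { converged <- TRUE; break }
    b[valid] <- b[valid] / (sv / ms)
  }
  if (!converged)
    warning(sprintf("ICE did not reach tol=%g in %d iterations; returning best iterate",
                    tol, max_iters))
  s <- b * (vm %*% b)[, 1]
  w <- b / sqrt(mean(s[valid]))
  w[!valid] <- NA_real_

  bal <- (w %o% w) * v
  bal[!valid, ] <- NA_real_
  bal[, !valid] <- NA_real_
  out <- contact_map(map$bins, bal, weights = w, balanced = TRUE)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  out
}

#' Distance-decay expected profiles by region group
#'
#' Mean balanced contact frequency at each bin separation, computed within
#' groups of chromosomes (pixel-weighted pooling across a group's
#' chromosomes). Distinct groups let the X and the autosomes keep their
#' distinct P(s) when forming observed/expected maps.
#'
#' @param map balanced [contact_map()].
#' @param region_groups named list of chromosome-name vectors partitioning
#'   (a subset of) the chromosomes; default one group per chromosome.
#' @return object of class `expected_set`: list with `profiles` (per group, a
#'   data.frame `dist` (bins), `expected`, `n_pixels`) and `groups`.
#' @export
expected_by_distance <- function(map, region_groups = NULL) {
  stopifnot(inherits(map, "contact_map"))
  if (is.null(region_groups))
    region_groups <- stats::setNames(as.list(map$bins$chrom_names),
                                     map$bins$chrom_names)
  profiles <- lapply(names(region_groups), function(g) {
    chroms <- region_groups[[g]]
    if (length(chroms) == 0) stop("empty region group: ", g)
    if (!all(chroms %in% map$bins$chrom_names))
      stop("unknown chromosome in group ", g)
    acc_sum <- numeric(0); acc_n <- numeric(0)
    for (cn in chroms) {
      idx <- chrom_bin_range(map$bins, cn)
      m <- map$values[idx, idx, drop = FALSE]
      nb <- length(idx)
      ut <- upper.tri(m, diag = TRUE)
      d <- (col(m) - row(m))[ut]
      val <- m[ut]
      ok <- !is.na(val)
      sums <- rep(0, nb); cnts <- rep(0, nb)
      if (any(ok)) {
        t1 <- tapply(val[ok], d[ok], sum)
        t2 <- tapply(rep(1, sum(ok)), d[ok], sum)
        di <- as.integer(names(t1)) + 1L
        sums[di] <- t1; cnts[di] <- t2
      }
      if (length(acc_sum) < nb) {
        acc_sum <- c(acc_sum, rep(0, nb - length(acc_sum)))
        acc_n <- c(acc_n, rep(0, nb - length(acc_n)))
      }
      acc_sum[seq_len(nb)] <- acc_sum[seq_len(nb)] + sums
      acc_n[seq_len(nb)] <- acc_n[seq_len(nb)] + cnts
    }
    data.frame(dist = seq_along(acc_sum) - 1L,
               expected = ifelse(acc_n > 0, acc_sum / acc_n, NA_real_),
               n_pixels = acc_n)
  })
  names(profiles) <- names(region_groups)
  structure(list(profiles = profiles, groups = region_groups),
            class = "expected_set")
}

#' Observed/expected transform
#'
#' Divides each cis pixel by the group-specific expected value at its bin
#' separation. Pixels of chromosomes outside every group, and pixels whose
#' expected is zero or missing, become `NA`. Inter-chromosomal pixels are
#' `NA` (expecteds are cis-only).
#'
#' @param map balanced [contact_map()].
#' @param expected an `expected_set` from [expected_by_distance()].
#' @return [contact_map()] of O/E values.
#' @export
observed_over_expected <- function(map, expected) {
  stopifnot(inherits(map, "contact_map"), inherits(expected, "expected_set"))
  n <- n_bins(map$bins)
  oe <- matrix(NA_real_, n, n)
  for (g in names(expected$groups)) {
    exp_g <- expected$profiles[[g]]
    ev <- exp_g$expected
    ev[!is.na(ev) & ev == 0] <- NA_real_
    for (cn in expected$groups[[g]]) {
      idx <- chrom_bin_range(map$bins, cn)
      m <- map$values[idx, idx, drop = FALSE]
      d <- abs(col(m) - row(m)) + 1L
      e <- matrix(ev[d], nrow(m), ncol(m))
      oe[idx, idx] <- m / e
    }
  }
  contact_map(map$bins, oe, weights = map$weights, balanced = TRUE)
}

#' Log2 ratio of two contact maps
#'
#' `log2((a + pseudocount) / (b + pseudocount))` per pixel; antisymmetric
#' under swapping the arguments. With the default pseudocount 0, pixels
#' where either map is zero or missing come out `NA`.
#'
#' @param map_a,map_b [contact_map()]s (or bare matrices) on identical bins.
#' @param pseudocount added to both maps before the ratio.
#' @return numeric matrix of log2 ratios.
#' @export
log2_ratio_map <- function(map_a, map_b, pseudocount = 0) {
  a <- if (inherits(map_a, "contact_map")) map_a$values else as.matrix(map_a)
  b <- if (inherits(map_b, "contact_map")) map_b$values else as.matrix(map_b)
  if (!all(dim(a) == dim(b))) stop("contact maps have different shapes")
  if (inherits(map_a, "contact_map") && inherits(map_b, "contact_map") &&
      !same_bins(map_a$bins, map_b$bins))
    stop("contact maps are on different bin tables")
  # difference of logs, so swapping arguments negates the result exactly
  r <- log2(a + pseudocount) - log2(b + pseudocount)
  r[!is.finite(r)] <- NA_real_
  r
}
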