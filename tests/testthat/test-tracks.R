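worm_bins <- function(bw = 1e5) {
  bin_table(c(chrI = 1e6, chrII = 1e6, chrIII = 1e6, chrIV = 1e6,
              chrV = 1e6, chrX = 1e6), bw)
}

test_that("input normalization divides tracks with guards", {
  bt <- bin_table(c(chr1 = 3e5), 1e5)
  chip <- scalar_track(bt, c(3, 2, 0))
  ctrl <- scalar_track(bt, c(1, 2, 0))
  expect_equal(ratio_track(chip, ctrl, pseudocount = 1)$values[1], 2)
  expect_equal(ratio_track(chip, chip)$values[1:2], c(1, 1))
  expect_equal(ratio_track(chip, chip, log2 = TRUE)$values[1:2], c(0, 0))
  # 0/0 with no pseudocount is missing
  expect_true(is.na(ratio_track(chip, ctrl)$values[3]))
})

test_that("X/A rescaling anchors group means at exactly 0 and 1", {
  set.seed(31)
  bt <- worm_bins()
  v <- stats::rnorm(n_bins(bt), mean = 1)
  v[bin_chroms(bt) == "chrX"] <- v[bin_chroms(bt) == "chrX"] + 2
  tr <- scalar_track(bt, v)
  rs <- rescale_xa(tr)
  ch <- bin_chroms(bt)
  auto <- !(ch %in% c("chrII", "chrX"))
  expect_equal(mean(rs$track$values[auto]), 0, tolerance = 1e-12)
  expect_equal(mean(rs$track$values[ch == "chrX"]), 1, tolerance = 1e-12)

  # hand arithmetic: A=2, X=6, xi=4 (on chrII, outside both groups) -> 0.5
  v2 <- ifelse(ch == "chrX", 6, 2)
  ii_bin <- which(ch == "chrII")[1]
  v2[ii_bin] <- 4
  rs2 <- rescale_xa(scalar_track(bt, v2))
  expect_equal(rs2$stats$A, 2)
  expect_equal(rs2$stats$X, 6)
  expect_equal(rs2$track$values[ii_bin], 0.5)

  # xi equal to the autosomal mean rescales to exactly 0
  expect_equal(rs2$track$values[which(auto)[2]], 0)

  # degenerate: uniform track
  expect_error(rescale_xa(scalar_track(bt, rep(1, n_bins(bt)))),
               "degenerate")
})

test_that("per-chromosome summaries rescale as in the X/A convention", {
  bt <- worm_bins()
  ch <- bin_chroms(bt)
  means <- c(chrI = 1, chrII = 2, chrIII = 1, chrIV = 1, chrV = 1, chrX = 5)
  tr <- scalar_track(bt, unname(means[ch]))
  cs <- chrom_summary(tr, "mean")
  expect_equal(cs$rescaled[cs$chrom %in% c("chrI", "chrIII", "chrIV", "chrV")],
               rep(0, 4))
  expect_equal(cs$rescaled[cs$chrom == "chrII"], 0.25)
  expect_equal(cs$rescaled[cs$chrom == "chrX"], 1)

  # peak-count mode: counts {10,10,10,10}, chrII 14, chrX 50
  peaks <- do.call(rbind, lapply(names(means), function(cn) {
    k <- c(chrI = 10, chrII = 14, chrIII = 10, chrIV = 10, chrV = 10,
           chrX = 50)[cn]
    data.frame(chrom = cn, start = seq_len(k) * 1e3, end = seq_len(k) * 1e3 + 500)
  }))
  pc <- chrom_summary(peaks, "peak_count", chrom_names = names(means))
  expect_equal(pc$rescaled[pc$chrom == "chrII"], 0.1)
  expect_equal(pc$rescaled[pc$chrom == "chrX"], 1)
  expect_equal(pc$rescaled[pc$chrom == "chrI"], 0)

  expect_error(chrom_summary(scalar_track(bt, rep(1, n_bins(bt))), "mean"),
               "degenerate")
})

test_that("consensus peaks follow the strict-majority rule", {
  pooled <- data.frame(chrom = "chrI",
                       start = c(100, 500, 900), end = c(200, 600, 1000))
  r1 <- data.frame(chrom = "chrI", start = c(120, 510), end = c(180, 590))
  r2 <- data.frame(chrom = "chrI", start = c(150, 950), end = c(210, 990))
  r3 <- data.frame(chrom = "chrI", start = 130, end = 170)

  # identical replicates keep everything
  expect_equal(consensus_peaks(list(pooled, pooled), pooled), pooled)

  # 3 replicates: peak 1 in 3/3 kept, peak 2 in 1/3 dropped, peak 3 in 1/3 dropped
  out <- consensus_peaks(list(r1, r2, r3), pooled)
  expect_equal(out$start, 100)

  # 2 replicates: support 1/2 is not a majority
  out2 <- consensus_peaks(list(r1, r2), pooled)
  expect_equal(out2$start, 100)
  expect_equal(nrow(consensus_peaks(list(r1, r3), pooled)), 1)

  # monotonicity: adding an all-covering replicate never removes peaks
  all_cov <- data.frame(chrom = "chrI", start = 0, end = 2000)
  out3 <- consensus_peaks(list(r1, r2, all_cov), pooled)
  expect_true(all(out$start %in% out3$start))
  expect_equal(nrow(consensus_peaks(list(r1), pooled[0, ])), 0)
})

test_that("rex signal ratios normalize to the reference site set", {
  bt <- bin_table(c(chrII = 1e6, chrX = 1e6), 100)
  v <- rep(1, n_bins(bt))
  # site at chrII:5e5 with signal 6; X references with means 2 and 4
  ch <- bin_chroms(bt)
  ii <- which(ch == "chrII"); xx <- which(ch == "chrX")
  v[ii[4999:5002]] <- 6
  v[xx[999:1002]] <- 2
  v[xx[4999:5002]] <- 4
  tr <- scalar_track(bt, v)
  site <- data.frame(chrom = "chrII", start = 5e5 - 200, end = 5e5 + 200)
  refs <- data.frame(chrom = "chrX",
                     start = c(1e5, 5e5) - 200, end = c(1e5, 5e5) + 200)
  expect_equal(rex_signal_ratio(tr, site, refs, width = 400), 2)

  # self-ratio of the reference set averages 1
  ratios <- sapply(1:2, function(r)
    rex_signal_ratio(tr, refs[r, ], refs, width = 400))
  expect_equal(mean(ratios), 1)

  near_edge <- data.frame(chrom = "chrII", start = 0, end = 100)
  expect_error(rex_signal_ratio(tr, near_edge, refs), "truncated")
})

test_that("domain-level expression aggregation averages genes by TSS bin", {
  lens <- c(chrII = 1e6)
  tab0 <- data.frame(gene = c("a", "b"), chrom = "chrII",
                     tss = c(1e4, 1.5e5), log2fc = c(0, 0))
  d0 <- domain_expression_change(tab0, lens, 2e5)
  expect_equal(d0$values[1], 0)

  tab <- data.frame(gene = c("a", "b"), chrom = "chrII",
                    tss = c(1e4, 1.5e5), log2fc = c(-1, 1))
  d1 <- domain_expression_change(tab, lens, 2e5)
  expect_equal(d1$values[1], 0)
  expect_true(all(is.na(d1$values[-1])))
  expect_equal(unname(attr(d1, "chrom_means")["chrII"]), 0)

  expect_error(domain_expression_change(tab[0, ], lens, 2e5), "empty")
})

test_that("occupancy-linked repression is visible at domain level only", {
  doms <- sapply(1:3, function(seed) {
    g <- build_sim_genome(c(chrII = 5e6), 1e4,
                          data.frame(chrom = "chrII",
                                     pos = c(2.40e6, 2.48e6, 2.56e6),
                                     strength = 1, p_stall = 0.8))
    cfg <- lef_config(n_lefs = 12, mode = "one_sided_rex_loading",
                      burn_in = 1000, n_samples = 120, sample_interval = 10,
                      seed = seed)
    occ <- occupancy_track(simulate_lefs(g, cfg))
    set.seed(seed + 100)
    genes <- data.frame(gene = paste0("g", 1:800), chrom = "chrII",
                        tss = stats::runif(800, 0, 5e6 - 1))
    tab <- synthetic_expression(occ, genes, r = 0.5, noise_sd = 1,
                                seed = seed + 200)
    dom <- domain_expression_change(tab, c(chrII = 5e6), 2e5)
    frac_sig <- mean(2 * stats::pnorm(-abs(tab$log2fc)) < 0.05)
    c(dom = mean(dom$values[12:14]), flank = mean(dom$values[c(8:11, 15:18)]),
      frac_sig = frac_sig)
  })
  expect_true(all(doms["dom", ] < doms["flank", ]))
  expect_true(all(doms["frac_sig", ] < 0.2))

  # permutation test flags the occupied domain
  g <- build_sim_genome(c(chrII = 5e6), 1e4,
                        data.frame(chrom = "chrII", pos = 2.5e6,
                                   strength = 1, p_stall = 0.8))
  cfg <- lef_config(n_lefs = 12, mode = "one_sided_rex_loading",
                    burn_in = 1000, n_samples = 120, sample_interval = 10,
                    seed = 4)
  occ <- occupancy_track(simulate_lefs(g, cfg))
  set.seed(999)
  genes <- data.frame(gene = paste0("g", 1:1000), chrom = "chrII",
                      tss = stats::runif(1000, 0, 5e6 - 1))
  tab <- synthetic_expression(occ, genes, r = 1, noise_sd = 0.5, seed = 5)
  res <- domain_repression_test(tab,
                                data.frame(chrom = "chrII", start = 2.3e6,
                                           end = 2.7e6),
                                n_perm = 2000)
  expect_lt(res$p_value, 0.05)
  expect_lt(res$observed, 0)
})
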