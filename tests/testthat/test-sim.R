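test_that("simulation genomes convert, merge, and validate rex tables", {
  g <- build_sim_genome(c(chrX = 1e6), 1e4,
                        data.frame(chrom = "chrX", pos = 25000,
                                   strength = 1, p_stall = 0.5))
  expect_equal(g$sites$bin, 3L)  # bins are 1-based; floor(25000/10000) = 2

  g2 <- build_sim_genome(c(chrX = 1e6), 1e4,
                         data.frame(chrom = "chrX", pos = c(25000, 25500),
                                    strength = c(1, 2), p_stall = c(0.3, 0.9)))
  expect_equal(nrow(g2$sites), 1)
  expect_equal(g2$sites$strength, 3)
  expect_equal(g2$sites$p_stall, 0.9)

  expect_error(build_sim_genome(c(chrX = 1e6), 1e4,
                                data.frame(chrom = "chrX", pos = 2e6,
                                           strength = 1, p_stall = 0)),
               "out of")
  g3 <- build_sim_genome(c(chrX = 1e6), 1e4)
  cfg <- lef_config(1, mode = "one_sided_rex_loading", burn_in = 1,
                    n_samples = 1, sample_interval = 1)
  expect_error(simulate_lefs(g3, cfg), "no loading sites")
})

test_that("a LEF boxed in by absorbing barriers never escapes", {
  g <- build_sim_genome(c(chrX = 1e6), 1e4,
                        data.frame(chrom = "chrX",
                                   pos = c(4.5e5, 5.05e5, 5.5e5),
                                   strength = c(0, 1, 0),
                                   p_stall = c(1, 0, 1)))
  cfg <- lef_config(n_lefs = 1, v = 1, D = 0, k_off = 0,
                    mode = "one_sided_rex_loading", burn_in = 100,
                    n_samples = 50, sample_interval = 5, seed = 8)
  ens <- simulate_lefs(g, cfg)
  for (m in ens$samples) {
    expect_true(m[, "left"] >= 46 && m[, "right"] <= 55)
    expect_true(51 %in% c(m[, "left"], m[, "right"]))  # anchor stays at rex
  }
})

test_that("the same seed reproduces the ensemble bit for bit", {
  g <- x_genome()
  cfg <- lef_config(n_lefs = 10, burn_in = 100, n_samples = 20,
                    sample_interval = 5, seed = 42)
  e1 <- simulate_lefs(g, cfg)
  e2 <- simulate_lefs(g, cfg)
  expect_identical(e1$samples, e2$samples)
  e3 <- simulate_lefs(g, lef_config(n_lefs = 10, burn_in = 100,
                                    n_samples = 20, sample_interval = 5,
                                    seed = 43))
  expect_false(identical(e1$samples, e3$samples))
})

test_that("unobstructed deterministic growth matches the closed form", {
  nb <- 100
  g <- build_sim_genome(c(chrX = nb * 1e4), 1e4,
                        data.frame(chrom = "chrX", pos = 4.95e5,
                                   strength = 1, p_stall = 0))
  cfg <- lef_config(n_lefs = 1, v = 1, D = 0, k_off = 0,
                    mode = "one_sided_rex_loading", burn_in = 0,
                    n_samples = 12, sample_interval = 10, seed = 17)
  ens <- simulate_lefs(g, cfg)
  load_bin <- 50
  first <- ens$samples[[1]]
  dirn <- if (first[, "right"] > load_bin) 1 else -1
  cap <- if (dirn == 1) nb - load_bin else load_bin - 1
  for (s in seq_along(ens$samples)) {
    t <- s * 10
    m <- ens$samples[[s]]
    expect_equal(unname(m[, "right"] - m[, "left"]), min(t, cap))
  }
})

test_that("ensemble bookkeeping invariants hold", {
  ens <- rex_run(seed = 1)$ensemble
  nb <- 1000
  for (m in ens$samples[seq(1, 150, by = 10)]) {
    expect_equal(nrow(m), 40)
    expect_true(all(m[, "left"] >= 1 & m[, "right"] <= nb))
    expect_true(all(m[, "left"] <= m[, "right"]))
  }
})

test_that("effective distances match a Floyd-Warshall oracle exactly", {
  set.seed(12)
  nb <- 50
  samples <- lapply(1:3, function(s) {
    a <- sample(nb - 12, 4)
    cbind(chrom = 1L, left = a, right = a + sample(3:12, 4, replace = TRUE))
  })
  ens <- manual_ensemble(samples, nb)
  alpha <- 1.3; d0 <- 2
  cm <- loops_to_contact_map(ens, alpha = alpha, d0 = d0)

  acc <- matrix(0, nb, nb)
  for (m in samples) {
    W <- matrix(Inf, nb, nb)
    diag(W) <- 0
    for (i in 1:(nb - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
    for (l in seq_len(nrow(m))) {
      W[m[l, "left"], m[l, "right"]] <- 1
      W[m[l, "right"], m[l, "left"]] <- 1
    }
    for (k in 1:nb) for (i in 1:nb) {
      relax <- W[i, k] + W[k, ]
      W[i, ] <- pmin(W[i, ], relax)
    }
    acc <- acc + (W + d0)^(-alpha)
  }
  expect_equal(cm$values, acc / 3, tolerance = 1e-14)
})

test_that("loop-free maps decay with the configured exponent", {
  g <- build_sim_genome(c(chrX = 3e6), 1e4)
  cfg <- lef_config(n_lefs = 1, v = 0, D = 0, k_off = 0,
                    mode = "one_sided_uniform", burn_in = 10, n_samples = 3,
                    sample_interval = 5, seed = 1)
  ens <- simulate_lefs(g, cfg)
  for (alpha in c(1, 1.5)) {
    cm <- loops_to_contact_map(ens, alpha = alpha)
    ps <- compute_ps(cm)
    fit <- stats::lm(log10(P) ~ log10(s), data = ps[ps$s > 2e5, ])
    expect_lt(abs(stats::coef(fit)[2] + alpha), 0.05)
  }
})

test_that("a persistent loop enriches its anchor-pair pixel", {
  nb <- 80
  a <- 20; b <- 60
  samples <- lapply(1:5, function(s) cbind(chrom = 1L, left = a, right = b))
  cm <- loops_to_contact_map(manual_ensemble(samples, nb))
  free <- powerlaw_map(nb)
  expect_equal(cm$values[a, b], (1 + 1)^-1.5)
  expect_gt(cm$values[a, b], free$values[a, b])
})

test_that("occupancy counts legs, conserves mass, and decays from rex", {
  # static configuration
  samples <- lapply(1:4, function(s) cbind(chrom = 1L, left = 10, right = 30))
  occ <- occupancy_track(manual_ensemble(samples, 50))
  expect_equal(occ$values[10], 1)
  expect_equal(occ$values[30], 1)
  expect_equal(sum(occ$values), 2)

  # conservation and monotone decline from a single rex
  decline <- sapply(1:3, function(seed) {
    g <- build_sim_genome(c(chrX = 1e7), 1e4,
                          data.frame(chrom = "chrX", pos = 5e6,
                                     strength = 1, p_stall = 0.8))
    cfg <- lef_config(n_lefs = 20, mode = "one_sided_rex_loading",
                      burn_in = 1000, n_samples = 100, sample_interval = 10,
                      seed = seed)
    ens <- simulate_lefs(g, cfg)
    ov <- occupancy_track(ens)$values
    expect_equal(sum(ov), 40, tolerance = 1e-12)
    dist <- abs(seq_along(ov) - 501)
    sapply(0:3, function(k) mean(ov[dist >= k * 100 & dist < (k + 1) * 100]))
  })
  avg <- rowMeans(decline)
  expect_true(all(diff(avg) <= 0))
  expect_gt(avg[1], avg[2])
})

test_that("mirrored genomes produce statistically identical ensembles", {
  nb <- 500
  run_at <- function(pos, seeds) {
    sapply(seeds, function(s) {
      g <- build_sim_genome(c(chrX = nb * 1e4), 1e4,
                            data.frame(chrom = "chrX", pos = pos,
                                       strength = 1, p_stall = 0.8))
      cfg <- lef_config(n_lefs = 25, mode = "one_sided_rex_loading",
                        burn_in = 1000, n_samples = 100, sample_interval = 10,
                        seed = s)
      ens <- simulate_lefs(g, cfg)
      c(loop = mean(ens$loop_lengths),
        ins = insulation_score(loops_to_contact_map(ens),
                               2e5)$values[floor(pos / 1e4) + 1])
    })
  }
  fwd <- run_at(1.5e6, 1:3)
  mir <- run_at(nb * 1e4 - 1.5e6, 4:6)
  expect_lt(abs(mean(fwd["loop", ]) - mean(mir["loop", ])), 3)
  expect_lt(abs(mean(fwd["ins", ]) - mean(mir["ins", ])), 0.25)
})

test_that("sub-unit barriers are probabilistically permeable", {
  nb <- 500
  g <- build_sim_genome(c(chrX = nb * 1e4), 1e4,
                        data.frame(chrom = "chrX",
                                   pos = c(2.2e6, 2.8e6),
                                   strength = c(1, 0),
                                   p_stall = c(0, 0.8)))
  cfg <- lef_config(n_lefs = 15, mode = "one_sided_rex_loading",
                    burn_in = 1000, n_samples = 150, sample_interval = 10,
                    seed = 2)
  occ <- occupancy_track(simulate_lefs(g, cfg))$values
  beyond <- occ[282:340]  # past the barrier bin (281)
  expect_gt(sum(beyond), 0)
})

test_that("synthetic expression follows its generative model", {
  bt_occ <- scalar_track(bin_table(c(chrII = 1e6), 1e4),
                         c(rep(2, 50), rep(0, 50)))
  genes <- data.frame(gene = paste0("g", 1:2000), chrom = "chrII",
                      tss = rep(seq(5e3, 1e6 - 5e3, length.out = 1000), 2))
  # r = 0: mean log2fc is 0 within 3 SE
  t0 <- synthetic_expression(bt_occ, genes, r = 0, noise_sd = 1, seed = 3)
  expect_lt(abs(mean(t0$log2fc)), 3 / sqrt(nrow(genes)))

  # reproducibility
  t1 <- synthetic_expression(bt_occ, genes, r = 0.5, noise_sd = 1, seed = 4)
  t2 <- synthetic_expression(bt_occ, genes, r = 0.5, noise_sd = 1, seed = 4)
  expect_identical(t1, t2)

  # occupied domain mean tracks -r * occupancy within 3 SE
  occ_genes <- t1$tss < 5e5
  expect_lt(abs(mean(t1$log2fc[occ_genes]) - (-0.5 * 2)),
            3 / sqrt(sum(occ_genes)))
  expect_lt(abs(mean(t1$log2fc[!occ_genes])), 3 / sqrt(sum(!occ_genes)))
})

test_that("corner peaks require anchored loading at paired rex sites", {
  nb <- 500
  g <- build_sim_genome(c(chrX = nb * 1e4), 1e4,
                        data.frame(chrom = "chrX", pos = c(2e6, 2.5e6),
                                   strength = 1, p_stall = 0.9))
  cfg <- lef_config(n_lefs = 15, D = 0, mode = "one_sided_rex_loading",
                    burn_in = 1000, n_samples = 150, sample_interval = 10,
                    seed = 33)
  cm <- loops_to_contact_map(simulate_lefs(g, cfg))
  oe <- observed_over_expected(cm, expected_by_distance(cm))
  cp <- corner_enrichment(oe, "chrX", 2e6, 2.5e6)
  expect_gt(cp$score, cp$bg95)

  # uniform loading with no barriers: no focal dot at the same pair
  g0 <- build_sim_genome(c(chrX = nb * 1e4), 1e4)
  cfg0 <- lef_config(n_lefs = 15, D = 0, mode = "one_sided_uniform",
                     burn_in = 1000, n_samples = 150, sample_interval = 10,
                     seed = 34)
  cm0 <- loops_to_contact_map(simulate_lefs(g0, cfg0))
  oe0 <- observed_over_expected(cm0, expected_by_distance(cm0))
  # no special pair exists; average the pair-pixel ratio over positions
  ratios <- sapply(c(1.5e6, 2e6, 2.5e6, 3e6), function(p) {
    cp0 <- corner_enrichment(oe0, "chrX", p, p + 5e5)
    cp0$score / cp0$bg95
  })
  expect_lt(mean(ratios), 1)
})
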