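# Shared fixtures: toy contact maps built in code, and lazily cached
# simulator runs reused across test files.

# symmetric map whose value is f(|i - j|) on a single chromosome
decay_map <- function(n, f, bin_width = 1e4, chrom = "chrX",
                      balanced = TRUE) {
  lens <- stats::setNames(n * bin_width, chrom)
  d <- abs(col(diag(n)) - row(diag(n)))
  v <- matrix(f(d), n, n)
  contact_map(bin_table(lens, bin_width), v,
              weights = if (balanced) rep(1, n) else NULL,
              balanced = balanced)
}

# power-law background with offset, the simulator's loop-free form
powerlaw_map <- function(n, alpha = 1.5, d0 = 1, ...) {
  decay_map(n, function(d) (d + d0)^(-alpha), ...)
}

# decay map with symmetric multiplicative log-normal noise
noisy_decay_map <- function(n, f, noise_sd, bin_width = 1e4,
                            chrom = "chrX") {
  d <- abs(col(diag(n)) - row(diag(n)))
  noise <- matrix(exp(stats::rnorm(n * n, 0, noise_sd)), n, n)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  v <- matrix(f(d), n, n) * noise
  lens <- stats::setNames(n * bin_width, chrom)
  contact_map(bin_table(lens, bin_width), v, weights = rep(1, n),
              balanced = TRUE)
}

# checkerboard compartment map: background * (1 + amp * a_i * a_j)
checkerboard_map <- function(n, block = 10, amp = 0.3, alpha = 1,
                             bin_width = 1e4, chrom = "chrA") {
  ab <- rep(c(1, -1), each = block, length.out = n)
  d <- abs(col(diag(n)) - row(diag(n)))
  v <- (d + 1)^(-alpha) * (1 + amp * outer(ab, ab))
  lens <- stats::setNames(n * bin_width, chrom)
  m <- contact_map(bin_table(lens, bin_width), v, weights = rep(1, n),
                   balanced = TRUE)
  attr(m, "ab") <- ab
  m
}

# hand-built loop ensemble (fixed configurations) for generator tests
manual_ensemble <- function(samples, n_bins, bin_width = 1e4,
                            chrom = "chrX") {
  g <- build_sim_genome(stats::setNames(n_bins * bin_width, chrom), bin_width)
  structure(list(samples = samples,
                 loop_lengths = as.numeric(unlist(lapply(samples, function(m)
                   m[, "right"] - m[, "left"]))),
                 chrom_names = chrom, genome = g,
                 config = lef_config(max(1, nrow(samples[[1]])), seed = 1)),
            class = "loop_ensemble")
}

# lazily cached expensive simulations shared between test files
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# X-like study genome: 1000 bins of 10 kb, 34 rex sites (~1 per 300 kb,
# matching the density of rex elements on the real X), probabilistic
# barriers
x_genome <- function(n_rex = 34, p_stall = 0.9, length_bp = 1e7) {
  pos <- (seq_len(n_rex) - 0.5) / n_rex * length_bp
  build_sim_genome(c(chrX = length_bp), 1e4,
                   data.frame(chrom = "chrX", pos = pos, strength = 1,
                              p_stall = p_stall))
}

# default rex-loading ensemble + map on the study genome (desk-scaled)
rex_run <- function(seed = 1, n_samples = 150) {
  cached(paste0("rex_run_", seed, "_", n_samples), {
    g <- x_genome()
    cfg <- lef_config(n_lefs = 40, mode = "one_sided_rex_loading",
                      burn_in = 1000, n_samples = n_samples,
                      sample_interval = 10, seed = seed)
    ens <- simulate_lefs(g, cfg)
    list(genome = g, ensemble = ens, map = loops_to_contact_map(ens))
  })
}

# uniform-loading run with a single central barrier of given p_stall
barrier_run <- function(p_stall, seed, n_bins = 500) {
  cached(paste0("barrier_", p_stall, "_", seed), {
    rex <- if (p_stall > 0)
      data.frame(chrom = "chrX", pos = (n_bins / 2 - 0.5) * 1e4,
                 strength = 0, p_stall = p_stall)
    else
      data.frame(chrom = character(), pos = numeric(), strength = numeric(),
                 p_stall = numeric())
    g <- build_sim_genome(c(chrX = n_bins * 1e4), 1e4, rex)
    cfg <- lef_config(n_lefs = 25, mode = "one_sided_uniform",
                      burn_in = 1000, n_samples = 150, sample_interval = 10,
                      seed = seed)
    loops_to_contact_map(simulate_lefs(g, cfg))
  })
}
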