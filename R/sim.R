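# 1D lattice loop-extrusion simulator for the condensin DC model: rex sites
# are loading sites and bidirectional probabilistic barriers; condensin DC is
# a one-sided extruder whose inactive anchor can diffuse.

#' Build a simulation genome
#'
#' Chromosomes become 1D lattices of `bin_width`-bp bins; rex sites become
#' loading sites (sampling weight = `strength`) and/or bidirectional
#' barriers (per-crossing stall probability `p_stall`). Positions are
#' converted to bins by floor division; entries landing in the same bin are
#' merged with summed strength and the maximum stall probability.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param bin_width lattice bin width in bp.
#' @param rex_table data.frame `chrom, pos, strength, p_stall` (pos in bp,
#'   0-based; strength >= 0; 0 <= p_stall <= 1). May be empty.
#' @return object of class `sim_genome`: list with `bins` (a
#'   [bin_table()]), `sites` (merged per-bin table with local 1-based `bin`),
#'   and per-chromosome lookups used by [simulate_lefs()].
#' @export
build_sim_genome <- function(chrom_lengths, bin_width,
                             rex_table = data.frame(chrom = character(),
                                                    pos = numeric(),
                                                    strength = numeric(),
                                                    p_stall = numeric())) {
  bins <- bin_table(chrom_lengths, bin_width)
  if (nrow(rex_table) > 0) {
    if (any(!rex_table$chrom %in% bins$chrom_names))
      stop("rex site on unknown chromosome")
    if (any(rex_table$pos < 0 |
            rex_table$pos >= chrom_lengths[rex_table$chrom]))
      stop("rex position out of chromosome bounds")
    if (any(rex_table$strength < 0)) stop("strengths must be >= 0")
    if (any(rex_table$p_stall < 0 | rex_table$p_stall > 1))
      stop("p_stall must be in [0, 1]")
    b <- floor(rex_table$pos / bin_width) + 1L
    key <- paste(rex_table$chrom, b)
    sites <- data.frame(
      chrom = tapply(rex_table$chrom, key, `[`, 1),
      bin = as.integer(tapply(b, key, `[`, 1)),
      strength = as.numeric(tapply(rex_table$strength, key, sum)),
      p_stall = as.numeric(tapply(rex_table$p_stall, key, max)),
      row.names = NULL)
    sites <- sites[order(match(sites$chrom, bins$chrom_names), sites$bin), ]
    rownames(sites) <- NULL
  } else {
    sites <- data.frame(chrom = character(), bin = integer(),
                        strength = numeric(), p_stall = numeric())
  }
  structure(list(bins = bins, sites = sites), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d chromosomes, %d bins, %d rex sites\n",
              length(x$bins$chrom_names), n_bins(x$bins), nrow(x$sites)))
  invisible(x)
}

#' Loop-extruding-factor kinetic configuration
#'
#' All rates are per-timestep probabilities. Modes: in
#' `one_sided_rex_loading` LEFs load at rex sites (sampled proportionally to
#' strength) with anchor = tip = site and a random extrusion direction;
#' `one_sided_uniform` loads one-sided LEFs at uniform random bins;
#' `two_sided_uniform` and `two_sided_point` extrude both legs, loading
#' uniformly or at the (rex) point source respectively.
#'
#' @param n_lefs LEFs per chromosome.
#' @param v extrusion speed: probability per step that the motor leg
#'   advances one bin (default 1).
#' @param D anchor diffusion: per-direction probability per step of a +-1
#'   anchor step (one-sided modes; requires `2 * D <= 1`). The default 0.5
#'   is the fully diffusive-anchor regime, which keeps loading sites from
#'   jamming and is the variant of anchor displacement modeled here.
#' @param k_off unload probability per step; unloaded LEFs reload instantly
#'   (default 0.012, which with `v = 1`, mutual blocking and rex barriers at
#'   the X-like density used throughout puts the realized mean loop near
#'   20 bins, i.e. 200 kb at 10-kb bins).
#' @param mode one of `"one_sided_rex_loading"`, `"one_sided_uniform"`,
#'   `"two_sided_uniform"`, `"two_sided_point"`.
#' @param burn_in steps discarded before sampling (default 1000).
#' @param n_samples configurations recorded (default 200).
#' @param sample_interval steps between samples (default 10).
#' @param seed RNG seed.
#' @return object of class `lef_config`.
#' @export
lef_config <- function(n_lefs, v = 1, D = 0.5, k_off = 0.012,
                       mode = c("one_sided_rex_loading", "one_sided_uniform",
                                "two_sided_uniform", "two_sided_point"),
                       burn_in = 1000, n_samples = 200, sample_interval = 10,
                       seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_lefs >= 1, v >= 0, v <= 1, D >= 0, 2 * D <= 1,
            k_off >= 0, k_off <= 1, n_samples >= 1, sample_interval >= 1,
            burn_in >= 0)
  structure(list(n_lefs = as.integer(n_lefs), v = v, D = D, k_off = k_off,
                 mode = mode, burn_in = as.integer(burn_in),
                 n_samples = as.integer(n_samples),
                 sample_interval = as.integer(sample_interval),
                 seed = as.integer(seed)),
            class = "lef_config")
}

#' Simulate a loop-extruding-factor ensemble
#'
#' Fixed-timestep kinetics on each chromosome's lattice. Per step and LEF
#' (in random order): with probability `k_off` the LEF unloads and reloads
#' per the mode; the motor leg(s) advance one bin with probability `v`,
#' blocked by chromosome ends and by other LEFs' legs (no traversal); in
#' one-sided modes the anchor performs an unbiased +-1 random walk
#' (per-direction probability `D`), confined by the chromosome end on its
#' side and blocked by any other occupied bin (including its own tip).
#' Barriers are orientation-free (bidirectional) and gate every leg: a leg
#' meeting a barrier draws the stall check once per encounter — with
#' probability `p_stall` it is blocked at that barrier until the LEF
#' unloads, otherwise it crosses freely — so `p_stall` is the long-run
#' blocked fraction of crossings, not a per-step delay. After `burn_in`
#' steps, configurations are recorded every `sample_interval` steps.
#'
#' @param genome a [build_sim_genome()] genome.
#' @param config a [lef_config()].
#' @return object of class `loop_ensemble`: list with `samples` (list of
#'   integer matrices with columns `chrom`, `left`, `right`; bins local,
#'   1-based, `left <= right`), `loop_lengths` (realized `right - left`, in
#'   bins, pooled over samples and LEFs), `genome`, `config`.
#' @export
simulate_lefs <- function(genome, config) {
  stopifnot(inherits(genome, "sim_genome"), inherits(config, "lef_config"))
  set.seed(config$seed)
  one_sided <- config$mode %in% c("one_sided_rex_loading", "one_sided_uniform")
  site_loading <- config$mode %in% c("one_sided_rex_loading", "two_sided_point")
  chroms <- genome$bins$chrom_names
  n_steps <- config$burn_in + config$n_samples * config$sample_interval
  sample_at <- config$burn_in + seq_len(config$n_samples) * config$sample_interval
  per_chrom <- lapply(chroms, function(cn) {
    nb <- genome$bins$n_bins_per_chrom[[cn]]
    if (2 * config$n_lefs > nb)
      stop("n_lefs exceeds chromosome capacity on ", cn)
    sites <- genome$sites[genome$sites$chrom == cn, , drop = FALSE]
    p_stall <- rep(0, nb)
    p_stall[sites$bin] <- sites$p_stall
    load_bins <- sites$bin[sites$strength > 0]
    load_w <- sites$strength[sites$strength > 0]
    if (site_loading && length(load_bins) == 0)
      stop("no loading sites on ", cn, " for mode ", config$mode)
    simulate_one_chrom(nb, p_stall, load_bins, load_w, config, one_sided,
                       site_loading, n_steps, sample_at)
  })
  samples <- lapply(seq_len(config$n_samples), function(s) {
    do.call(rbind, lapply(seq_along(chroms), function(ci) {
      m <- per_chrom[[ci]]$samples[[s]]
      cbind(chrom = ci, m)
    }))
  })
  loop_lengths <- unlist(lapply(samples, function(m) m[, "right"] - m[, "left"]))
  structure(list(samples = samples,
                 loop_lengths = as.numeric(loop_lengths),
                 chrom_names = chroms,
                 genome = genome, config = config),
            class = "loop_ensemble")
}

# Core kinetics on one chromosome; returns list(samples = list of matrices
# (left, right)).
#
# Barrier semantics: the stall check is drawn once per leg-barrier encounter.
# A leg that fails the draw is blocked at that barrier for the rest of the
# LEF's residence (redrawn after unloading); a leg that passes crosses
# freely. This makes p_stall the long-run fraction of blocked crossings
# rather than a per-step delay, and it applies to diffusing anchors too —
# the barrier is bidirectional for the whole complex.
simulate_one_chrom <- function(nb, p_stall, load_bins, load_w, config,
                               one_sided, site_loading, n_steps, sample_at) {
  nl <- config$n_lefs
  occ <- integer(nb)
  left <- integer(nl); right <- integer(nl); dir <- integer(nl)
  barrier_id <- integer(nb)
  bar_bins <- which(p_stall > 0)
  barrier_id[bar_bins] <- seq_along(bar_bins)
  n_bar <- length(bar_bins)
  # 0 = undrawn, 1 = pass, 2 = blocked; legs: 1 = left, 2 = right
  verdict <- array(0L, c(nl, 2L, max(n_bar, 1L)))

  draw_load_bin <- function() {
    if (site_loading) {
      if (length(load_bins) == 1) load_bins
      else sample(load_bins, 1, prob = load_w)
    } else sample.int(nb, 1)
  }
  load_lef <- function(l) {
    b <- draw_load_bin()
    left[l] <<- b; right[l] <<- b
    dir[l] <<- if (one_sided) sample(c(-1L, 1L), 1) else 0L
    occ[b] <<- occ[b] + 2L
    if (n_bar > 0) verdict[l, , ] <<- 0L
  }
  for (l in seq_len(nl)) load_lef(l)

  # leg `leg` of LEF `l` attempts to enter `to`
  can_enter <- function(l, leg, to) {
    if (to < 1L || to > nb) return(FALSE)
    if (occ[to] > 0L) return(FALSE)
    bid <- barrier_id[to]
    if (bid > 0L) {
      v <- verdict[l, leg, bid]
      if (v == 0L) {
        v <- if (stats::runif(1) < p_stall[to]) 2L else 1L
        verdict[l, leg, bid] <<- v
      }
      if (v == 2L) return(FALSE)
    }
    TRUE
  }
  move_leg <- function(from, to) {
    occ[from] <<- occ[from] - 1L
    occ[to] <<- occ[to] + 1L
  }

  samples <- vector("list", length(sample_at))
  si <- 1L
  for (step in seq_len(n_steps)) {
    for (l in sample.int(nl)) {
      if (config$k_off > 0 && stats::runif(1) < config$k_off) {
        occ[left[l]] <- occ[left[l]] - 1L
        occ[right[l]] <- occ[right[l]] - 1L
        load_lef(l)
        next
      }
      if (one_sided) {
        if (dir[l] == 1L) {  # motor = right leg, anchor = left leg
          if (stats::runif(1) < config$v && can_enter(l, 2L, right[l] + 1L)) {
            move_leg(right[l], right[l] + 1L); right[l] <- right[l] + 1L
          }
          if (config$D > 0) {
            u <- stats::runif(1)
            if (u < config$D) {
              if (can_enter(l, 1L, left[l] - 1L)) {
                move_leg(left[l], left[l] - 1L); left[l] <- left[l] - 1L
              }
            } else if (u < 2 * config$D) {
              if (left[l] + 1L <= right[l] && can_enter(l, 1L, left[l] + 1L)) {
                move_leg(left[l], left[l] + 1L); left[l] <- left[l] + 1L
              }
            }
          }
        } else {  # motor = left leg, anchor = right leg
          if (stats::runif(1) < config$v && can_enter(l, 1L, left[l] - 1L)) {
            move_leg(left[l], left[l] - 1L); left[l] <- left[l] - 1L
          }
          if (config$D > 0) {
            u <- stats::runif(1)
            if (u < config$D) {
              if (can_enter(l, 2L, right[l] + 1L)) {
                move_leg(right[l], right[l] + 1L); right[l] <- right[l] + 1L
              }
            } else if (u < 2 * config$D) {
              if (right[l] - 1L >= left[l] && can_enter(l, 2L, right[l] - 1L)) {
                move_leg(right[l], right[l] - 1L); right[l] <- right[l] - 1L
              }
            }
          }
        }
      } else {  # two-sided: both legs extrude outward
        if (stats::runif(1) < config$v && can_enter(l, 1L, left[l] - 1L)) {
          move_leg(left[l], left[l] - 1L); left[l] <- left[l] - 1L
        }
        if (stats::runif(1) < config$v && can_enter(l, 2L, right[l] + 1L)) {
          move_leg(right[l], right[l] + 1L); right[l] <- right[l] + 1L
        }
      }
    }
    if (si <= length(sample_at) && step == sample_at[si]) {
      samples[[si]] <- cbind(left = left, right = right)
      si <- si + 1L
    }
  }
  list(samples = samples)
}

#' @export
print.loop_ensemble <- function(x, ...) {
  cat(sprintf("<loop_ensemble> %d samples, %d LEFs/chrom, mean loop %.1f bins\n",
              length(x$samples), x$config$n_lefs, mean(x$loop_lengths)))
  invisible(x)
}

#' Contact map from a loop ensemble
#'
#' Effective-distance construction: within each sampled configuration, the
#' distance between two bins is the shortest path in the graph whose edges
#' are adjacent-bin steps (weight 1) plus each LEF's anchor-tip shortcut
#' (weight 1); the contact value is the mean over configurations of
#' `(d_eff + d0)^(-alpha)`. With no LEFs this reduces to the pure power-law
#' background `(s + d0)^(-alpha)`, so `alpha` sets the background P(s)
#' slope. Inter-chromosomal pixels are `NA`.
#'
#' @param ensemble a [simulate_lefs()] ensemble.
#' @param alpha background decay exponent (> 0). The default 1.5 is the
#'   contact-probability exponent of an ideal (Gaussian) polymer chain.
#' @param d0 distance offset (>= 0, default 1).
#' @return a balanced-convention [contact_map()] (unit weights).
#' @export
loops_to_contact_map <- function(ensemble, alpha = 1.5, d0 = 1) {
  stopifnot(inherits(ensemble, "loop_ensemble"))
  if (alpha <= 0) stop("alpha must be > 0")
  if (d0 < 0) stop("d0 must be >= 0")
  if (length(ensemble$samples) == 0) stop("empty ensemble")
  bins <- ensemble$genome$bins
  n <- n_bins(bins)
  v <- matrix(NA_real_, n, n)
  for (ci in seq_along(ensemble$chrom_names)) {
    cn <- ensemble$chrom_names[ci]
    idx <- chrom_bin_range(bins, cn)
    loops <- lapply(ensemble$samples, function(m) {
      sel <- m[, "chrom"] == ci
      matrix(as.integer(m[sel, c("left", "right")]), ncol = 2)
    })
    v[idx, idx] <- .contact_from_loops_cpp(length(idx), loops, alpha, d0)
  }
  contact_map(bins, v, weights = rep(1, n), balanced = TRUE)
}

#' LEF occupancy track
#'
#' Mean number of LEF legs (anchors + tips) per bin per sampled
#' configuration — the simulator's analog of a condensin DC ChIP signal.
#' The track sums to `2 * n_lefs` per chromosome in every sample.
#'
#' @param ensemble a [simulate_lefs()] ensemble.
#' @return [scalar_track()] on the simulation bins.
#' @export
occupancy_track <- function(ensemble) {
  stopifnot(inherits(ensemble, "loop_ensemble"))
  if (length(ensemble$samples) == 0) stop("empty ensemble")
  bins <- ensemble$genome$bins
  counts <- numeric(n_bins(bins))
  for (m in ensemble$samples) {
    gidx <- c(bins$offsets[ensemble$chrom_names[m[, "chrom"]]] + m[, "left"],
              bins$offsets[ensemble$chrom_names[m[, "chrom"]]] + m[, "right"])
    t <- tabulate(gidx, nbins = n_bins(bins))
    counts <- counts + t
  }
  scalar_track(bins, counts / length(ensemble$samples))
}

#' Synthetic expression changes under occupancy-linked repression
#'
#' Gene-level log2 fold-changes generated as
#' `log2fc = -r * occupancy(TSS bin) + Normal(0, noise_sd)`: repression is
#' proportional to local condensin occupancy but weak relative to the
#' per-gene noise, so that only domain-level averaging detects it (the
#' regime observed for ectopic recruitment on an autosome).
#'
#' @param occupancy [scalar_track()] from [occupancy_track()].
#' @param genes data.frame `gene, chrom, tss` (TSS in bp, 0-based).
#' @param r repression coefficient (>= 0) in log2 units per occupancy unit.
#' @param noise_sd per-gene noise standard deviation (> 0).
#' @param seed RNG seed.
#' @return data.frame `gene, chrom, tss, log2fc`.
#' @export
synthetic_expression <- function(occupancy, genes, r = 0.5, noise_sd = 1,
                                 seed = 1) {
  stopifnot(inherits(occupancy, "scalar_track"), r >= 0, noise_sd > 0)
  set.seed(seed)
  gi <- bin_index(occupancy$bins, genes$chrom, genes$tss)
  occ <- occupancy$values[gi]
  occ[is.na(occ)] <- 0
  data.frame(gene = genes$gene, chrom = genes$chrom, tss = genes$tss,
             log2fc = -r * occ + stats::rnorm(nrow(genes), 0, noise_sd))
}
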