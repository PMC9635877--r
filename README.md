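# rexloop

Loop-extrusion simulation and contact-map statistics for condensin-driven
chromosome organization, built around *C. elegans* dosage compensation.

## The problem

The X chromosomes of *C. elegans* hermaphrodites are organized into
loop-anchored TADs by condensin DC, an X-specific condensin recruited to
*rex* elements from which it spreads and represses transcription ~2-fold.
The working model: rex sites are both **loading sites** and
**bidirectional probabilistic barriers** for condensin DC, a **one-sided
loop extruder** whose inactive anchor is **displaceable**. `rexloop` is for
researchers who want to exercise that model quantitatively: it pairs a 1D
lattice simulator of the mechanism with the Hi-C and ChIP-seq statistics
used to read its signatures, so every analytical claim can be tested on
synthetic contact maps of known ground truth at desk scale.

## What it computes

**Simulator** (`build_sim_genome`, `lef_config`, `simulate_lefs`,
`loops_to_contact_map`, `occupancy_track`, `synthetic_expression`) —
fixed-timestep kinetics of loop-extruding factors (LEFs) on binned
chromosomes: loading at rex ∝ strength, extrusion at speed *v*, anchor
diffusion *D*, unloading *k*<sub>off</sub>, stalling with probability
*p*<sub>stall</sub> per barrier encounter; contact maps via shortest-path
effective distances, `(d_eff + d0)^(-α)` averaged over sampled loop
configurations.

**Contact-map statistics** —

* `balance_ice(map, max_iters, mad_max, ignore_diags, tol)`: iterative
  correction with MAD-based bin filtering; valid marginals average 1.
* `expected_by_distance` / `observed_over_expected` / `log2_ratio_map`:
  group-aware distance-decay normalization (the X and autosomes have
  distinct P(s), so expecteds are computed per chromosome group).
* `compute_ps` → `log_derivative` → `infer_loop_size`: the P(s) shoulder
  read-out — the local maximum of d log P / d log s marks the mean loop
  size.
* `compute_ev1`, `saddle_strength`, `local_strength_profile`,
  `compare_conditions`: A/B compartment eigenvector and the
  within/between-compartment contact ratio, chromosome-wide or per 2-Mb
  tile.
* `insulation_score`, `differential_insulation`, `remap_for_insertion`:
  diamond insulation (log2, chromosome-centered), insertion-genome
  coordinate handling, and insertion-minus-wild-type differencing.
* `on_diagonal_pileup`: O/E meta-plots at anchor sets (e.g. strong rex
  sites); `antidiagonal_enrichment`, `flame_enrichment`,
  `corner_enrichment` quantify two-sided vs one-sided extrusion
  signatures.

**ChIP and expression** — `ratio_track` (input normalization),
`rescale_xa` (`xf = (xi − A)/(X − A)` with A the autosomal mean excluding
chrII and X the chrX mean), `chrom_summary`, `consensus_peaks` (strict
majority across replicates), `rex_signal_ratio` (400-bp windows vs
endogenous strong rex), `domain_expression_change` (mean log2 fold-change
in 200/500-kb bins) and `domain_repression_test`.

## Worked example

Simulate the default X-like chromosome (10 Mb at 10-kb bins, 34 rex sites
— one per ~300 kb), then read the loop size back off the contact map:

```r
library(rexloop)

rex <- data.frame(chrom = "chrX", pos = (seq_len(34) - 0.5) / 34 * 1e7,
                  strength = 1, p_stall = 0.9)
genome <- build_sim_genome(c(chrX = 1e7), bin_width = 1e4, rex)
config <- lef_config(n_lefs = 40, mode = "one_sided_rex_loading", seed = 7)
ens <- simulate_lefs(genome, config)
ens
#> <loop_ensemble> 200 samples, 40 LEFs/chrom, mean loop 19.9 bins

map <- loops_to_contact_map(ens)
dv <- log_derivative(compute_ps(map))
sprintf("inferred mean loop size: %.0f kb (simulator truth: %.0f kb)",
        infer_loop_size(dv, c(3e4, 3e6)) / 1e3, mean(ens$loop_lengths) * 10)
#> "inferred mean loop size: 225 kb (simulator truth: 199 kb)"

ins <- insulation_score(map, window = 5e5)
rex_bins <- bin_index(genome$bins, rex$chrom, rex$pos)
sprintf("median insulation at rex bins: %.3f; elsewhere: %.3f",
        median(ins$values[rex_bins], na.rm = TRUE),
        median(ins$values[-rex_bins], na.rm = TRUE))
#> "median insulation at rex bins: -0.055; elsewhere: -0.008"

occ <- occupancy_track(ens)
sprintf("occupancy at rex bins vs genome mean: %.2f vs %.2f",
        mean(occ$values[rex_bins]), mean(occ$values))
#> "occupancy at rex bins vs genome mean: 0.18 vs 0.08"
```

The shoulder of the P(s) log-derivative recovers the realized mean loop
(~200 kb, the loop scale of the embryonic X); rex bins insulate relative
to their surroundings and accumulate more than twice the average condensin
occupancy. The methods vignette
(`vignettes/condensin-dc-methods.Rmd`) documents the model, every tunable
parameter, and the numerical choices.

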