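---
title: "Models and methods: loop extrusion from rex sites and the Hi-C statistics that read it out"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: loop extrusion from rex sites and the Hi-C statistics that read it out}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The biological model

In *C. elegans* hermaphrodites, the dosage compensation complex carries a
specialized condensin (condensin DC) that binds both X chromosomes and
halves their transcriptional output. Condensin DC is recruited to a small
set of *rex* elements and spreads from them, building loop-anchored TADs
that autosomes lack. `rexloop` encodes the mechanistic picture in which

* a rex site is a **loading site**: condensin DC enters chromatin there, in
  proportion to a per-site strength;
* a rex site is a **bidirectional, probabilistic barrier**: a translocating
  condensin meeting a rex is blocked with probability `p_stall`, regardless
  of approach direction;
* condensin DC is a **one-sided loop extruder**: one motor leg reels in
  chromatin while the other (the anchor) is inactive;
* the **anchor is displaceable**: of the several proposed displacement
  routes (a second SMC complex, subsequent loading, translocation without
  looping, diffusion), the simulator implements the diffusion variant, as a
  ±1 random walk at rate `D`.

The package provides (i) a 1D lattice simulator of this model that emits
contact maps, occupancy (ChIP-like) tracks and expression tables, and (ii)
the Hi-C/ChIP statistics used to interrogate such data: ICE balancing,
distance-decay P(s) with log-derivative loop-size inference, compartment
eigenvectors and saddle strength, diamond insulation, on-diagonal pileups,
and X/A ChIP rescaling. Every analytical claim can therefore be exercised
end to end on synthetic data of known ground truth.

# The simulator

## Kinetics

Chromosomes are lattices of `bin_width`-bp bins (10 kb throughout). All
rates are per-timestep probabilities. Per step, each LEF (in random order):

1. unloads with probability `k_off` and instantly reloads according to the
   mode (rex-proportional or uniform; one- or two-sided);
2. advances its motor leg(s) one bin with probability `v`, blocked by
   chromosome ends and by any other LEF's leg (no traversal);
3. in one-sided modes, diffuses its anchor ±1 with per-direction
   probability `D`, confined by its own tip and by other LEFs.

**Barrier semantics.** A leg meeting a barrier draws the stall check *once
per encounter*: with probability `p_stall` it is blocked at that barrier
until the LEF unloads; otherwise it crosses freely. A per-step re-draw
would make sub-unit barriers invisible — a `p_stall = 0.7` barrier would
delay a `v = 1` motor by only ~2 steps against a mean residence of ~80 —
whereas the per-encounter draw makes `p_stall` the long-run blocked
fraction of crossings, which is what barrier strength means operationally.
Barriers gate *every* leg, including diffusing anchors: rex is a barrier to
the complex, not to one leg of it.

Reloading is instantaneous (constant LEF number), standing in for exchange
with a free nuclear pool at steady state. Collisions are strictly blocking,
the standard assumption for eukaryotic SMC complexes.

## From loop configurations to contact maps

Each sampled configuration defines a graph on the lattice: adjacent bins
are connected with weight 1, and each LEF contributes an anchor–tip
shortcut of weight 1. The contact value of a bin pair is the mean over
configurations of `(d_eff + d0)^(-alpha)`, where `d_eff` is the shortest
path. With no loops this is a pure power law, so `alpha` is the background
P(s) exponent.

* `alpha = 1.5` (default): the contact probability exponent of an ideal
  (Gaussian) polymer chain. A shallower background (e.g. `alpha = 1`)
  under-weights short-range contacts so strongly that the P(s) shoulder of
  a dispersed loop population lands well above the mean loop size.
* `d0 = 1` bin: keeps the self-contact finite; immaterial beyond a few
  bins.

This effective-distance construction is a deliberate caricature — it is the
minimal generative bridge from 1D loop configurations to Hi-C-like maps.
The all-pairs shortest-path accumulation is implemented in compiled code
(a BFS per source bin; all edge weights are 1) and is cross-checked in the
tests against a brute-force Floyd–Warshall oracle.

## Study conditions (generator defaults)

The default synthetic X is a 10-Mb chromosome at 10-kb bins (1000 bins)
carrying 34 equally spaced rex sites — about one per 300 kb, the density of
rex elements on the real X (~60 sites over ~17.7 Mb); the 17 odd-numbered
sites play the role of the "strong" rex subset for pileups. Kinetic
defaults: `n_lefs = 40` per chromosome, `v = 1`, `D = 0.5`,
`k_off = 0.012`, `p_stall = 0.9`. These were fixed once, on two grounds:

* `k_off = 0.012` with `v = 1` puts the realized mean loop at ≈ 20 bins
  (200 kb at 10-kb bins), the loop scale reported for the embryonic X;
* `p_stall = 0.9 < 1` keeps barriers probabilistic — flames extend past a
  rex with the observed partial penetrance — and `D = 0.5` (a freely
  diffusing anchor) prevents the permanent pile-ups that single-bin loading
  sites otherwise produce under strict mutual blocking.

Simulations discard 1000 burn-in steps and record 150–200 configurations
every 10 steps; tests use 120–150 samples on 500–1000-bin chromosomes.

## What the generator does and does not emulate

It emulates: a power-law contact background with a controllable exponent;
TAD-like enrichment between barriers; flames from anchored one-sided
extrusion; corner peaks between paired rex sites; insulation dips at
barriers; a secondary anti-diagonal under two-sided point loading;
occupancy decaying with distance from rex; and domain-level repression
proportional to occupancy with per-gene noise.

It does not emulate: polymer physics (no excluded volume, no
distance-dependent capture radius), trans contacts, replication or
cell-cycle heterogeneity, mappability/GC bias, read sampling noise, or
cohesin acting alongside condensin DC. Passing tests therefore demonstrate
internal consistency of method and model at desk scale, not performance on
sequencing data.

Two regime dependencies deserve emphasis, both consistent with the cited
simulation literature on one-sided extrusion:

* **corner peaks require stable anchors.** With the default diffusive
  anchor the pair-pixel dot between two rex sites washes out (ratio to
  matched-separation background ≈ 0.5); with `D = 0` it is strong (≈ 5–6).
  The corner-peak demonstrations therefore run at `D = 0`.
* **insulation at a pure loading site can be positive.** Oppositely
  oriented LEFs co-anchored at one rex bridge its two sides through their
  shortcut edges, so a strong loading site in this construction *gains*
  cross-contacts. A clean insulation dip is produced by the barrier
  function, which is how the barrier-strength experiments are set up
  (uniform loading, barrier-only rex).

# The analysis stack

## Balancing

`balance_ice()` follows the standard iterative-correction recipe: bins
whose log10 marginal deviates from their chromosome's median by more than
`mad_max = 5` MADs are invalidated, the first `ignore_diags = 2` diagonals
are excluded from marginal sums, and weights are iterated (at most
`max_iters = 500` rounds) until the variance of scaled valid marginals
falls below `tol`. Balanced values are rescaled so valid marginals average
1, making the output scale deterministic. `tol = 1e-9`: a looser tolerance
(1e-5) leaves the marginal coefficient of variation near 3e-3, visibly
short of the 1e-4 the rest of the stack assumes; 1e-9 costs only a few
extra iterations on desk-scale maps.

## P(s), log-derivative, loop size

Separations are pooled into geometric bins (`log_bin_factor = 2^(1/8)`).
Each bin's representative `s` is the pixel-weighted log-centroid of its
integer separations — for single-separation bins this is the separation
itself, which matters: a geometric edge midpoint mis-centers those bins by
half a bin and imprints a ±0.09 oscillation on the slope of a perfect
power law.

`log_derivative()` smooths log10 P against log10 s with *local linear*
kernel regression (`smooth_sigma = 0.1` in log10 units) before central
differencing. Local linear fits are design-adaptive: a pure power law
passes through exactly, whereas a kernel-weighted mean is biased wherever
the log-binned points are unevenly spaced (up to 0.095 in slope on the
same test). `infer_loop_size()` returns the `s` of the most prominent
local maximum of the slope, requiring prominence ≥ 0.02 so that numerical
wiggle never counts as a shoulder; ties break toward smaller `s`; a
monotone slope yields `NA`.

Under the study conditions the inferred shoulder sits at ~1.1× the realized
mean loop length (225 kb vs ~200 kb) — the shoulder reflects the
steady-state loop population, whose older, longer loops dominate the
contact signal relative to the just-reloaded short ones.

## Compartments

`compute_ev1()` takes the leading eigenvector of the correlation matrix of
the O/E submatrix over a region (use chromosome center regions; arms
behave differently), sign-oriented by positive correlation with a
reference track (gene density or active-state coverage). Saddle strength
uses EV1 halves (k = 2): the pooled mean O/E over AA and BB pixel pairs
divided by the pooled mean over AB pairs, with the first two diagonals
excluded. Pixel-pooled means rather than sums remove pair-count imbalance;
with equal-size quantiles the two coincide up to weighting.
`local_strength_profile()` recomputes EV1 and strength per non-overlapping
2-Mb tile (tiles with < 10 valid bins are `NA`), and
`compare_conditions()` forms between-condition ratios of such tracks.

## Insulation

The diamond score at bin *i* is the mean balanced contact in
`[i−w, i) × [i, i+w)` (window 500 kb by default), log2-normalized by the
chromosome's geometric mean diamond — so scores average zero per
chromosome, are invariant to global rescaling, and dips mark boundaries.
Boundary *calling* is deliberately not implemented; differences between
conditions (`differential_insulation()`, after `remap_for_insertion()`
projects wild-type data onto an insertion genome) are the quantitative
object.

## Pileups and signatures

`on_diagonal_pileup()` averages O/E submatrices centered at anchor bins
(flank 250 kb), dropping anchors within a flank of a chromosome end;
strand is ignored because rex barriers are bidirectional. The signature
metrics compare a structure against matched-separation background:
flames against bootstrap means of randomly placed pixel sets, the
anti-diagonal against the *local quadrant* at the same separations
(co-loaded opposite one-sided LEFs enrich the whole quadrant, so only a
ridge that stands above its own quadrant counts as the two-sided
signature), and corner peaks against single pixels at the pair separation.

## ChIP rescaling and domain expression

`rescale_xa()` implements `xf = (xi − A) / (X − A)` with `A` the mean over
autosomes excluding chrII and `X` the chrX mean, anchoring those group
means at exactly 0 and 1. chrII is excluded because it is the chromosome
that receives ectopic rex insertions, making it an unreliable baseline
across strains. `chrom_summary()` applies the same affine convention to
per-chromosome means or peak counts. `consensus_peaks()` keeps pooled
peaks supported by strictly more than half of the replicates (both of two).
`rex_signal_ratio()` compares a 400-bp midpoint-centered window at a site
against the mean over reference rex sites. `domain_expression_change()`
averages per-gene log2 fold-changes by TSS bin (200-kb and 500-kb bins are
the usual domain scales; no length weighting), with an optional
permutation test (`domain_repression_test()`) since no specific test is
canonical.

# Numerical and design choices, collected

* Coordinates 0-based half-open; bin indices genome-global, 1-based in R.
* COO text + chromsizes sidecar is the interchange format; HDF5 (cool)
  containers are not read — convert externally.
* ICE: MAD filter two-sided in log10 space per chromosome; `tol = 1e-9`
  on marginal variance; non-convergence warns and flags the best iterate.
* Insertion remapping quantizes insertions to whole bins so that composing
  two remaps equals the combined remap exactly.
* `log2_ratio_map()` computes `log2(a+pc) − log2(b+pc)`, making argument
  swap an exact negation; with `pc = 0`, zeros become missing.
* Saddle quantiles are equal-sized by construction (rank, ties by first
  occurrence); EV1 sign falls back to largest-|entry|-positive without a
  reference.
* Peak prominence: walk to the nearest higher point on each side, take the
  higher of the two intervening minima.
* Barrier stall: one draw per leg–barrier encounter (see above).

# Known limitations

* The effective-distance map is not a polymer model; absolute contact
  values and the detailed shape of flames/dots should not be compared
  against sequencing-derived maps, only their presence/absence and
  relative ordering.
* Anchored loading at a shared bin bridges the two sides of a rex (positive
  insulation at pure loading sites), a construction artifact discussed
  above.
* One diffusion-based anchor-displacement mechanism is implemented; the
  alternatives (displacement by another SMC, by subsequent loading, or by
  non-looping translocation) are not distinguishable in this framework.
* Balancing convergence tolerance and terminal short-bin handling are this
  package's choices; upstream pipelines may differ in both.

# Problem sizes

Tests and the acceptance script run on 200–1000-bin chromosomes with
10–50 LEFs, 120–200 sampled configurations, and 3 seeds per stochastic
claim; these sizes make every property measurable with comfortable margins
on a single CPU.
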