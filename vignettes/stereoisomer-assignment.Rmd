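---
title: "Joint stereoisomer assignment from grouped NMR shift sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint stereoisomer assignment from grouped NMR shift sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereomatch)
```

## The assignment problem

A group of n stereoisomers of the same compound has been synthesised and
their ¹³C spectra recorded, and for each candidate configuration a shift set
has been predicted by quantum chemistry (GIAO shieldings on a conformer
ensemble). The task is to decide which experimental set belongs to which
predicted — hence which configuration each measured sample has.

The classic route scores each experimental set separately against every
calculated set with per-atom errors Δδ = δ_calc − δ_exp, summarised as
MAE = mean |Δδ|, or with DP4-style probabilities. Its weakness is
structural: diastereomer shift sets are frequently *more similar to one
another* than the typical prediction error. `rmsd_summary()` quantifies
this — when the average pairwise RMSD between the isomers' sets is of the
same order as the per-set MAE against the truth, the per-set ranking can
select the same calculated candidate for two different samples, and the
group-level assignment is left inconsistent.

## The joint statistic

`rank_alignments()` treats the group as the unit. The calculated sets form
a fixed sequence; each of the n! orderings of the experimental sets (one
*comparison alignment*, `enumerate_alignments()`) is scored by comparing
pairwise *differences*:

* for each unordered pair of positions i < j, the calculated difference set
  Δδ_calc(i,j) = δ_calc,i − δ_calc,j and the aligned experimental
  difference set Δδ_exp(σ(i),σ(j)) are formed per atom
  (`pair_difference_sets()`);
* their per-atom absolute discrepancy ΔΔδ = |Δδ_calc − Δδ_exp|
  (`dd_delta()`) is averaged over all n(n−1)/2 pairs and all shared atoms
  (`mae_dddelta()`), giving MAE_ΔΔδ with
  n_ΔΔδ = n(n−1)/2 × (atom count) terms.

The alignment with the lowest MAE_ΔΔδ is the proposed correspondence. Two
structural properties make this more robust than averaging per-set MAEs
(also available, `avg_mae_per_alignment()`):

* **calibration invariance** — adding a constant to every calculated (or
  every experimental) set leaves every MAE_ΔΔδ unchanged, because
  constants cancel inside each difference set. Reference-compound and
  level-of-theory offsets therefore cannot steer the ranking;
* **joint consistency** — an alignment must explain all pairwise contrasts
  simultaneously; a single calculated set cannot "win twice".

Both properties are asserted literally in the test suite, together with an
exhaustive brute-force cross-check of every score on random small bundles.

### Assumptions

The statistic assumes matched carbons: every compared atom label must carry
a resolved assignment in every set. Exchangeable or overlapping
experimental peaks must be resolved to atom labels upstream; `study_bundle()`
drops any label missing from at least one set (with a warning) rather than
guess. It also assumes the n experimental sets really are a permutation of
the n candidates — the method ranks permutations only and cannot flag "none
of the above".

## Upstream: shieldings to shifts

`read_conformer_table()` ingests per-conformer relative energies and
isotropic shieldings. The pipeline applies:

* `energy_window_filter()` — drop conformers above an energy window
  (default 3.0 kcal/mol ≡ 12.5 kJ/mol, the customary cutoff for shielding
  ensembles);
* `boltzmann_weights()` — w_i ∝ exp(−ΔE_i/RT). Exponential weighting at
  T = 298.15 K is the standard reading of "Boltzmann averaging"; both the
  temperature and the energy unit (kcal/mol default; kJ/mol, hartree) are
  explicit parameters because upstream programs disagree on units;
* `average_shieldings()` — population-weighted per-atom mean;
* `calibrate_multistandard()` — TMS reference for sp³ carbons
  (δ = σ_TMS − σ), benzene for sp² (δ = σ_benzene − σ + 128.37 ppm).
  Carbonyl carbons are excluded from the benzene rule by convention; which
  standard they use is genuinely underdetermined, so it is a parameter
  (`carbonyl_policy`, default `"tms"`). The reference shieldings
  σ_TMS/σ_benzene have **no default**: they are specific to the
  functional/basis set and must be computed at the same level as the
  solute.

Calibration is affine, so it commutes with Boltzmann averaging; the suite
verifies both routes agree to 1e-12. Note the joint statistic does not
actually need calibration at all — constant offsets cancel — so the
pipeline matters mainly for the classic per-set diagnostics.

## The synthetic generator

`generate_bundle()` emulates the tabular structure of a real isomer-group
study: a base carbon skeleton with sp³ shifts uniform in 10–80 ppm and sp²
in 100–170 ppm; independent per-atom, per-isomer N(0, contrast_sd)
perturbations as the configuration-dependent contrast (default 2.0 ppm,
which puts typical per-atom inter-isomer differences in the 0–4 ppm range
seen in real diastereomer groups); N(0, noise_sd) experimental noise
(default 0.3 ppm); an optional constant calculated-side offset emulating
calibration error; and a known ground-truth permutation. Everything is
deterministic given the integer seed, and the generator restores the
caller's RNG state.

What it does **not** emulate: correlated shift perturbations across
neighbouring stereocenters, atom-specific prediction-error profiles
(sp²/carbonyl carbons err differently in practice), peak overlap, or any
real conformational physics. Passing the recovery experiment therefore
demonstrates the engine's correctness and statistical power under idealised
independent noise — not prediction accuracy on real molecules, which is
owned by the upstream quantum chemistry.

The regression experiment fixed by the generator's defaults: 200 seeded
tetrads (n = 4, 18 carbons, 2.0 ppm contrast, 0.3 ppm noise) must yield the
true permutation at rank 1 in at least 95% of replicates. A companion
constructed fixture reproduces the per-set ambiguity phenomenon
deterministically: an experimental set built as a 0.4/0.6 mixture of two
isomers' predictions makes per-set MAE pick the same calculated set for two
samples, while every pairwise difference still favours the true alignment
(per atom, 0.6|d| < |d| < 1.4|d|), so MAE_ΔΔδ resolves it exactly.

## Numerical and design choices

* Unordered pairs are used once each; reversing a pair's orientation flips
  the sign of both difference sets and leaves ΔΔδ unchanged (tested), so
  enumerating ordered pairs would only double the work.
* Schemes are 1-based permutations of `1:n`, lexicographically enumerated
  with the identity first; ties within 1e-9 ppm are reported (`ties`,
  `tie` column), never silently broken — enumeration order affects display
  only.
* Enumeration is exhaustive; n! is desk-scale for realistic n. A guard
  (`max_sets`, default 8 → at most 40320 schemes) protects against
  accidental large n.
* Plain double-precision summation: with shift magnitudes ≤ 250 ppm and at
  most a few thousand terms, worst-case rounding is far below any decision
  threshold; compensated summation would be noise here.
* Degenerate inputs are hard errors with named offenders: duplicate atom
  labels, non-numeric shift cells, unknown hybridization tokens, empty
  label intersections, non-permutation schemes, empty ensembles. Missing
  shift cells are `NA` (absent), never zero.
* The DP4-style backend is a generic single-component location-scale
  t-density over errors, normalised across candidates in log space.
  Published parameterisations (Goodman's DP4, Sarotti's DP4+) belong to
  their own calibrations; the backend takes their parameters via
  `probability_params()` and deliberately ships none, nor the DP4+
  scaled/unscaled and sp²/sp³ partitioning.

## Problem sizes

The shipped tests run bundles of n ≤ 5 with up to 20 atoms, a 100-bundle
brute-force equivalence sweep, and the 200-replicate recovery experiment —
a few minutes end to end on one core, since a full 24-scheme tetrad ranking
costs well under a millisecond. `scripts/acceptance.R` re-derives the
headline quantities from a single `--seed` in a few seconds.

## Limitations

* The ranking proposes a best permutation and its gap to second place; it
  attaches no probability to that margin, and no significance threshold
  for "how much lower is low enough" is defined.
* All experimental sets must belong to the candidate pool; mixtures,
  impurities, or a missing candidate break the permutation premise
  silently (the best available permutation is still returned).
* Comparisons run on the label intersection of all 2n sets, so one
  unassigned carbon in one set removes that carbon everywhere.
* Atom-wise error weighting (e.g. down-weighting carbons near flexible
  regions) is not implemented; all shared atoms count equally.
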