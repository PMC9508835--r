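---
title: "Methods: SHAPE-directed structure-function analysis of 5'-UTRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SHAPE-directed structure-function analysis of 5'-UTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrfold)
```

# The problem

Secondary structure in a 5' untranslated region can control how
efficiently a ribosome reaches and initiates at the start codon.
`utrfold` implements a complete desk-scale pipeline for dissecting this
relationship with tiled structure-destabilizing mutagenesis: a panel of
six-nucleotide `5'-UUAUUA-3'` substitutions is tiled across a G/C-rich
5'-UTR, each variant's structure is probed chemically (SHAPE-MaP), probing
data steer thermodynamic structure models, mutant structural landscapes
are clustered into groups, start-codon accessibility is scored as a
non-equilibrium unfolding cost, and the structural scores are related to
reporter translation. A synthetic-data generator supplies every input the
pipeline needs, so the entire analysis is testable end to end without
sequencing data.

# Reactivity calling

The pipeline consumes per-nucleotide mutational-profiling (MaP) rate
tables: apparent mutation rates and read depths for a reagent-modified
sample and an untreated control.

* **Raw reactivity** is `rateMod - rateUnt` (two-condition design, no
  denatured control). Nucleotides with read depth below 4000 in either
  channel are masked rather than reported, the standard depth filter for
  MaP data.
* **Normalization** uses the 2%/8% rule: unmasked values are ranked, the
  top 2% are set aside as outliers, and everything is divided by the mean
  of the next 8%, so that band averages 1 after scaling. The rule is
  scale-equivariant; negative raw values are retained (the folding stage
  decides their energetic treatment). At least 20 unmasked positions are
  required.
* **Direct reactivity** is `ln(rateMod / rateUnt)`, masked wherever a
  depth is below 4000 or a rate is zero.
* **Replicate averaging** takes the arithmetic mean and standard error
  across biological replicates and masks positions whose SEM reaches 50%
  of the absolute mean. With a single replicate the SEM is undefined and
  the rule cannot be evaluated, so the position is left unmasked; with a
  zero mean and positive SEM the rule (read as `SEM >= 0.5 * |mean|`)
  masks. Masks only grow along the pipeline.

# The folding engine

Structure prediction is a Zuker-style minimum free energy (MFE) dynamic
program and a McCaskill partition function over nested structures with
Watson-Crick and GU pairs, minimum hairpin loop 3, and a maximum pairing
span of 600 nt (default). Both use the same reduced nearest-neighbor
energy model, shipped as plain-text tables under `inst/extdata/`:
stacking free energies for the six pair types, hairpin/bulge/internal
loop length penalties with Jacobson-Stockmayer extrapolation beyond 30
unpaired nucleotides (`dg(n) = dg(30) + 1.75 RT ln(n/30)`), and an
affine multibranch model (offset 3.4, 0.4 per branch, 0 per unpaired
nucleotide), all at 37 °C. Interior loops are capped at 30 unpaired
nucleotides in the search, the standard restriction.

The model deliberately omits dangling ends, coaxial stacking and special
hairpin sequences. Correctness is defined not by agreement with any
published parameter set but by an exhaustive-enumeration oracle: for
random short sequences the test suite enumerates every valid nested
structure, scores each with `evaluate_energy()`, and requires the DP
minimum and the Boltzmann pair probabilities to match to 1e-6 (observed
agreement is at machine precision). The analyses downstream are
threshold- and ranking-based, for which this reduced model is sufficient
and fully self-consistent.

**SHAPE pseudo-free energies.** A reactivity `S` contributes
`1.8 * ln(S + 1) - 0.6` kcal/mol, the standard slope/intercept pair,
added once per helix stack each of the stack's four nucleotides
participates in — helix-internal nucleotides accrue it twice, helix ends
once. Missing data contribute 0, so an all-missing profile reproduces
the unguided fold exactly. Reactivities at or below -1 (undefined
logarithm) are treated as missing with a warning; values between -1 and
0 are evaluated as written.

**Numerics.** The partition function is rescaled per nucleotide by
`exp(E_mfe / (RT n))`, which keeps every inside/outside quantity in
double range up to the 1200-nt single-window guard; the scale factors
cancel exactly in `P(i,j)`. The multiloop grammar is unambiguous, so
each structure is counted once. MFE ties are broken toward fewer pairs
(tracked as a secondary DP objective), then by a fixed traceback order,
making results deterministic.

**Energy evaluation of fixed structures** (`evaluate_energy()`)
decomposes a structure into loops and sums the same tables, in the
manner of the classic `efn2` tool; on the MFE structure it reproduces
the DP energy exactly, a property the suite checks on hundreds of random
sequences.

# Differential reactivity

`delta_shape()` compares two profiles in the style of the deltaSHAPE
framework with its published defaults, which the package exposes as
arguments: smoothing window 5, Z-factor `1 - 1.96 (SEM_a + SEM_b) /
|mu_a - mu_b| > 0`, standard score `|Z| >= 1` against the profile-wide
difference distribution, and a nucleotide is called only when at least 3
positions in its window (itself included) pass both tests. Excluded
intervals (primer-binding sites) can never be called. Swapping the
profiles flips every call's direction and nothing else.

# Structure comparison and the mutant landscape

Structure models are compared at the base-pair level: `sens` is the
fraction of reference pairs recovered, `ppv` the fraction of model pairs
present in the reference, and their arithmetic mean is the overall
similarity. Pair sets come from pairing-probability matrices thresholded
at 0.1 (inclusive), restricted to the 5'-UTR region of interest
(conventionally positions +1 to +270). Two empty sets count as perfect
agreement; an empty set against a non-empty one scores zero. Because the
direction of comparison is not symmetric, `overall_similarity()` takes
B as reference by default and offers a symmetrized variant, which
`build_similarity_matrix()` uses so the landscape matrix is symmetric.

The landscape analysis projects the (column-centered) similarity matrix
onto its first two principal components (signs fixed by the
largest-magnitude loading), selects the number of structure groups by
the inertia elbow, and groups constructs by k-means (100 restarts, fixed
seed, labels renumbered by first appearance so input order is
cosmetic). Each group's centroid construct is the member nearest the
group mean.

Two choices here were genuinely open:

* **Clustering space.** K-means runs on the 2-D projection by default
  (matching the visualize-then-cluster reading of the procedure); a flag
  clusters the full similarity rows instead.
* **Elbow rule.** The elbow is the `k` maximizing the second difference
  of the *log* inertia curve. The raw second difference of a convex
  decreasing curve is generically largest at the first drop (it picks
  `k = 2` regardless of structure); on the log scale the statistic
  locates where the relative improvement collapses, which is the elbow
  in the operative sense. `k` remains user-overridable.

# Start-codon accessibility and translation

The accessibility score is the non-equilibrium unfolding cost
`dG_unfold = dG_constrained - dG_reference`: the constrained structure
is the reference minus every pair with *either* endpoint within `±w`
nucleotides of the start-codon adenosine (default `w = 15`, sweep 13-16
available), and both structures are evaluated thermodynamically — no
pseudo-energies, even for SHAPE-directed references, mirroring
`efn2`-style evaluation (a flag includes them). The RNA is not allowed
to refold: all other pairs are untouched.

Two properties deserve care. When the reference is the thermodynamic MFE
structure, `dG_unfold >= 0` holds by optimality, and it is zero exactly
when no pair touches the window; the suite verifies both. The cost is
however **not** monotone in `w`, although the removed-pair set is:
widening the window can delete a destabilizing remnant of a partially
cleared helix (typically a lone pair whose loop penalties outweigh its
stacking), lowering the constrained energy. This is inherent to literal
pair removal under any loop-decomposition energy model, so the package
documents it rather than hiding it; the suite asserts monotonicity of
the removed-pair count instead.

Translation is analyzed from dual-luciferase readouts: per-replicate
nanoluciferase/firefly ratios, divided by the native construct's mean
ratio, summarized as mean ± SD over n = 6 replicates (two plasmid
preparations × three biological replicates in the emulated design).
Effects are classified at a 15% change, boundary inclusive (a relative
translation of exactly 0.85 counts as a decrease). Group comparisons use
Welch's two-tailed t-test by default — group sizes and variances differ
substantially in such panels — with Student's variant behind a flag.
`structure_translation_report()` joins unfolding costs, translation and
group labels into per-group distributions, pairwise tests and overall
Spearman/Pearson correlations.

`scan_uorfs()` scans 5' of the annotated main start codon for AUG and
CUG (extendable to GUG/UUG/ACG) initiation codons opening in-frame
stretches of at least 30 nt, reports the first in-frame stop (or flags
stop-less frames), and notes the favorable `CUG/G` context.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
tested:

* **Mutant panels** tile UUAUUA windows over a G/C-rich (58%) random
  5'-UTR; the region end comes from the construct annotation rather
  than a hard-coded constant.
* **Planted structures** are helix layouts (hairpins or three-helix
  junctions) with randomized stem/loop geometry, G/C-biased stems and
  A/C-biased loops, so the planted fold is thermodynamically realizable
  by design.
* **MaP rate tables** draw per-position binomial mutation counts at
  20000 reads: background probability 0.002 in both channels, plus
  0.004 at paired and 0.03 at unpaired positions in the modified
  channel. These per-read probabilities are tunable conventions chosen
  to place the simulated signal in the regime where the depth-4000
  filter and the differential-reactivity thresholds are meaningful; they
  are not measured constants.
* **Archetype panels** for landscape tests derive alternative global
  folds from the native helix layout, retaining a graded share (60%,
  40%, 20%) of native helices and refilling freed regions. The grading
  matters: independently drawn archetypes are all equally dissimilar (a
  symmetric simplex), a degenerate geometry that a two-component
  projection cannot always resolve, whereas graded sharing mirrors real
  mutant panels, whose groups differ in how much structure they retain.
* **Translation panels** draw six replicate luciferase readouts per
  construct with expected ratio `exp(-beta * dG_unfold)` times
  lognormal noise (`beta = 0.1` per kcal/mol and `sigma = 0.1` by
  default), embedding the structure-translation anti-correlation as
  generative truth for recovery tests.

What passing tests show — and what they do not. The simulations
establish that each stage implements its stated contract and that the
pipeline recovers planted truths (structures at sens/ppv ≥ 0.8 from
depth-20000 probing; four structure groups at ARI ≥ 0.9; the coupling
coefficient within 30%). They do not emulate alignment artifacts,
PCR/UMI error structure, reagent-specific reactivity biases,
pseudoknots, or in-cell effects such as protein occupancy and
translation itself; conclusions about real libraries still require the
upstream read-level controls those effects demand.

# Problem sizes and reproducibility

The shipped tests and the acceptance script run the folding oracle on
500 random sequences of length ≤ 12, fold 43-construct panels of 320-nt
reporters, and cluster 43 × 43 landscapes — sizes chosen so the whole
analysis reruns from scratch in about a minute while exercising every
stage at full fidelity. All stochastic steps (simulation, k-means
restarts) take explicit integer seeds, and every simulator is
bit-reproducible given its seed.

# Known limitations

* The energy model is reduced; absolute energies are not comparable to
  Turner-parameter tools, only the package's own rankings and
  thresholds are meaningful.
* Pseudoknots are out of scope throughout (folding, CT/dot-bracket I/O,
  comparison).
* Sequences longer than 1200 nt are refused rather than folded in
  sliding windows.
* `dG_unfold` monotonicity in the window width does not hold in general
  (see above); per-window sweeps should be read with the removed-pair
  counts alongside.
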