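---
title: "Detecting conserved miRNA hairpins with a structured CRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved miRNA hairpins with a structured CRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpinCRF)
```

## The problem

Most conserved microRNA genes are processed from a fold-back precursor:
Drosha excises a hairpin from the primary transcript, Dicer cuts out a
~22-bp duplex, and one strand (the mature miRNA) is loaded into RISC
while the other (the passenger) is degraded. The hairpin leaves a
characteristic position-specific footprint in comparative-genomics
tracks and in predicted secondary structure: the duplex is strongly
conserved and stably paired; conservation and pairing drop abruptly at
the Drosha recognition base pair (DRB), roughly 13 nt outside the
5'-arm Drosha cut and 11 nt outside the 3'-arm cut; the mature arm is
more conserved than the passenger arm; and mature strands begin with U
far more often than chance. `hairpinCRF` models this anatomy explicitly
so that a genome scan yields both hairpin loci and the position of the
mature 5' end.

## Features

Every position is described by 7 dimensions: the local conservation
score, the same score 20 nt upstream and 20 nt downstream (which let
the model see the conserved-block boundary), an independent
per-position conservation score, the base-pair potential (the largest
pair probability the position participates in), the signed base-pair
distance to that partner, and the nucleotide. The two secondary
structure dimensions come from a partition-function fold.

**Folding.** Pair probabilities are computed exactly under a
pair-additive energy model: each structure is Boltzmann-weighted by the
sum of its pair scores (GC −3, AU −2, GU −1 at `temperature_scale = 1`)
over all pseudoknot-free structures whose pairs span at most `max_span`
(default 120 nt) and enclose at least `min_loop` (default 3 nt,
the steric minimum). The span bound makes the inside–outside dynamic
program banded — O(n·L²) time and O(n·L) memory — so chromosome-scale
input is linear in length. Full thermodynamic parameter sets are out of
scope by design: the algorithmic content (windowed McCaskill
probabilities feeding a position-wise feature vector) is preserved at a
fraction of the complexity, and `base_pair_matrix()` accepts an
external engine's (i, j, p) triplets when a thermodynamic model is
wanted. Note one subtlety this model makes visible: G·U wobble pairs
break strand-reversal symmetry (a G·U pair reverse-complements to a
non-pairing C·A), so the reverse strand is always folded from its own
reverse-complemented sequence rather than by transposing the forward
matrix.

Exterior partition values are kept in log space and the outside band is
normalized by the total partition function, so the recursions do not
overflow on windows up to tens of kilobases. An exhaustive-enumeration
oracle (`enumerate_pair_probabilities()`) computes the same quantities
by listing every legal structure for sequences up to 20 nt; the test
suite holds the DP to within 1e-9 of it.

**Discretization.** Dimensions 1–6 are discretized at the
20/40/60/80th percentiles of the values observed in the training
hairpin windows, nearest-rank convention, with boundary values assigned
to the lower symbol; −∞ (unpaired) in dimension 6 becomes its own
symbol. A position counts as paired when its base-pair potential
reaches `pair_threshold` (default 0.5 — above 0.5 the maximizing pair
is unambiguous in the matching sense); the threshold is exposed because
the "predicted to form a base pair" criterion is genuinely a modeling
choice. `N` bases never pair and encode as the lowest nucleotide symbol
with a flag, so downstream filters can drop N-rich calls.

## The state graph

The CRF decomposes into 12 sub-models: one self-looping Non-miRNA
state; left and right Flanking chains of exactly 20 states (sized to
reach the DRB signal, which sits ~11–13 nt outside the Drosha cleavage
sites); four Mature and two Passenger chains of 25 states each; three
Loop chains of 8 self-looped states. Three paths connect the flanks
through the duplex — Mature–Loop–Passenger, Passenger–Loop–Mature and
Mature–Loop–Mature — one per possible mature-strand location. Each
state has its own 35-entry emission table (alphabet sizes
5+5+5+5+5+6+4), and every edge its own transition weight: 215 emitting
states, 7,525 emission parameters.

Design points that were genuinely open, and how they were fixed:

- **Skip edges.** Mature/Passenger chains run 1→…→25 with extra edges
  from states 17–24 directly to state 25, admitting strand lengths of
  18–25 nt (a length-22 strand uses the 21→25 edge). The range covers
  the observed mature-length variation and is configurable in
  `arch_config()`.
- **Loop topology.** A chain of 8 states, each self-looped: loop
  traversals are at least 8 nt with length preferences learned from
  the transition weights, without spending many states.
- **No parameter tying.** The 5'-arm and 3'-arm Mature sub-models learn
  distinct profiles, matching the observation that mature/passenger
  asymmetries are strong on the 5' arm and weak on the 3' arm.
- **Distinct left/right flanks.** They model different genomic context
  (upstream vs downstream of the hairpin).
- **Anchoring.** Sequences must start and end in the Non-miRNA state;
  training windows carry N-labeled context at both ends and scan
  windows are long enough that the anchor bias never reaches a window
  interior (see "Scanning" below).

## Training

Given labeled windows (labels M/P/L/F/N), the objective is the
label-constrained conditional log-likelihood: the log partition
function of the graph restricted at each position to states carrying
that position's label, minus the log partition function of the full
graph, summed over examples, minus the Gaussian prior Σ_j m_j²/(2c).
Because several states share each label, the constrained term is itself
a latent-variable sum, and both terms are computed by the same scaled
forward–backward kernel (per-position max-shifted emissions,
renormalized alphas, log partition reassembled from the scales). The
gradient is the difference of expected feature counts under the
constrained and full distributions. The prior is written with larger
`c` meaning weaker shrinkage, which matches the direction in which the
selection grid is used; the negative (background) windows enter the
likelihood as all-N-labeled examples.

Optimization is limited-memory quasi-Newton (`optim(method =
"L-BFGS-B")`) from the all-zero start, gradient tolerance 1e-5, at most
500 iterations; non-convergence returns the best iterate with a
warning. All randomness (splits, negative sampling) flows from one
seed, so refits are bit-identical.

**Penalty selection.** Positives are split 80/20; the training group
takes an equal number of negatives. For each candidate
c ∈ {0.1, 1, 10, 50, 100} the model is fitted on the training group and
scored on the validation group by the maximum F-score over a threshold
sweep of the hairpin caller. Ties (common when the validation set is
cleanly separable) break first on the mean F across the sweep — a
flatter, better-calibrated posterior wins — then toward weaker
shrinkage.

**Label repair.** Real annotations contain mature strands outside
18–25 nt and flanks that are not exactly 20 nt. `repair_labels()`
re-projects such labelings onto the nearest graph-feasible one,
adjusting each run at the side facing away from the duplex so repairs
do not cascade, and warns about every change.

## Scanning and calling

`scan_genome()` folds and featurizes the whole strand once, then
decodes overlapping windows (defaults: 2,000 nt with 400-nt overlap;
both ≥ 300 nt enforced) and stitches per-position posteriors, taking
each position from the window in which it lies farthest from a window
edge. Since featurization is global, stitched tracks differ from an
unwindowed decode only through the Non-miRNA anchor bias at window
edges, which decays well below 1e-6 within an overlap length. The
reverse strand is scanned by reverse-complementing the sequence and
reversing the (strand-symmetric) tracks, with coordinates mapped back.

P^mi sums posteriors over all non-background states (equivalently
1 − p_i,Non-miRNA); P^5end sums the four Mature entry states, so
P^5end ≤ P^mi everywhere. Hairpin segments are maximal runs with
P^mi strictly above T that are at least 80 nt long, discarding runs of
150 nt or more; 5'-end calls are positions with P^5end > T, by default
gated to called segments (an ungated mode exists because the gating
convention is not forced by the method). The two thresholds default to
the same T but are exposed separately since evaluation sweeps them
independently.

## Synthetic data: what it does and does not emulate

`generate_hairpin()` builds a hairpin with the anatomy above: a
GC-biased perfect stem (lower stem 13 bp — the DRB distance — plus a
2-nt slack and the 22-nt duplex), substitutions on the 3' side at rate
0.03, a terminal loop of 8–20 nt, and the mature strand placed on the
5' arm, 3' arm, or both (probabilities 0.45/0.45/0.10). The 2-nt
3'-overhang convention links mature and passenger coordinates through
the pair map (`deduce_passenger()` applies π to the interval ends and
shifts by +2; the same formula is its own inverse on a perfect stem).
The mature 5' nucleotide is U with probability 0.8. Conservation is
*synthesized*, not computed from simulated alignments — the scanner
only ever consumes tracks, so tracks are the minimal faithful stand-in:
~0.9 over the hairpin, ~0.2 in flanks, Gaussian dips of depth 0.5 at
the DRB positions (−13 from the duplex start, +11 past its end), noise
sd 0.05; the PhyloP-like track adds independent noise (sd 0.1) and a
+0.25 elevation over mature arms. The GC bias and mutation rate were
calibrated once against the generator's own fidelity property — that
folding a generated hairpin recovers BPP ≥ 0.5 on ≥ 70% of duplex
positions under the simple energy model — and are configuration, not
assertions about real genomes.

`generate_genome()` plants standardized 200-nt hairpin windows (duplex
centered, flanks labeled F for exactly 20 nt each side, N elsewhere)
into background sequence at ≥ 200-nt spacing, along with 200-nt
conserved decoy blocks (mean conservation 0.65–0.85, random sequence)
that force the model to use structure, not conservation alone.
Background training windows are sampled from the low (< 0.4) and high
(> 0.6) mean-conservation bands.

What passing tests on this generator show: that the full pipeline —
folding, featurization, discretization, constrained training, penalty
selection, windowed decoding, calling, evaluation — recovers planted
signal of the modeled shape, deterministically, at realistic
signal-to-noise. What they cannot show: performance on real genomes,
where conservation tracks have alignment artifacts, hairpins deviate
from the modeled anatomy (bulged duplexes, multi-hairpin clusters,
mirtrons are all outside the generator), and negatives include
structured conserved RNAs rather than unstructured conserved blocks.

## Evaluation

`confusion_metrics()` reports sensitivity TP/(TP+FN), positive
predictive value TP/(TP+FP) and their harmonic mean; undefined ratios
are reported as `NA` with a flag, never silently 0, to keep threshold
sweeps honest. 5'-end accuracy counts a call as true when it falls
within 0, 1 or 2 nt of an unmatched true 5' end (nearest-first greedy,
each truth used once); calls outside hairpin intervals are ignored
because negatives are only defined within hairpins. Hairpin ranking
uses ≥ 1-nt overlap by default with a 50%-reciprocal option, since the
overlap criterion is a convention rather than part of the method.
`cross_validate()` holds out one bundle per fold, optionally excluding
training hairpins that share a family with any test hairpin, selects
the penalty on the internal split, and scans the held-out genome.

## Problem sizes and numerical choices

The reference synthetic study used throughout (tests and
`scripts/acceptance.R`) is a 100-kb genome with 20 hairpins and 20
decoys; training uses the 20 positive windows plus 20 banded background
windows, the full penalty grid, and a 19-point threshold sweep. The
oracle checks run 200 random 8–18-nt folds and dozens of small-graph
CRF enumerations. These sizes keep a full study to a few minutes while
leaving the statistics (binomial CIs on recovery rates, gradient checks
at h = 1e-5 against tolerance 1e-4, DP-vs-enumeration at 1e-9)
meaningful. Degenerate inputs are handled explicitly: empty sequences
fold to empty matrices, all-identical codec training values warn and
produce a degenerate codec, infeasible labels name their first bad
position, and zero-denominator metrics stay `NA`.

## Known limitations

- The pair-additive energy model ranks AU-rich stems as less stable
  than a thermodynamic model would; matrices differ numerically from
  any specific folding engine, and the original engine's exact
  invocation is not recoverable. The external-matrix hook exists for
  exactly this case.
- Mature strands shorter than 18 or longer than 25 nt cannot be
  represented without reconfiguring the skip-edge range.
- The scanner assumes strand-symmetric conservation tracks when
  scanning the reverse strand.
- Viterbi decoding is deliberately absent: posterior decoding is the
  method; a single-best path would not compose with the segment rules.
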