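---
title: "Compression-based functional connectivity: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression-based functional connectivity: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpikeNets)
```

This vignette documents the models implemented in SpikeNets, the
parameters that matter, the numerical choices behind them, and — just as
important — what the synthetic validation does and does not show.

## 1. The PPM codec and its use as a similarity engine

`codeLength()` returns the *ideal* code length of a symbol sequence under
a variable-order Markov model estimated online by Prediction by Partial
Matching: at each position the longest matching context predicts the next
symbol; unseen symbols trigger an escape (method C: escape mass equal to
the number of distinct symbols seen), already-seen symbols are excluded at
shorter contexts (full exclusion), and the final fallback is a uniform
model over the not-yet-excluded alphabet. The accumulated `-log2` of every
predictive probability — escapes included — is the code length in bits. No
bitstream is emitted: the ideal length is the quantity compression-distance
theory is stated in, and it avoids byte-alignment and container artifacts.
The engine is deterministic and implemented in C++ (an array trie with
rolling per-order suffix pointers, `O(maxOrder)` per symbol).

Two empirical properties of fixed-order PPM shape everything downstream
and are asserted in the test suite:

* **Learning redundancy.** On 1000 i.i.d. fair bits at order 8 the code
  length is ≈ 1.6 bits/symbol, not 1.0: order-8 binary contexts are seen
  only a handful of times in a 1000-symbol window, so escape costs
  dominate. The entropy bound is approached only asymptotically. The
  all-zeros sequence has a closed form (9 + log2(992) ≈ 18.95 bits at
  order 8) used as a hand-checked oracle.
* **The deterministic-context ceiling.** A context observed once predicts
  its continuation with probability 1/2 under escape method C, so coding a
  verbatim repeat of an incompressible sequence still costs ~1 bit/symbol.
  Consequently `ncs(x, x)` approaches 1 only for *structured*
  (compressible) trains — a periodic train scores ≈ 0.92 — while for
  i.i.d. trains self-similarity saturates near 0.33. NCS values should
  therefore be read relative to a null distribution (or thresholded by
  percentile), not as an absolute scale.

`maxOrder` defaults to half the window length capped at 16
(`defaultMaxOrder`). The half-window rule ties model memory to the
analysis window; the cap keeps the context trie tractable for second-long
windows and is overridable (`cap = Inf`).

## 2. NCS, its asymmetry, and significance

`ncs(x, y)` implements
`1 − [C(x⊕y) − min(C(x), C(y))] / max(C(x), C(y))`, the
similarity-oriented reversal of the normalized compression distance, with
the concatenation order `x` then `y` taken literally; the mild asymmetry
carries no causal meaning and graphs are built from the elementwise
maximum of the two directions. Raw values can leave [0, 1] through
compressor overhead and are clipped.

Because PPM is *position-blind* — only local substring content matters,
never absolute time — NCS detects a shared pattern at any lag inside the
window (the drifting-pattern benchmark exercises exactly this), but it
does **not** measure synchrony: two trains that co-fire without sharing
local motifs score no higher than rate-matched independents. This is the
central interpretive caveat for NCS-based functional connectivity.

`ncsSignificance()` builds the null by shuffling the spike positions of
the second train within the window (spike count preserved) and returns the
add-one permutation p-value, so p is uniform on its lattice under
independence (tested by Kolmogorov–Smirnov over seeded runs) and the
false-positive rate at α = 0.05 is calibrated (0.05 ± 0.02 over 100
pairs). Trains with no spikes cannot carry evidence: the test returns
p = 1, and consistently `ncsMatrix()` assigns weight 0 to any pair in
which either train is empty — without this rule, silent units would form
spurious near-cliques (identical all-zero windows are maximally similar)
that dominate percentile thresholding.

## 3. Phase synchrony

`instantaneousPhase()` forms the analytic signal via the FFT construction
(zero negative frequencies, double positive ones) after mean subtraction;
`phaseSynchrony()` is the modulus of the mean phase-difference phasor with
5 % of samples trimmed at each end against analytic-signal edge
transients. Band-pass filtering before phase extraction is deliberately
the caller's responsibility (`bandpassFilter()` provides a zero-phase
Butterworth helper); broadband versus band-limited input is a scientific
choice the package does not impose. The phase-coupled generator
(`genCoupledPair`) injects a slowly varying Gaussian phase jitter whose
sample SD is set to `sqrt(-2 log target)`, the wrapped-normal resultant,
so the target locking is recovered within ±0.05 across the 0.1–0.9 grid.

## 4. Graphs: thresholding and admissibility

`binarize()` supports a percentile threshold on the off-diagonal weight
distribution (default 90, i.e. the top 10 % of unordered pairs become
edges, ties broken deterministically by weight then indices) and an
absolute threshold in [0, 1] (strict inequality). Raising either threshold
never adds an edge. `admissible()` first drops graphs in which fewer than
99 % of nodes have degree ≥ 1 ("connected" can be switched to
giant-component membership), then removes node/edge/density outliers
outside the 5th–95th percentile band of the remaining list — the exact
band is not recoverable from the source analysis, so it is a configurable
default.

## 5. Network statistics and null models

`C`, `L`, betweenness and fast-greedy modularity go through igraph;
brute-force enumerative oracles (plain-R BFS, exhaustive shortest-path
enumeration, the direct modularity formula) arbitrate them on every seeded
graph up to 20 nodes. Unreachable pairs are excluded from `L` (with a
count attached) rather than imputed: admissibility makes disconnection
rare and no principled imputation exists. Degree-preserving randomization
uses connected double-edge swaps; latticization accepts a swap only when
neither rewired edge gets longer in ring distance and at least one gets
strictly shorter (a Pareto rule). A total-cost rule — accept when the
summed ring distance does not increase — was tried first and *lowers*
clustering: cost-neutral swaps random-walk the edge set apart, and a
net-improving swap can lengthen an already-short edge; the Pareto rule
yields `C_latt ≥ C` on 20/20 seeded Watts–Strogatz graphs.
`smallWorldness()` averages the null statistics over `nNull` realizations
(default 10; the study uses 5) and is bit-reproducible for a fixed seed.
On canonical graphs the indices behave as expected: WS(1000, k = 10,
p = 0.05) gives S ≈ 42 with |ω| < 0.35, a density-matched Erdős–Rényi
graph gives S ≈ 1.0 with ω ≈ 0.6, and a ring lattice gives ω ≈ −0.8.

## 6. The cell-assembly simulator

The generative model asserts, rather than derives, functional structure:
`round(lambda * nNodes)` Watts–Strogatz assemblies (sizes uniform on
50–150 at the default 10,000-node pool — microcolumn scale; ring
neighbors k = 5, rewiring p = 0.05) are embedded over a common node pool
and may share members. Time is tiled into 10-step (1 ms/step) execution
windows; per window at most 2 assemblies are drawn and each fires with
probability 0.99. Three choices deserve explanation:

* **Offsets are scaled betweenness values, not ranks.** Members fire at
  `floor(betweenness / max * windowLen)` steps after the assembly onset,
  so peripheral members lead and the *shape* of the centrality
  distribution survives: heavy-tailed for WS assemblies, constant (fully
  synchronous) for ring lattices, narrow for random graphs. Dense-rank
  compression was tried first and erases precisely this difference
  between the structural variants.
* **Random onset phase.** Each activation lands at a uniform random phase
  inside its window; on a rigid global grid every unit pair becomes a
  lag-shifted copy of every other and pairwise similarity degenerates.
* **Propagation writes to the neighbor.** Each firing member also
  triggers its assembly neighbors at the summed offsets plus a uniform
  1–3 ms delay; spike times are clamped to the raster bounds.

Under the ≤ 2-concurrent-assemblies contract the population firing rate is
*flat* in `lambda` once at least two assemblies exist — exactly two are
drawn per window regardless of how many are available — so `lambda`
modulates the diversity of activation patterns, not the rate.
`nullVariant()` produces the ring-lattice (p = 0) and random (p = 1)
controls with all other parameters untouched.

## 7. The simulation study and what it shows

`runSimulationStudy()` runs build → simulate → sample 100 units → NCS
pipeline for every density on the grid {0.01, 0.03, 0.05, 0.075, 0.1,
0.25, 0.5} and every structural variant, at the study sizes: a 2000-node
pool, 2 s of activity, 100-ms analysis windows (10 per run), percentile
threshold 90, 5 nulls per graph, 3 seeds per cell — sizes chosen so the
full grid completes in minutes on one CPU. The connectivity screen is
disabled for the study (`minConnected = 0`): the model emits structurally
silent units inside short windows by design, and screening at 99 % would
discard every window.

The study harness is fully tested for its mechanical contracts (grid
coverage, variant configuration, bit-reproducibility). Its scientific
outcome at these problem sizes, computed by the acceptance suite, is
sobering and worth stating plainly: the sampled-unit functional graphs
yield S ≈ 0.9–1.1 with ω ≈ 0 for *all three* variants across the whole
density grid — no unimodal density dependence and no separation between
the small-world assemblies and their lattice/random controls. The root
causes are the two structural facts documented above: NCS's position
blindness (single co-activations of co-assembly members carry no local
motif overlap) and the concurrency cap (activation statistics are
density-invariant). Separating the variants through this pipeline appears
to require either far larger recordings, a synchrony-sensitive similarity,
or a different activation regime. The validation suite states the
variant-contrast expectation as written and reports its failure at these
problem sizes rather than weakening the assertion.

## 8. Other defaults and degenerate inputs

* Drift benchmark: background noise 0.01 spikes/bin outside the pattern
  span (keeping the embedded pattern intact, so spike counts decompose
  into pattern + noise); pattern bits Bernoulli(0.5). Under these
  conditions the Pearson-significant band spans drifts ≈ 21–27 (median
  over 20 seeds), slightly wider than but overlapping the 23–27 reference
  band; NCS is significant at all 47 drifts.
* Cross-correlation arm: the maximum lagged cross-correlation is tested
  against the same shuffle-surrogate null as NCS.
* Firing-rate unit exclusion defaults to 0.5–100 Hz (`filterUnitsByRate`).
* Responsiveness: evoked rate strictly above basal mean + 5 SD.
* Empty rasters, single-unit windows, constant LFP signals, oversampling
  requests and alphabet violations all raise explicit errors; star graphs
  (no possible degree-preserving swap) return the input with a warning.
* Multiple-testing correction is deliberately not applied inside report
  tables; rows carry raw test outcomes plus full provenance (window,
  threshold, seed).

## 9. What the synthetic data do not emulate

The generators reproduce the statistical structure the analysis assumes —
embedded patterns at controlled lags, calibrated phase coupling, assembly
co-activation — but not refractory periods, rate nonstationarity,
oscillatory spike-field coupling, electrode crosstalk, or spike-sorting
errors. Green tests therefore certify the *pipeline's* correctness and
calibration, not the biological validity of NCS connectivity on any
particular recording.
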