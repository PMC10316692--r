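---
title: "Mapping raw nanopore signal by subsequence dynamic time warping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping raw nanopore signal by subsequence dynamic time warping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squigglemap)
```

## The problem

Nanopore sequencers expose the raw ionic-current trace (the "squiggle") of
a molecule while it is still being sequenced, and allow the molecule to be
ejected from the pore if real-time analysis decides it is not of interest
(selective sequencing, or Read Until). Making that decision by basecalling
and conventional alignment is expensive; `squigglemap` instead maps the
first fraction of a second of raw signal directly against a
signal-space rendering of the reference, with no basecalling at all.

The pipeline has three stages:

1. **Reference synthesis.** A k-mer pore model assigns an expected current
   level to every k-length word. Sliding a k-base window over the
   reference (and over its reverse complement — DNA is double-stranded)
   yields one synthetic signal of length $L - k + 1$ per strand. Each
   strand is z-score normalized independently and quantized.
2. **Query preparation.** The raw samples of a read are segmented into
   *events* (spans of approximately constant current, nominally one k-mer
   dwelling in the pore), the adapter prefix is trimmed, and a
   fixed-length window of 250 event means is z-normalized and quantized
   with the same scaling factor as the reference.
3. **Alignment.** Subsequence dynamic time warping (sDTW) locally aligns
   the 250-event query anywhere inside each strand's reference signal; the
   better strand, the end position, a mapping quality, and an
   accept/reject decision follow.

## The sDTW model

For a query $x_{1..M}$ and reference $y_{1..N}$ ($1 \le M \le N$), the
accumulated cost is

$$\gamma(i,j) = |x_i - y_j| + \min\{\gamma(i-1,j),\ \gamma(i-1,j-1),\
\gamma(i,j-1)\}$$

with boundary conditions $\gamma(i,0) = \infty$ and $\gamma(0,j) = 0$. The
zero top boundary lets the alignment start free of charge at any reference
position; the minimum of the last row marks where the best local alignment
*ends*, which is all a selective-sequencing decision needs. Manhattan
distance is used throughout: it is the cheapest distance to evaluate in
narrow integer arithmetic and loses nothing at this SNR.

Three engines evaluate the same recurrence:

* **`oracle`** — the full $M \times N$ matrix in double precision, with
  backtracking for the warp path and start position. $O(MN)$ memory;
  used for validation, small problems, and whenever the path itself is
  wanted.
* **`linear`** — double precision with a single cost array of $M + 1$
  entries (outer loop over the reference, inner over the query), tracking
  the running last-row minimum. Same values as the oracle, exactly: both
  engines are constrained to the same floating-point operation order, so
  their equality is tested as identity, not within a tolerance.
* **`wavefront`** — a bit-accurate software model of a chain of $M$
  fixed-point processing elements evaluating one oblique anti-diagonal per
  step. Neighbor values travel through two register arrays of size $M$
  (the previous and second-previous cost of each element), the reference
  streams through the chain, and the full search finishes in exactly
  $M + N - 1$ steps. All additions, subtractions and absolute values are
  performed in the configured word width under the configured overflow
  policy, so the engine reproduces — bit for bit — what such an
  accumulator pipeline computes, including its failure modes.

Tie-breaking is deterministic everywhere: the last-row argmin takes the
smallest reference index, and backtracking prefers diagonal, then left,
then up. $\gamma(0,0)$ is treated as $0$, consistent with the free-start
row.

## Fixed-point representation

The quantizer multiplies z-normalized signal by an integer scaling factor
(default $32 = 2^5$), rounds half away from zero, and clamps into the
representable range of the word width (default 16 bits). The scaling
factor trades resolution against headroom: too small and distinct levels
collapse onto the same integer; too large and the *accumulated* distance
along an alignment column exceeds $2^{15}-1$ and wraps negative. Wrapped
cells then masquerade as excellent scores and the reported end position
becomes garbage. `match_fraction_by_scale()` exhibits both regimes:
agreement with the float engine rises monotonically over scales
2–32 and collapses under wraparound at scale 256 on a 30 kb reference.

Two overflow policies are provided because hardware accumulators may
implement either. `wraparound` (two's-complement, the default) models a
plain adder and reproduces the collapse; `saturate` pins at the range
limits, which keeps the "infinity" column boundary sticky. The boundary
value itself is the maximum representable integer; it only ever enters the
recurrence through `min()`, so it never propagates unless a whole
neighborhood is at infinity. The wavefront engine counts every
renormalization that changed a value and reports it as `n_overflow`.

## Event detection

Boundaries between events are found with two straddling-window statistics
computed at every sample: a short-window (4 sample) Welch *t* that
localizes level changes sharply, and a long-window (8 sample) mean
difference scaled by the *short*-window noise variance, whose stringent
threshold (9.0) confirms them. A sample is a boundary when the short
statistic is a local maximum above its threshold (1.4) with prominence at
least 0.2 *and* the long statistic exceeds its threshold.

Two design points deserve explanation:

* The long statistic pools its variance from the short, boundary-adjacent
  windows rather than over its own window. Event dwells can be as short as
  4 samples, so an 8-sample window frequently spans a neighboring level
  step; a variance taken over that window is then dominated by the step,
  not by noise, and masks true boundaries (in development this variant of
  the detector missed roughly 60 % of boundaries on realistic dwell
  distributions). Pooling from the inner windows keeps the statistic a
  noise-scaled step detector under short dwells.
* Requiring *both* statistics, rather than either, is what suppresses
  false boundaries: a lone short-window threshold of 1.4 is exceeded by
  pure noise far too often, while the long statistic at threshold 9 has an
  essentially zero false-positive rate and only misses steps smaller than
  about $9\,\sigma\sqrt{2/w_\ell}$ — which at these noise levels are steps
  between nearly identical current levels, whose merger the aligner
  absorbs anyway.

On noiseless piecewise-constant signal the detector recovers boundaries
exactly (the variance floor makes the statistics effectively infinite only
at the true transition), so event means equal true levels exactly — with
one physical caveat: consecutive identical k-mers emit identical levels
and are indistinguishable from one long event. Tests therefore compare
against the *collapsed* truth.

## Adapter trimming and query assembly

Reads begin with 50–300 events of library adapter before genomic signal.
A fixed trim of 50 events is the conventional default and is what
`prepare_query()` and `trim_and_select()` do. For the end-to-end pipeline,
however, a fixed 50-event trim is demonstrably insufficient under the very
adapter-length distribution it is meant to handle: with adapters uniform
over 50–300 events, up to 80 % of a 250-event query can be adapter, and in
development end-position recovery under a fixed trim measured 67 %, with
failures concentrated exactly in the adapter-dominated reads.

`map_read()` (and hence `map_batch()`) therefore treats the trim as a
small model-selection problem: it assembles a candidate query for each
feasible trim in $\{50, 100, \ldots, 300\}$ — the plausible adapter
range — maps each candidate, and keeps the one with the lowest per-event
mean distance, ties going to the smallest trim. A candidate whose trim
roughly matches the true adapter length is mostly genomic and aligns with
a much lower per-event score than an adapter-contaminated one, so the
selection is sharp. The per-event score was preferred over mapping quality
as the selection criterion because it is continuous (MAPQ saturates at
60). Passing a single value in `trims` restores the fixed-trim behaviour.

Normalization happens once per candidate query, over the selected 250
event means only. This mirrors reference preparation but means a query
containing adapter events is normalized with a slightly inflated spread —
a real property of this kind of pipeline, not an artifact, and one reason
adapter-dominated queries score poorly.

## Mapping quality and selection

Both strands are searched; the lower best score wins, with the forward
strand taking exact ties. The runner-up for the quality computation is the
better of (a) the losing strand's best score and (b) the winning strand's
best score outside an exclusion window of $2M$ positions around the end
(one query length of guard on each side, so the runner-up is never the
same alignment shifted by noise). The quality itself is this package's
own formula, isolated in `compute_mapq()`:
$\mathrm{mapq} = \min(60, \lfloor 60\,(s_2 - s_1)/s_2 \rfloor)$, with 60
when no runner-up exists or $s_1 = 0$, and 0 when $s_2 \le s_1$.

Event coordinates convert to 1-based base coordinates as follows: forward
signal index $e$ is the window over bases $[e+1, e+k]$, so the alignment
end is base $e + k$ and the nominal span is one base per query event;
reverse-strand indices map through $L - e - k + 1$ with the span extended
toward larger forward coordinates. The linear and wavefront engines have
no true start position, so the span is nominal — validated against
planted truths, it always contains the planting locus.

The default selection policy accepts a read iff it mapped with
$\mathrm{mapq} \ge 20$ and its base interval overlaps a BED target region
by at least one base (any location if no regions are given); an optional
per-event score ceiling (`score_max`, in normalized units per event, hence
comparable across query sizes and scales) can be added.

## The synthetic testbed

`generate_pore_model()` draws 4^k levels from an evenly spaced grid over
60–140 model units with ±(spacing/4) jitter, shuffled over the k-mers:
deterministic per seed, complete, and with a guaranteed minimum gap
between any two levels. `simulate_read()` picks a strand and a uniform
start, takes the model levels along the sequence as event truth, prepends
an adapter segment whose levels alternate between bands just outside the
central model range (so adapter steps are detectable and moderately,
realistically, out-of-band), draws per-event dwells (geometric, minimum 4
samples, mean 10), and adds Gaussian level noise (default σ = 0.5 model
units; recovery experiments also use 0.3). Truth records strand,
coordinates, adapter length, per-event levels and dwells.

What the simulator does *not* emulate: pA-scale calibration, homopolymer
dwell inflation, current drift within a read, stall and back-step
artifacts, or basecaller-grade noise structure. Passing tests on this
testbed therefore demonstrate the correctness and numerical behaviour of
the pipeline, not flowcell-grade accuracy claims.

The truth-based accuracy metric is deliberately sample-anchored: the
expected end of a query is the reference window that was in the pore when
the *final sample* of the last selected event was recorded
(`expected_end_event()`). Counting events instead would make the
expectation drift with every detector split or merge and measure the
wrong thing.

## Validation problem sizes

The shipped test suite validates, among other things: exact equality of
the linear engine with the full-matrix oracle over 500 random instances
($M \le 64$, $N \le 512$); bit-identity of the wavefront engine with a
sequential fixed-point evaluation (and with an independently written
modular-arithmetic oracle) under both overflow policies; the
accuracy-versus-scale sweep on 200 simulated reads against a 30 kb
reference over scales $\{2,4,8,16,32,256\}$; and end-position recovery
within ±5 bases for 5 × 40 reads at σ = 0.3 against the same reference
size. These sizes were chosen as the smallest that exercise every regime
(including genuine 16-bit overflow, which needs accumulated costs past
$2^{15}$) while keeping the suite comfortably interactive.

## Known limitations

* References are indexed per FASTA record and held densely in memory; the
  intended regime is kilobase-to-low-megabase targets, not whole large
  genomes.
* Binary BLOW5 is not parsed (no reader library available to this
  package); ASCII SLOW5 and a plain TSV format are.
* The linear and wavefront engines report end positions only; warp paths
  require the oracle engine and its $O(MN)$ memory.
* R10.4 and RNA chemistries, pore-model training, and live sequencer
  integration are out of scope.
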