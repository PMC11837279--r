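---
title: "Methods: interval rule mining with a parallel sunflower optimiser"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interval rule mining with a parallel sunflower optimiser}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Electronic-nose instruments report a vector of raw sensor channels per
measurement — metal-oxide gas sensors (MQ-series and similar) with
baselines in the hundreds, next to temperature and humidity channels in
the tens. In applications such as classifying bovine reproductive state
from intrauterine gas composition, practitioners need classifiers whose
decisions can be read and audited: *which* channels matter, and in
*which* ranges. `sunrule` mines per-class **interval rules** of the form

```
if((lo1 ≤ ch1 ≤ hi1) and (lo2 ≤ ch2 ≤ hi2) and ...) Then CLASS
```

with inclusive bounds in raw sensor units, scoring each candidate rule
by its confusion-matrix accuracy on a training partition. Each rule is
evaluated independently — there are no rule lists, voting schemes or
overlap resolution; this mirrors how the motivating instrument's
candidate tables are reported and keeps every rule individually
interpretable.

## Rule semantics and fitness

For a rule with consequent class $S$ and conditions
$\{(j, y^a_j, y^h_j)\}$, a row $D_k$ *fires* the antecedent iff
$y^a_j \le D_{kj} \le y^h_j$ for every condition (bounds inclusive, so a
value exactly on a bound fires). Treating the rule as a one-vs-rest
binary classifier:

| antecedent | label = consequent | count |
|------------|--------------------|-------|
| fires      | yes                | TP    |
| fires      | no                 | FP    |
| no fire    | yes                | FN    |
| no fire    | no                 | TN    |

and the fitness is the classification accuracy
$\mathrm{Acc} = (TP + TN)/(TP + TN + FP + FN)$. The counts always sum to
the number of rows. This is the only confusion assignment under which
the accuracy formula measures classification accuracy; the package
treats it as canonical. A consequence worth knowing: a rule that never
fires on a table containing none of its consequent class scores
accuracy 1 (all rows are true negatives), and a rule spanning the full
observed range of every channel scores exactly the consequent's relative
frequency (the ZeroR baseline).

## Normalization

Search runs in min–max normalized coordinates: each channel is mapped
affinely from its observed training extrema onto a target interval
$[N_b, N_h]$ (default $[0,1]$). The mapping is fitted **on the training
partition only**; held-out rows may normalize outside the interval and
are deliberately not clipped, so raw-unit rule semantics are preserved
exactly. Because the map is strictly increasing on non-constant
channels, evaluating a rule in normalized coordinates is equivalent to
evaluating its raw-unit decoding; the round trip
`invert(apply(x)) = x` holds to 1e-9 relative tolerance. Constant
channels map to $N_b$, invert to their constant value, and are excluded
from rule search (an interval on a constant channel carries no
information).

## The optimiser

The sunflower optimisation algorithm (SFOA) is a population
metaheuristic over a bounded box. The incumbent best candidate is the
*sun* $C^*$; every other candidate $C_i$ orients toward it along the
unit vector $R_i = (C^* - C_i)/\lVert C^* - C_i \rVert$ and moves to
$C_{i+1} = C_i + s_i R_i$. Steps are capped by
$d_{max} = (C_{max} - C_{min}) / (2\,S_{pop})$ so that large jumps do
not skip over structure; with the published population of 30 on a unit
interval, $d_{max} = 1/60$. Per iteration, the `ceiling(p·N)` candidates
nearest the sun each produce one offspring uniformly on the segment to
their next-ranked neighbour (*pollination*, replacing the same number of
worst candidates), and the `floor(O·N)` worst candidates are replaced by
fresh uniform draws (*elimination*). The sun itself is never moved,
pollinated over, or eliminated, so the best-so-far fitness is
non-decreasing (elitism).

**Step-magnitude law.** The source description of the step magnitude is
typographically corrupted; its recoverable form is
$s_i = \varphi \, P_i \lVert X_i + X_{i-1} \rVert$ — the norm of the
*sum* of consecutive positions, weighted by an inertia coefficient
$\varphi$ and a pollination-probability weight $P_i$. The package takes
this form literally, with $P_i \equiv 1$ (the model assumes each
sunflower performs exactly one pollination, i.e. pollination is
certain), and truncates the resulting displacement per dimension at
$d_{max}$. Two properties motivated keeping the sum (rather than
reading it as a distance): the sum-norm stays bounded away from zero,
so steps saturate the $d_{max}$ cap while the population is spread out
and candidates keep probing a $d_{max}$-scale neighbourhood of the sun
instead of collapsing onto it; and on the package's planted-rule
recovery benchmark this reading recovered the planted rule in 8/10
seeds versus 6/10 for the distance reading, with the correct active
attribute set in all ten. The distance variant remains available
through the `step_law` hook. $\varphi$ defaults to 0.05 (no published
value exists); since steps usually saturate the cap, results are
insensitive to $\varphi$ over a wide range.

**Tie-breaks and edges.** Argmax ties resolve to the lowest index
everywhere; box violations clamp (no reflection); an individual sitting
exactly on the sun holds its position. Rate-to-count conversions use
`ceiling` for pollination (so the published 2.5% of 30 still yields one
offspring) and `floor` for elimination (20% of 30 gives six
replacements).

## Encoding rules as continuous vectors

A candidate rule for class $S$ over $d$ channels is a $3d$-vector: an
activation block $y^t \in [0,1]^d$ and two bound blocks $y^a, y^h$ in
normalized units. Attribute $j$ joins the decoded rule iff
$y^t_j > \delta$ — strictly, so a score exactly at the threshold stays
inactive; $\delta$ defaults to 0.5, the neutral midpoint of the
activation range (the source only calls it "predefined"). Active bounds
decode with a swap when $y^a_j > y^h_j$, guaranteeing valid intervals,
and map back to raw units for reporting. A solution with no active
attribute scores fitness 0.

Per class, the bound blocks are confined to the **class subspace**: the
per-channel extrema (normalized) of the training rows bearing that
class. This keeps candidate intervals inside the region where the class
is observed. Fitness is still computed on the *full* training table —
with class-only evaluation every covering rule would trivially score 1,
since no row could be a false positive or true negative. Inside the
miner, the step cap is taken from the normalized data interval
($1/60$ at the published settings) rather than from each subspace
dimension's narrower width, matching the cap formula's definition on
the data bounds.

The "parallel" scheme runs two (configurable) independent optimiser
islands per class with distinct derived seeds and no migration; the
union of their final populations is decoded, deduplicated by exact
condition equality after rounding bounds to six significant digits, and
ranked by training accuracy, then by fewer conditions, then by
discovery order. The top `rules_kept` (default 4, the size of the
published candidate tables) are reported and scored on the held-out
split.

## Splits and repeated experiments

The train/test split is stratified 80/20 with an explicit seed
(stratification is the package's choice; the source states only the
ratio). Repeated experiments re-split and re-seed each run and report
Best / Worst / Mean / Median / Std of the per-class top-rule held-out
accuracy. The number of independent experiments defaults to 10 (the
source's prose) and is configurable to 5 (its settings table); the
discrepancy is inherent to the source.

## The synthetic benchmark

No real dataset is deposited, so every claim the test suite makes is
grounded in a planted-rule generator:

- **Marginals.** Each channel is uniform on $[0,1]$ in generator
  coordinates, then scaled affinely to raw units. Uniform marginals make
  interval coverage a closed-form product measure, so acceptance
  arithmetic is exact when channels are independent.
- **Correlation.** Channels share a latent factor with weight 0.3
  (sensor channels co-vary in practice); the mixture is pushed back to
  exact uniform marginals through its own CDF (a probability integral
  transform), preserving rank correlation. With correlation on, joint
  coverage is no longer exactly the product measure — tests that rely
  on exact coverage set the weight to 0.
- **Scales.** Default channel scales emulate the instrument: gas-like
  channels with spreads of hundreds of raw units, every sixth channel
  temperature-like with a spread in the tens, so families differ by
  more than 10×.
- **Labels.** A row inside every planted interval is positive;
  non-covered rows leak to positive with probability `base_rate`
  (default 0.05); labels then flip i.i.d. with probability `label_noise`
  (default 0.1). Noiseless benchmarks set both to zero. A target class
  ratio (e.g. the motivating datasets' 364:125 and 283:111 imbalances)
  can be requested and is solved into `base_rate`; ratios below the
  planted coverage are rejected as infeasible.
- **Null control.** The same features with labels drawn independently
  at a fixed positive fraction (default 0.3, making the negative class
  a ~70% majority like the motivating data); no rule can beat the
  majority frequency by more than sampling error.

What a green suite establishes: the engine scores rules exactly (oracle
equivalence), the optimiser respects its contracts (elitism, box
containment, determinism), the miner recovers a known planted rule at
the published settings and does *not* hallucinate structure in null
data. What it does not establish: performance on real sensor drift,
cross-sensitivity, time-series structure, or any physiological claim —
the generator models none of these.

## Numerical choices and degenerate inputs

- Rule text rendering uses the shortest decimal that round-trips the
  double, so `parse_rule(format_rule(r))` is exact.
- Decoded bounds that land exactly on a data value can, after the
  normalized-to-raw inversion, differ from it by one ulp; reported
  train accuracies are therefore always recomputed through the raw-unit
  rule engine rather than taken from the internal normalized fitness.
- Degenerate class subspaces (single-row classes, constant-within-class
  channels) get a sliver of width (1e-9, relative where possible) so
  the optimiser box stays valid.
- Empty tables produce all-zero confusion counts; accuracy on all-zero
  counts is an error rather than a silent NaN.
- Derived seeds are kept below $2^{31}$.

## Known limitations

- The miner is one-vs-rest per class; more than two classes work but
  rules never interact.
- Accuracy as the sole fitness is insensitive to class imbalance within
  a rule's coverage; on heavily imbalanced tables the ZeroR-equivalent
  rule is a strong local optimum (visible in the null control).
- The optimiser's step law interpretation is a reconstruction from a
  corrupted source; the `step_law` hook exists precisely so alternative
  readings can be compared.
- External baseline learners (rule inducers, SVMs, decision trees) are
  not reimplemented; the benchmark command degrades to the built-in
  majority-class baseline when no external library is available.
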