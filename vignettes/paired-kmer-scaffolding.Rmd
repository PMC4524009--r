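---
title: "Paired k-mer scaffolding: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired k-mer scaffolding: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scaffolding model

`scafflink` orders and orients the contigs of a draft assembly using
long, error-containing sequences, without aligning them. The premise is a
statistical property of nanopore-like data: although overall identity sits
near 77 %, correct base calls come in bursts, with error-free stretches of
13–15 bp on average. A 15-mer drawn from such a stretch is simultaneously
error-free and (in genomes up to tens of megabases) specific enough to
place uniquely. Two k-mers taken from one read at a known spacing
therefore behave like a mate pair of known insert size, and k-mer pairs
that land on two different contigs are evidence for the relative order,
orientation and distance of those contigs.

The pipeline is: index the assembly's k-mers (both strands) in a Bloom
filter; slide over each read extracting pairs whose outer span is exactly
`d` (first k-mer starting at window offset `w`, second ending at `w + d`);
keep pairs whose two members hit the filter; place kept k-mers on the
contigs; convert uniquely-placed, cross-contig pairs into oriented links
with per-pair gap estimates; and lay out scaffolds greedily under support
and ambiguity guards.

### The gap formula and the pair-span convention

For a pair whose first k-mer starts at 0-based `p1` on contig 1 (length
`L1`, coordinates in the orientation the link uses) and whose second
k-mer starts at `p2` on contig 2:

```
D   = (L1 - p1) + (p2 + k)      # calculated distance (footprint)
gap = d - D                     # positive gap, negative overlap
```

This arithmetic is exact — with error-free reads and uniquely placed
k-mers every estimate equals the true inter-contig distance — *provided*
`d` is the outer span of the pair (5' end of the first k-mer to 3' end of
the second). Had pairs been extracted at a 5'-to-5' spacing of `d`, every
estimate would be biased low by exactly `k`. We therefore fix the
extraction so that the second k-mer ends `d` bases after the first one
starts; two abutting contigs then yield `D = d` exactly. The package
treats this as the definition of `d` everywhere (extraction, tolerance
test, gap estimation), and the property-based test suite asserts the
zero-bias behaviour.

### Distance tolerance

A pair observation is accepted only when `|D - d| < e * d`, with
`e = 0.1` by default — at `d = 4000` the accepted band is 4000 ± 400 bp.
The bound is strict: a calculated distance of exactly 4,400 bp at
`d = 4000` (indicating a contig overlap of 400 bp or more) is rejected.
Strictness at the boundary is a deliberate choice; an inclusive bound
would differ only on a measure-zero set of integer footprints, and the
exclusive form matches the reading that 4,400 bp lies "beyond" the
allowed distance.

### Link accounting

Each *observation* of a k-mer pair counts as one link: a pair seen seven
times across reads contributes seven links to its contig pair. The
alternative (counting distinct pairs once) discards read-depth evidence;
frequency weighting is what lets a minimum-link threshold act as a depth
filter. Rejected observations are tallied by reason — `same_contig`,
`non_unique` (either k-mer placed more than once across all contigs and
both strands), `out_of_tolerance`, and `orientation_conflict`. The last
deserves a note: for a pair landing on two *different* contigs, all four
strand combinations map to a valid oriented link, so no cross-contig
orientation conflict exists; the category records the same-contig
sub-case where the two k-mers land on opposite strands (an
inverted-repeat signature), which is pathological rather than merely
uninformative. The accounting closes exactly:
`accepted + rejected = observations with both k-mers placed`, and the
test suite asserts this identity on noisy data.

The per-link gap estimate is the arithmetic mean of per-observation
estimates, rounded half away from zero so gaps and overlaps are treated
symmetrically. Link direction is canonicalised to the contig of smaller
input rank; a reverse observation accumulates onto the canonical
direction with both orientations flipped, which makes the link set
invariant under reverse-complementing the entire read set (also tested).

### Greedy layout

Contigs seed scaffolds in descending length order (ties: input order),
the convention of this tool family's lineage, and extension proceeds
rightward then leftward from each seed. At an open extremity the
candidate neighbours are compared by link count; the best is merged only
if it has at least `l = 5` links and the runner-up to best ratio is at
most `a = 0.3`. Two tie-breaking rules are stricter than they might be:
a tie for best merges nothing (consistent with the ambiguity guard's
purpose), and a chosen neighbour already consumed by any scaffold stops
the extension rather than re-queuing (no scaffold splicing; each
scaffold is finalized once). These guarantee termination — cycles in the
link graph cannot trap the walk — and make every contig appear in
exactly one scaffold, a property tested over randomly generated link
sets.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `k` | 15 | bases | k-mer length; must be long enough to be specific, short enough to fit inside correct stretches (13–15 bp on average in R7-like data) |
| `d` | 4000 | bases | pair outer span; ascending list for iterative runs |
| `t` | 2 | bases | window step; smaller = more pairs, more memory/time |
| `e` | 0.1 | fraction | distance tolerance half-width as a fraction of `d` |
| `l` | 5 | links | minimum supporting observations to merge |
| `a` | 0.3 | ratio | maximum alternate-to-primary link ratio |
| `p` | 0.001 | probability | Bloom filter false-positive rate |
| `z` | 500 | bases | minimum contig length admitted to scaffolding |

`l = 5` and `a = 0.3` are intentionally permissive defaults suited to
low-coverage long-read data; raise `l` at high depth. Note that `e*d`
must exceed the largest expected gap for junctions to be accepted at a
single `d`; iterating over increasing `d` (with `run_links()`) is the
intended way to capture a range of gap sizes.

## The Bloom filter

Sizing uses the exact expected element count
`n = 2 * sum(max(0, L_c - k + 1))` over contigs (both strands) and the
standard optimal formulas `m = ceil(-n ln p / ln² 2)` bits and
`h = round(m/n ln 2)` hash functions. An exact base count was preferred
over a file-size heuristic because it makes the false-positive contract
testable: the measured FPR on absent k-mers is asserted to stay within
twice the target across `p` from 1e-2 to 1e-4. Keys are hashed with two
64-bit FNV-1a variants combined by double hashing — deterministic, so a
filter built in a fixed order serialises to identical bytes every time.
K-mers are inserted as seen from both strands rather than canonicalised,
which keeps downstream orientation logic free of canonical-form
bookkeeping. The `-x` option swaps in an exact k-mer set behind the same
query contract; at `p = 1e-6` the two backends produce identical link
sets on the test fixtures, which is the package's oracle-equivalence
check. A reused filter (`-r`) is accepted only for the first iteration
of a multi-distance run — merge pads change the sequence content, so the
filter is rebuilt between iterations — and a reused filter whose `k`
differs from the run's is a hard error.

## The error model and simulator

Run lengths of the three error modes follow two-component mixtures:

* mismatch: `a_m · Poisson(λ_m) + (1 − a_m) · Geometric(p_m)`, zero-indexed
  (a stored value of 0 is a run of one mismatched base);
* insertion / deletion: `a_x · Weibull(λ_x, κ_x) + (1 − a_x) ·
  Geometric(p_x)`, one-indexed, modelling interarrival times of read
  failures.

Weibull draws are continuous, rounded to the nearest integer with a
minimum of 1. Along a read the simulator alternates correct stretches of
geometric length (mean 14 bases by default) with error events whose type
is multinomial (`type_weights`); mismatched bases are drawn from a 4×4
substitution profile with zero diagonal encoding the qualitative trend
that A and T are more stable than C and G and substitutions favour C and
G. The inter-event process is a modelling choice — the alternating
geometric stretch is consistent with the observed 13–15 bp correct
bursts, but the per-base initiation rates of each error mode are
exposed as free knobs rather than asserted.

The `preset_nanopore_r7()` parameter set is *calibrated, not
transcribed*: it was tuned once, analytically, so that simulated reads
reproduce the published summary statistics of R7-chemistry 2D data
(mean identity ≈ 77 % via `E[identity] = s̄ / (s̄ + E[error columns per
cycle])` with `s̄ = 14`, and correct stretches of ~14 bp), with mixture
components deliberately well separated so the model is identifiable from
samples. Simulated identity is computed from the event bookkeeping
itself (matches / alignment columns), so no aligner is involved.

What the generator does *not* emulate: real substitution rates estimated
from alignments, homopolymer-dependent error, read-length distributions,
chimeric reads, quality scores, and coverage biases. Passing tests on
this generator therefore demonstrate the correctness of the scaffolding
logic under the stated error statistics, not performance on any
particular real dataset.

## Fitting and the KS screen

`fit_mixture()` maximises the tally-weighted likelihood over transformed
parameters (logit for probabilities, log for positive scales) with
Nelder–Mead and eight random restarts; non-convergence of every restart
is an explicit error, never a silent fallback. The Weibull component is
discretised to match the integer rounding used in sampling
(`P(1) = F(1.5)`, `P(x) = F(x+0.5) − F(x−0.5)` for `x ≥ 2`). A fitted
mixture weight within 0.05 of either boundary is flagged `degenerate`,
the correct outcome when the data are explained by a single component.

Goodness of fit uses the plain Kolmogorov–Smirnov statistic against the
fitted discrete CDF, with the asymptotic Kolmogorov p-value and no
discreteness correction. Two conservatisms stack: the plain KS is
conservative on discrete data, and testing against *fitted* parameters
inflates p-values further. That is acceptable here because the screen's
role is to reject gross misspecification at the 0.05 threshold, not to
calibrate type-I error exactly; on correctly specified data the screen
passes essentially always. One implementation subtlety: because the
fitted CDF is a step function on the integer grid, the KS supremum is
evaluated on that grid (including unobserved support values), not with
the continuous-case left-limit comparison, which would spuriously
inflate the statistic by the height of the first jump.

## Degenerate inputs and edge rules

* K-mers containing non-ACGT symbols are never queried or placed; a
  window containing one is voided but the window count still advances.
* Reads shorter than `d` contribute no candidate pairs (and no error).
* Gap encodings: estimated gap `g ≥ 1` emits `g` literal `N`s; `g ≤ 0`
  (overlap *or* abutting) emits a single lowercase `n`, folding the
  zero case into the overlap flag to avoid zero-length separators.
* An assembly with no contig of length ≥ `k` fails fast ("no k-mers to
  index"), as does a `.scaffold` layout referencing unknown contigs.
* Palindromic even-`k` k-mers would double-count strand occurrences in
  multiplicity; the default `k = 15` (odd) avoids the issue, which is
  why odd `k` is recommended.

## Problem sizes used by the test suite

The synthetic study conditions are a 200 kbp genome cut into 20 contigs
with gaps of 100–500 bp (30 % of contigs stored reverse-complemented),
scaffolded at `d = 6000` so the tolerance band (600 bp) covers every
planted gap: 200 error-free 8 kbp reads for the exactness checks, and
1,000 nanopore-like reads (≈ 40× junction depth) for the noise-robustness
checks. Mixture recovery uses 10⁵ draws per error type and a 100-replicate
KS harness at 2×10⁴ draws each. These sizes were chosen as the smallest
instances that exercise every code path at realistic depth; all fixtures
are generated in code at run time.

## Known limitations

* The scaffolder never corrects bases or fills gaps; `N`-pad lengths are
  estimates from link means, not sequence.
* A single extraction pass uses one spacing `d`; capturing several gap
  scales requires the iterative protocol.
* Memory for the pair store grows with read volume and shrinking `t`;
  the Perl-era remedy (larger `t`, larger `d`) applies unchanged.
* The `.scaffold` layout grammar
  (`scaffoldN,totalSize,f<id>z<len>m<gap>_...`) is this package's own
  deterministic, parseable dialect; no byte-compatibility with any other
  tool's summary format is claimed.
* At `k = 15`, genomes much beyond tens of megabases will produce
  chance k-mer collisions; larger genomes need larger `k`.
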