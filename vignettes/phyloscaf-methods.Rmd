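---
title: "Phylogeny-weighted comparative contig scaffolding: model and methods"
author: "phyloscaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-weighted comparative contig scaffolding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Draft bacterial genomes come out of assembly as a bag of contigs. Closing the
gaps in the lab (primer walking) is far cheaper when the relative order and
orientation of the contigs is known in advance. When finished genomes of
related species are available, synteny lets us estimate that order: a contig
that maps just upstream of another contig on a close relative is probably its
neighbour in the draft genome too. Rearrangements between species corrupt
this signal, so evidence from a close relative should count for more than
evidence from a distant one — which is what the phylogenetic weighting in
this package formalizes.

`phyloscaf` takes a contig multi-FASTA, one or more reference genomes (each
possibly consisting of several records, e.g. chromosome plus plasmid), and a
Newick tree with branch lengths containing the contig species and every
reference species. It produces either an optimal linear contig order or, by
default, a conflict-tolerant *layout graph* that keeps alternative
adjacencies visible instead of forcing a single (possibly wrong) path.

## Matching contigs to references

Matches are local alignments between a contig substring and a reference
substring. The implementation is a seed-and-extend filter:

1. **Seeding.** All exact $q$-gram hits between contig and reference record
   ($q = 11$ by default) are found through a sorted integer-code index.
   Windows containing `N` never match.
2. **Chaining.** Seeds are chained greedily in reference order; a seed joins
   the chain with the nearest diagonal among those reachable within
   `max_chain_gap` (200 bases) and `diag_band` (20 bases of diagonal drift,
   absorbing small indels).
3. **Extension.** For well-supported chains (at least `full_ext_min_qhits`
   = 8 seeds covering at least 60% of the contig) the whole contig is
   projected through the chain and verified in one step; otherwise the chain
   core is extended greedily base by base along the diagonal, with an X-drop
   style stop once the error budget is exceeded by 25 errors.
4. **Verification.** Every candidate region is checked by banded unit-cost
   edit distance (substitutions and indels, implemented in C++). A match is
   reported only if it spans at least `min_length` = 64 bases on the
   reference and its error rate over the matched region is at most
   `max_error` = 8%. The seed count is reported as `qhits`, a match-quality
   surrogate.

The banded verification uses escalating bands: a narrow band (2% of the
region length) yields an upper bound on the distance that already decides
most cases; only rejections are re-checked at the full band implied by the
error threshold. A banded distance is exact whenever the optimal alignment
stays within the band, which holds for any region passing the 8% threshold
at the full band (the diagonal drift of such an alignment is bounded by its
edit budget). The speculative whole-contig extension uses the narrow band
only; when it fails, the greedy path recovers the partial region, so the
worst case of the shortcut is a slightly shorter reported match, never a
false one.

Matches found on the reverse strand are encoded with descending contig
coordinates ($s_b > s_e$); reference coordinates always ascend. BLAST
tabular (`-outfmt 6`) and `nucmer show-coords -rclT` tables can be imported
instead of the built-in matcher; their rows are normalized to the same
convention, and `qhits` is synthesized as
$\max(1, \mathrm{round}(\mathrm{identity} \times \mathrm{length}) - q + 1)$
because those tools do not report exact $q$-gram counts.

## The contig adjacency graph

Every contig $c_i$ contributes two *connector* vertices, $l_i$ and $r_i$,
joined by a zero-weight *intra* edge. All remaining connector pairs are
*adjacency* edges whose weight scores the hypothesis that the two contig
ends are neighbours in the genome.

A match $m = ((s_b, s_e), (t_b, t_e))$ of a contig of length $|c|$ implies a
placement of the whole contig on the reference, the *projection*. For a
forward match we use $\pi(m) = (t_b - s_b + 1,\; t_e + |c| - s_e)$, so that
a full-length match projects exactly onto its own interval under 1-based
inclusive coordinates; the variant without the $+1$ is available as the
`"raw"` convention. For a reverse match,
$\pi(m) = (t_b - (|c| - s_b),\; t_e + s_e - 1)$ by the same self-consistency
requirement. Projections may run off the ends of a record.

The *displacement* of two projections on the same record is
$d = \mathrm{start}(\text{later}) - \mathrm{end}(\text{earlier}) - 1$:
abutting projections give $d = 0$, overlapping ones a negative $d$.
Displacement across different genomes or records is undefined (`NA`) —
coordinates are not comparable there.

Two displacement regimes carry signal: insertions and deletions between the
species spread $d$ around 0, while *lost fragments* — genomic segments that
were simply never sequenced — shift $d$ towards the typical lost-fragment
size. Both are modelled with one Gaussian kernel each:

$$
s(d, \tau) \;=\; \frac{1}{\tau}\left[(1-\varphi)\,
  e^{-d^2 / \left(2\sigma_1(\tau)^2\right)} \;+\;
  \varphi\, e^{-(d-\mu)^2 / \left(2\sigma_2^2\right)}\right]
$$

with defaults $\sigma_1 = 10\,000$, $\mu = 2\,000$, $\sigma_2 = 1\,000$,
$\varphi = 0.1$. $\tau$ is the patristic (path-length) distance between the
contig species and the reference species, so distant references score less;
$\sigma_1(\tau) = \sigma_1 \tau / \tau_{\min}$ widens the indel tolerance
for distant references while the printed $\sigma_1$ applies to the closest
reference in the run ($\tau_{\min}$). Several choices here were genuinely
open and are worth recording:

* the Gaussians are **unnormalized kernels** (value 1 at their mean), not
  densities — as densities, the much narrower lost-fragment component would
  dominate near $d = \mu$ regardless of $\varphi$, contradicting the role of
  $\varphi$ as the mixture weight of the rarer event;
* $\varphi$ weights the **lost-fragment** component, the rarer of the two
  events, consistent with its small default;
* the per-reference weight of an edge is the **maximum** over all supporting
  match pairs, not their sum — sums would let repeat-induced multiplicity
  inflate one adjacency;
* the total edge weight is the **sum over references**, so concordant
  evidence from several genomes accumulates;
* the choice of patristic path length (rather than divergence time) for
  $\tau$ matches the requirement that every branch length in the input tree
  is used as given.

Which connectors a projection pair supports follows from facing: the earlier
projection contributes its rightward-facing connector ($r$ if forward, $l$
if reverse), the later one its leftward-facing connector. Pairs farther
apart than `d_cutoff` (200 kb) contribute essentially zero and are skipped.

Expert knowledge (mate pairs, fosmid ends, hybrid maps) enters by edge
overrides: *forbid* sets a weight to zero, *force* sets it to the current
maximum adjacency weight of the graph; forbids are applied before forces.

## Exact ordering

Maximizing the total adjacency weight of a linear signed contig order is a
travelling-salesman problem: flip weights into distances $m - w$ (with $m$
the maximum weight), drop the intra edges, and insert an intermediate node
between $l_i$ and $r_i$ with zero-distance edges, which forces any
Hamiltonian cycle to traverse each contig exactly once in one orientation.
`solve_exact()` searches signed contig sequences depth-first with branch and
bound; the admissible bound adds, for every contig not yet placed, the
maximum weight incident to either of its connectors. The first contig is
fixed (lexicographically smallest id, forward), cancelling rotation and
reflection symmetry, and children are explored in lexicographic order with
strict improvement — so among equally good tours the lexicographically
least signed permutation is returned, making the solver deterministic. The
optimal cycle is cut at its lowest-weight realized adjacency (preferring the
closing edge on ties) to present a linear worklist; bacterial chromosomes
are circular, so the cycle itself is the natural object. The solver refuses
instances above `exact_limit` (14 contigs) — beyond that the layout
heuristic is the intended tool.

## The layout graph

Real contig sets rarely admit a clean linear order: repeats close cycles and
rearrangements create conflicting adjacencies. The layout heuristic is a
relaxed multi-fragment greedy: process adjacency edges by decreasing weight
(ties broken lexicographically) and insert an edge iff its weight exceeds
`min_weight` *and* at least one endpoint carries no previously inserted
adjacency edge. Counting the structural intra edge, a connector inside a
grown path has degree two; the rule therefore lets **one** endpoint — never
both — exceed the usual tour degree, which keeps conflicting alternatives
visible, and no cycle check is performed, which lets repeats close cycles.
Insertion is judged against the layout at the moment of insertion, never
retroactively, and no cap is placed on how many conflict edges may pile onto
one connector (conflict stars are a feature of the display, not an error).
The default `min_weight` of 0 admits every strictly positive edge.

Annotated DOT export mirrors the display conventions used for such graphs:
one node per contig labelled with its reference-order rank (when known) and
its size in kb, gray fill below 3.5 kb, rectangular shape for contigs of
which at least 95% of the bases are covered twice or more by matches on at
least one reference genome, connector sides as edge head/tail labels, and
edge labels in $\log_{10}$ scale.

## Evaluation

Given a finished genome of the contig species, the *reference order* places
each contig on the region where it gains the most matches: match clusters
on one record are candidate placements, the winner maximizes summed `qhits`
(ties: summed match length, then leftmost), orientation follows the majority
of matched bases, and contigs without matches are excluded but reported.
Predicted connector-level adjacencies are scored against the consecutive
pairs of that order: a prediction is a true positive only if both the contig
pair and the connector sides agree — a right pair in the wrong relative
orientation counts as a false positive, flagged separately in the report.
Edges touching excluded contigs are dropped rather than counted as false
positives, matching an evaluation restricted to placeable contigs. With $P$
reference connections ($n-1$ linear, $n$ circular), sensitivity is
$\mathrm{TPR} = \mathrm{TP}/P$ and precision
$\mathrm{PPV} = \mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$, reported as
undefined when nothing was predicted. `n50()` implements the usual robust
size summary.

## The simulator

`simulate_assembly()` generates validation problems with full ground truth:
a random ancestral genome evolves independently down each branch of the
input tree; the sequence at the designated leaf is cut into contigs
separated by lost fragments; each contig is reverse-complemented with
probability 1/2. Events per branch are Poisson in rate × branch length:

| parameter | default | meaning |
|---|---|---|
| `sub_rate` | 0.02 | substitutions per base per unit branch length |
| `indel_rate` | 0.001 | indel events per base per unit branch length (geometric sizes, mean 3) |
| `inv_rate` | 0 | inversions per unit branch length (geometric sizes, mean 10 kb) |
| `transloc_rate` | 0 | translocations per unit branch length |
| `lost_fragment_mean`, `lost_fragment_sd` | 2000, 1000 | gap sizes, Normal truncated at 0 |
| `min_contig` | 1000 | smallest contig emitted |

The gap-size defaults deliberately equal the $\mu$ and $\sigma_2$ of the
scoring function: the simulator realizes the generative model the score
assumes. The substitution default (2% per unit branch) keeps simulated
species within the identity range where an 8% error threshold is a
meaningful filter; structural rates default to zero so that rearrangement
stress is always an explicit choice of the experiment.

The validation suite runs this simulator at 200 kb genomes, 10 contigs and
three references on the tree
`((S:0.35,R1:0.35):0.15,(R2:0.30,R3:0.30):0.20)` — one close reference
(patristic distance 0.7) and two distant ones (1.15) — and, for the
rearrangement experiments, an inversion rate that puts ten expected
inversions on the mean branch. These sizes exercise every stage (tens of
thousands of seeds per contig, multi-record bookkeeping, conflict handling)
while keeping a full multi-seed run in the minutes range.

What the simulator does **not** emulate — and what passing tests therefore
do not show about real data: read-level sequencing error and coverage
structure (contigs are exact substrings plus branch mutations), repeat
families (random sequence is repeat-free, so repeat-induced conflicts are
exercised only by hand-built cases), base composition bias, horizontal
transfer, and assembly chimeras.

## Numerical and degenerate-input behaviour

* All tie-breaks are fixed (lexicographic), so every stage is deterministic:
  identical inputs give byte-identical outputs, and the match cache (keyed
  by an MD5 digest of sequences and parameters) returns byte-identical
  tables.
* `tau` must be strictly positive: the contig species cannot serve as its
  own reference, and a zero-length path in the tree is rejected rather than
  silently producing infinite weight.
* A run without any matches yields an all-zero graph with a warning, an
  empty layout, and an evaluation with undefined precision.
* Contigs shorter than `min_length` cannot be matched and are skipped with
  a warning; they still appear as isolated nodes in the layout.
* Projections may extend beyond record boundaries; displacement handles
  that without clamping, and whole-contig extension clips to the record.

## Known limitations

* A contig smaller than roughly the lost-fragment size is inherently
  ambiguous: the edge that skips it has a displacement near $\mu$ and can
  score comparably to the true adjacencies, entering the layout as a
  conflict edge through the one-endpoint exception. This is the model being
  honest about an unidentifiable case, but it does cost precision when such
  contigs occur.
* The whole-contig extension shortcut requires eight supporting seeds; a
  true 64-base match whose errors leave fewer intact 11-mers is only found
  if the greedy extension can reach it from a seed, so heavily clustered
  error patterns near the minimum length may be missed.
* The per-reference maximum (rather than a sum) over supporting match pairs
  discards multiplicity information that could, in principle, distinguish
  a repeat-mediated adjacency from a unique one.
* Inversion counts per branch scale with branch length; a fixed per-branch
  event count would require per-branch rates, which the parameterization
  does not expose.
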