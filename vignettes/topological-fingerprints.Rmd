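---
title: "Topological fingerprints for RNA structure classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological fingerprints for RNA structure classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xiosfp)
```

## The model

Functionally related RNAs often conserve almost nothing at the sequence
level; what they conserve is the arrangement of base-paired helices — which
stems nest inside which, which cross to form pseudoknots. xiosfp works at
that level of abstraction. A structure's base pairs are collapsed to stems
(paired half-intervals on the sequence), and each unordered stem pair falls
into exactly one of four relationships:

* **S** (serial): the stems are adjacent on the sequence; no edge is stored.
* **I** (included): one stem nests inside the other's loop; stored as a
  directed edge from container to contained, because containment is not
  symmetric and topology counts are only reproducible if the direction is
  recoverable.
* **O** (overlapping): the half-stem intervals interleave — a pseudoknot.
* **X** (exclusive): the stems conflict (shared bases or interleaved
  half-stems that cannot coexist). The class is represented throughout, but
  no single consistent structure produces X edges, and none of the
  generators in this package emit them; X is effectively a catch-all for
  pairs that are neither S, I nor O.

The resulting XIOS graph drops all metric detail (stem lengths, loop sizes)
and keeps only topology, which is exactly the part that survives
inaccurate or incomplete structure determination.

A topology of N stems can equally be written as an *arrangement*: the
sequence of the 2N half-stems, each stem label appearing twice. `(1, 2, 1,
2)` is the minimal pseudoknot; `(1, 2, 3, 2, 3, 1)` is a crossed pair inside
the loop of an enclosing stem. Arrangements are the native representation
for enumeration and for the graph surgery used in the evaluation protocols.

## The motif library

`buildMotifLibrary()` enumerates every arrangement of up to seven stems
whose first occurrences ascend — there are (2N−1)!! of them per size, 135,135
at N = 7 — converts each to a graph, discards topologies that are not
connected under I/O edges, and deduplicates by canonical code:

```{r library, eval = FALSE}
lib <- buildMotifLibrary(7)
table(motifTable(lib)$n_stems)
#>     1     2     3     4     5     6     7
#>     1     2     8    46   368  3914 51390
```

The census (1, 2, 8, 46, 368, 3914, 51390; 55,728 motifs of 2–7 stems) is
the package's decisive end-to-end test: it is only reproduced if
enumeration, edge derivation and canonicalization are all correct.

**Canonicalization.** Isomorphic graphs — including mirror images such as
`(1,2,1,3,3,2)` and `(1,2,2,3,1,3)`, which are the same topology read from
the other end of the molecule — must map to one key. We use the
lexicographically minimal adjacency encoding over all vertex orderings,
computed by branch-and-bound in C++ with the edge-label order
i < j < o < x < (no edge). Minimality over *all* orderings makes
equal-code ⟺ isomorphic true by construction; the property is additionally
verified against a brute-force bijection oracle in the test suite. Any
complete canonical form would do — the census above is the arbiter, not the
code dialect. The string form (`"1.2.i|1.3.i|2.3.o|"`) is this package's
own compact index.

**Ancestry.** Deleting one stem from a motif (keeping I/O connectivity)
yields its *parents*; the transitive closure gives its *ancestors*. Parent
sets are computed lazily and memoized, since most analyses touch only a
small fraction of the library. Ancestry is floored at two stems: the
single-stem motif is an ancestor of everything, so it carries no
discriminative signal and is excluded from fingerprints and from the
Hamming universe (hence 55,728, not 55,729).

## Fingerprints

A graph's *simple fingerprint* is the set of ≤7-stem motifs it contains.
Two routes are provided:

* `exhaustiveFingerprint()` enumerates every connected induced subgraph of
  exactly min(7, component size) vertices per I/O component (ESU
  enumeration, each subset visited once) and counts subsets per motif. It
  is deterministic and, below roughly 20 vertices, fast.
* `simpleFingerprint()` draws random connected subgraphs — a uniform start
  vertex, then repeated uniform choices among the I/O neighbors of the
  grown set, stopping at seven vertices or when no neighbor remains — and
  counts how often each motif is sampled. Sampling stops when every motif
  observed so far has been drawn at least `minCount = 10` times. The
  condition is evaluated after every sample, so a newly discovered motif
  resets readiness; a `maxIter` cap (default 10^6) guards against
  pathological cases and warns when hit. Independent samplers may be run
  concurrently and their count maps merged additively, with termination
  judged on the merged map.

Components smaller than seven stems contribute their whole component;
sampled singletons are discarded, consistent with the two-stem floor. The
*extended fingerprint* (`extendFingerprint()`) adds every ancestor of every
member with count 0: partial matches between related topologies then show
up as shared ancestors even when the sampled 7-stem motifs differ.

The "sampled 10 times" rule could be read as ten distinct start vertices;
we count raw samples, which is the weaker and simpler reading, and verify
against the exhaustive oracle that the motif *set* is complete at
termination (50 random graphs of up to 12 vertices in the acceptance
suite, and the set is stable across seeds).

## Similarity and evaluation

Fingerprints are compared as sets — counts are deliberately ignored — with
five functions: intersection |X∩Y|, cosine |X∩Y|/√(|X||Y|), Dice
2|X∩Y|/(|X|+|Y|), Jaccard |X∩Y|/|X∪Y|, and Hamming (the number of motifs
on which the fingerprints agree, over a universe of U motifs; U defaults
to 55,728). Conventions at the boundary: two empty fingerprints are
identical (normalized similarity 1); one empty gives 0. U only shifts
Hamming scores by a constant within a batch, so rankings and ROC curves do
not depend on it.

Classification is evaluated by ranking all unordered pairs (self-pairs
excluded) by similarity, labeling same-family pairs positive, and
computing the ROC AUC via the midrank Mann–Whitney statistic (ties count
1/2). `njTree()` wraps the standard Saitou–Nei neighbor joining from
\pkg{ape} on 1 − similarity, clamping negative branch lengths to zero.

## The synthetic study conditions

The curated structure collection used in the original study is not
distributed with this package, so the evaluation protocols run on
synthetic families generated by the package itself:

* `randomXiosGraph(n)` draws a uniform perfect matching of 2n half-stem
  positions (equivalently, a uniform first-occurrence-canonical
  arrangement) and rejects IO-disconnected topologies.
* `synthFamilies()` builds 8 families × 10 members from 15-stem seed
  topologies: each member loses a random 20% of the seed's stems
  (`removeVertices()`, round-half-up) and is re-expanded to 15 stems by
  splicing motifs drawn from a decoy database built from all seeds.
* The decoy database (`buildDecoyDB()`) is the exhaustive frequency table
  of connected 2–5-stem subgraphs in the source set — the background motif
  distribution. `expandGraph()` draws motifs proportional to frequency
  (sizes restricted so the remaining budget is never 1) and splices each
  as a contiguous block into the host arrangement at a uniform cut point.
  The paper-scale protocol pads everything to 30 vertices; the simulations
  here use 15-vertex members and 15-vertex decoy controls so that
  exhaustive fingerprints stay cheap, and because the control criterion
  (decoy-vs-decoy AUC near 0.5) is size-free.

The splice mechanism is this package's own concrete choice where the
original embedding procedure is unspecified: inserting a contiguous block
preserves the decoy's internal topology and the host's topology exactly,
and lands the insertion serial to or nested inside host stems (never
crossing them). Each insertion is logged in the result so tests can verify
the embedded block's canonical code.

Under these fixed conditions (seeded), the acceptance suite observes:
extended-Jaccard AUC above 0.9 and at least the simple-Jaccard AUC; AUC
decreasing monotonically as the removal fraction grows through 0, 0.1,
0.3, 0.5, 0.7; and decoy-vs-decoy AUC within [0.4, 0.6]. These mirror the
directional findings on the real curated set (extended 0.952 vs simple
0.870; a decaying removal series; decoys near chance) without claiming the
real-data values, which require the curated structure files.

What the generator does *not* emulate: real stem-length and loop-size
distributions, family-specific motif biases, or experimental noise
correlated across members. Passing the synthetic acceptance therefore
demonstrates that the machinery separates topology families under
controlled perturbation, not that the specific published AUCs are
reproduced.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout, matching CT/BPSEQ.
* `pairsToStems()` merges consecutive pairs when both the left-position
  step and the right-position step are between 1 and gapLimit + 1; a
  crossing successor (right end increasing) never merges, which the merge
  rule needs to state explicitly to avoid fusing crossed pairs into one
  "stem". The default `gapLimit = 3` tolerates small bulges; stem
  granularity is a user knob, not a derived quantity.
* Vertex-removal counts round half-up; removal that would empty a graph is
  refused except in the pseudoknot-removal protocol, where a total budget
  of 100% is meaningful for a pure pseudoknot.
* When pseudoknot stems exceed the removal budget, a random subset of them
  is removed and a warning flags that O edges remain.
* Degenerate similarity inputs (empty fingerprints) follow the documented
  conventions above; the Hamming universe must be at least |X∪Y|.
* Problem sizes in the tests — 15-stem families, 12-vertex sampling
  checks, 2,000 oracle pairs at ≤6 vertices — were chosen as the smallest
  sizes at which the corresponding property is non-trivial.

## Limitations

* The library stops at seven stems, as in the original method; larger
  common substructures are only visible through their ≤7-stem motifs.
* X edges are represented but never produced by any constructor here;
  workflows over mutually exclusive alternative structures would need a
  builder of their own.
* Canonical code strings are this package's own index; they partition
  graphs identically to any minimum-DFS-code implementation but are not
  byte-compatible with other software.
* `exhaustiveFingerprint()` is combinatorial in graph size (guarded at 40
  vertices); use sampling beyond that.
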