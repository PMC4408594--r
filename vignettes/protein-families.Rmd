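---
title: "Building and scoring protein families from pairwise similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and scoring protein families from pairwise similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protofam)
```

## The clustering model and its assumptions

protofam clusters proteins bottom-up from an all-vs-all similarity table.
The working assumptions are those of homology-graph clustering generally:
that BLAST E-values, even weak ones, carry a usable ordering of relatedness;
that families are better recovered by agglomerating under a *relaxed*
E-value ceiling (default 100) than by thresholding hard, because the merge
order — not the absolute score — decides the tree; and that proteins with no
admissible similarity to anything else are genuine singletons, not noise to
be forced into families.

At each step the two most similar admissible clusters merge. Admissibility
requires at least one real cross-cluster edge: pairs of clusters connected
only through the "missing = ceiling" convention never merge, which is what
makes the result a forest (one tree per connected component) instead of a
single rooted tree. Merging through ceiling-only pseudo-edges would
fabricate similarity that was never observed.

### Linkage

The default linkage is the geometric mean of the cross-cluster E-values,
computed as the arithmetic mean of `log10 E` with missing pairs contributing
`log10(e_ceiling)`. Averaging on the log scale is the natural choice for
E-values, whose informative range spans hundreds of orders of magnitude; an
arithmetic mean of raw E-values would be dominated entirely by the single
worst pair. The `arithmetic-mean-negloge` option is accepted as a synonym:
it is the same quantity up to sign, orders every cluster pair identically,
and therefore produces the same forest — the package implements them as one
rule rather than pretending they differ. `single` and `complete` linkage are
provided mainly as alternative rules for validation studies; they share the
admissibility condition.

Because the mean-based linkage satisfies a Lance–Williams-type recurrence
(sums of logs and pair counts combine additively under a merge), the engine
updates cluster-pair statistics incrementally instead of re-scanning leaf
pairs. The test suite verifies, merge by merge including tie-breaks, that
this incremental engine reproduces a deliberately naive implementation that
recomputes every linkage from the raw leaf-pair matrix at every step.

### Determinism and numerical choices

* **Tie-breaking.** When two cluster pairs have exactly equal linkage, the
  pair whose `(smaller node id, larger node id)` is lexicographically
  smallest merges first. Clustering is therefore a pure function of the
  input graph and the linkage name; there is no randomness anywhere in the
  tree construction.
* **E = 0.** Aligners report underflowed E-values as 0; these are clamped to
  `1e-180` before the log transform, preserving their rank as "strongest
  observed" without producing infinities.
* **Duplicate and asymmetric hits.** All-vs-all BLAST reports most pairs
  twice (and multiple HSPs per pair). The parser keeps the *minimum*
  E-value per unordered pair — best evidence wins, and parsing becomes
  independent of row order and hit direction. When only one direction was
  reported, that value is used as-is; the clustering is undirected, so no
  symmetrization penalty is applied. Min/mean/max are all defensible
  combiners here; minimum is the documented choice because it matches the
  best-hit convention and is idempotent under re-reporting.
* **Node ids.** Leaves are numbered `0..N-1` in input order; the internal
  node created at merge step `m` is `N + m - 1`, the usual linkage-table
  convention, so merge tables round-trip losslessly.

### ProtoLevel, LifeTime, cuts, condensation

ProtoLevel is defined forest-wide: `PL = 100·m/M` with `M` the total number
of merges across all trees, a single global merge ordering. The alternative
— per-tree normalization — would make PL incomparable between families of
different depth; the global definition keeps "PL70" meaning the same
percentage of total merging work everywhere. A cut at `pl` keeps the
clusters alive after `m* = floor(pl·M/100)` merges, which makes PL0
(all singletons) and PL100 (the roots) exact endpoints. Families default to
clusters of size ≥ 2; the size-1 remainder is reported separately rather
than silently dropped, since singleton counting conventions differ between
studies.

A node's LifeTime is the PL span from its creation to its absorption into
its parent (roots run to PL100). LifeTimes telescope to exactly 100 along
every leaf-to-root path — a property the tests assert — and long-lived nodes
mark resolutions at which a cluster is stable. `condense()` splices out
internal nodes with LT below a floor, attaching their children to the
nearest surviving ancestor: `lt_min = 0` is the identity (the binary
forest), large floors leave only leaves and roots. Member sets and ancestry
of survivors are unchanged by construction.

## Annotation scoring

The correspondence score between a cluster `c` and the protein set `k` of a
keyword is the Jaccard overlap `|c ∩ k| / |c ∪ k|`. The union denominator is
what gives the score its stated semantics — it reaches 1 exactly when the
cluster *is* the keyword's protein set, penalizing both dilution (false
positives) and fragmentation (false negatives) symmetrically — and equals
`TP / (TP + FP + FN)` in confusion-matrix terms.

"Purity" in the annotation-gain rule is the *annotated-only* specificity:
the fraction of a family's annotated members carrying the keyword,
unannotated members excluded from the denominator. This is deliberate: the
unannotated members are precisely the inference targets, so counting them as
false positives would make coverage, not consistency, the gatekeeper. The
all-as-fp variant is available for reporting. The gain floor is strict
(purity > 0.2 by default) and gains target only proteins with *no* keyword
at all — a protein with any existing annotation is never overwritten — so
re-running the gain on an augmented table is a no-op, a fixed point the
tests check. Multi-keyword proteins count as true positives for each keyword
they carry; scoring is per-protein, not per-domain-hit (a protein with three
copies of a domain contributes once).

Cluster naming uses the same CS machinery with a floor of 0.2 (aligned with
the gain floor; there is no canonical value, and anything in 0.1–0.3 changes
little on well-separated data) and lexicographic tie-breaking for
reproducibility. The gain-candidate report applies strict filters — family
size at least 40, false-positive rate `FP/(TP+FP)` strictly below 5%, mean
matched-domain length strictly above 75 aa — reflecting the observation that
long single domains are the regime where hierarchical clustering infers
annotations most reliably.

## The multinomial occupancy null

Whether a family over-represents the analysed species is judged against
sampling `n` proteins *with replacement* with probabilities proportional to
proteome sizes — a multinomial model, appropriate because cluster sizes are
tiny relative to the 287 405-protein pool (the without-replacement
correction is of order `n²/N ≈ 10⁻³`). The expected occupancy is the closed
form `Σ_s (1 − (1 − p_s)^n)`; the full distribution of the number of
distinct species comes from inclusion–exclusion over species subsets,

`P(D = d) = Σ_{t ≤ d} (−1)^{d−t} C(S−t, d−t) A_t`, with
`A_t = Σ_{|T|=t} (Σ_{s∈T} p_s)^n`.

Subset enumeration is `2^S` (trivial for S = 18; guarded at S ≤ 25). The
signed sums can leave a residue of order machine epsilon, so probabilities
are clamped to `[0, 1]`; the tests require the distribution to sum to 1
within `1e-9`, to match full `S^n` outcome enumeration on small instances,
and to agree with Monte-Carlo sampling within three standard errors. On the
bundled 18-proteome arthropod catalog the computation gives an expected
occupancy of ≈ 11.36 species for a cluster of 18 proteins and
`P(D ≥ 15 | n = 18) ≈ 0.0077`.

The bundled catalog's per-species counts reconcile exactly with the
collection's documented totals (287 405 proteins; 206 615 UniProtKB +
80 790 HGD; 138 762 Hymenoptera), which the acceptance script and tests
recompute.

## The synthetic generator

`simulate_families()` is the package's test bed: it plants a known family
partition and emits the three inputs every other module consumes. It
emulates the features that matter for the pipeline's logic — species
assigned by proteome-size-weighted round-robin; family sizes from a
truncated geometric with a heavy-tail component (so a few families dwarf
the rest, as real family-size distributions do); within-family similarities
drawn with `−log10 E` uniform in `[20, 120]`, far below the ceiling;
optional spurious cross-family edges just under the ceiling; one true
keyword per family applied to a coverage fraction (default 0.73, the
typical Pfam coverage of arthropod proteomes) and corrupted at a
configurable noise rate. All draws go through a single generator keyed by
the mandatory seed, so outputs are bit-reproducible.

What it does **not** emulate: E-values correlated through evolutionary
distance (real similarity decays smoothly; planted families are
near-cliques), domain architecture (multi-domain proteins bridging
families, the main source of chaining in real data), alignment-length
effects, and fragmented gene models. Passing the planted-recovery
benchmarks therefore shows the machinery is correct — the merge rule, cut,
scoring and gain do what they claim — not that PL70 is the right resolution
for any particular real proteome: on well-separated synthetic components
the best cut sits at PL100 because each component's root *is* the planted
family, whereas real similarity graphs are connected enough that the
interesting structure lies at interior levels.

Benchmark problem sizes were chosen to exercise every code path while
keeping the full suite fast: oracle-equivalence on 100 random graphs of up
to 50 proteins, planted-recovery on 20 instances of 180 proteins in 10
families, and gain-restoration on instances of 240 proteins in 12 families.

## Interfaces and limitations

The package surface is functions plus a thin `exec/protofam` subcommand
script; outputs are headered TSVs, trees export as Newick with
`[&id=,pl=,lt=]` comment tags on internal nodes (comments rather than node
labels, so downstream tools that ignore them still parse the topology).

Known limitations: the merge engine is pure R and comfortable to a few
thousand proteins — proteome-scale runs (10⁵–10⁶ sequences) need the
constrained-memory engineering this package deliberately does not attempt;
the exact occupancy computation is capped at 25 species; keyword scoring
treats annotations as flat sets (no domain hierarchy or clan structure);
and `parse_blast_tabular` trusts its input's protein identifiers — no
accession normalization is attempted.
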