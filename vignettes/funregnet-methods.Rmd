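---
title: "Methods: orthology-based regulatory network inference"
author: "funregnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthology-based regulatory network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funregnet)
```

## The inference procedure

funregnet reconstructs a directed gene regulatory network (GRN) for a
target fungal genome from three kinds of evidence:

1. **Curated interactions in model species.** Tab-delimited tables of
   experimentally supported TF → target-gene (TG) relations in
   *Aspergillus nidulans*, *Neurospora crassa* and
   *Saccharomyces cerevisiae* (or any species the user supplies), each
   optionally carrying an effect sign (positive / negative / unknown).
2. **Orthology.** A ProteinOrtho-layout table linking the proteins of each
   source species to target-species proteins. The transfer rule is strict:
   a candidate edge is created in the target species *only when both the TF
   and the TG have orthologs there*. An interaction with an orphan on
   either side contributes nothing.
3. **Binding-site corroboration.** Each inferred edge is annotated with the
   number of predicted binding sites for the TF's position weight matrix
   (PWM) in the 1000-bp promoter of the target gene. Binding sites are
   evidence, not a filter: edges with zero predicted sites are retained,
   mirroring the relative reliability of curation + orthology versus motif
   scanning.

### Many-to-many orthology

Ortholog tables routinely contain co-orthologs on either side. funregnet
expands them as a full cross-product: if a TF has two target co-orthologs
and its TG has one, two edges are created. This is a deliberately
recall-first choice — every supported pair is emitted, and provenance
(which source species support each merged edge) keeps the expansion
traceable. Identical (TF, TG) pairs arising from several source species
are merged: provenance is the union, the weight is the sum of per-species
weights (1 each by default, so weight = number of supporting species; a
phylogenetic-distance weighting can be supplied as a named vector), and
the effect sign is resolved by a total order: agreeing signs keep the
sign, a sign beats "unknown", and conflicting signs give "unknown". The
total order is needed because downstream summaries tally
positive/negative/unknown edges.

### Promoters

Promoters are fixed-length windows (default 1000 bp, configurable)
immediately upstream of the annotated gene start, strand-oriented:
for a `+` gene the 0-based half-open genomic interval
`[start-1-L, start-1)`, for a `-` gene `[end, end+L)`
reverse-complemented. GFF3 coordinates stay 1-based inclusive; internal
intervals are 0-based half-open — stating both conventions per type removes
the usual off-by-one ambiguity. Windows crossing a contig edge are
truncated (not padded) and flagged. Promoters are *not* trimmed when they
overlap an upstream neighbour's coding sequence; annotation-aware trimming
is easy to add but changes the scanned universe, so the default mirrors
plain fixed-window extraction. Genes annotated with strand "." are treated
as `+` with a warning.

## Exact per-site p-values for PWM scanning

A CIS-BP frequency matrix is converted to a log2-odds matrix against a
0-order background $b$:

$$s_i(x) = \log_2 \frac{p_i(x) + c\,b(x)}{(1 + c)\,b(x)}$$

with pseudocount fraction $c = 0.01$ (configurable). The null distribution
of the window score $S = \sum_i s_i(X_i)$, $X_i \sim b$ i.i.d., is computed
*exactly* by dynamic programming: scores are held on an integer lattice of
step `granularity` (default 0.001 bits) and the point mass at 0 is
convolved position by position with the four-outcome distribution
$\{s_i(x) : b(x)\}$. The survival function $P(S \ge s)$ then gives the
p-value of every window. Window scores produced during scanning are
computed *on the same lattice*, so the p-value lookup is exact at lattice
resolution, not an approximation — the test suite checks the DP against
enumeration of all $4^w$ words for $w \le 6$, where agreement is at
floating-point precision.

Both strands are scanned, all overlapping hits are reported (no greedy
masking), windows containing non-ACGT characters are skipped, and a window
is a hit iff its p-value is at most `p_threshold` (default $10^{-4}$).
The threshold is interpreted as a per-site p-value; matrix-scan tools
describe the same cutoff in e-value vocabulary, but at a fixed scan length
the two orderings coincide and the per-site form is the one with an exact
null. The default background is estimated (with +1 pseudocounts) from the
full scanned promoter set; a uniform background is available by flag.
Calibration is verified empirically: on $10^6$ i.i.d. background
positions the observed hit rate at $p \le 10^{-4}$ matches the
$2\,(L - w + 1)\,10^{-4}$ expectation within 3 binomial standard
deviations.

Numerical notes: the lattice support is capped (default $5\times10^6$
points) and a too-fine granularity produces an error suggesting a coarser
step rather than silently overflowing; matrices whose rows do not sum to
1 within $10^{-3}$ are rejected (counts-dialect files must be converted
to frequencies first); zero-probability cells require a positive
pseudocount, otherwise conversion errors out rather than emitting
$-\infty$.

## Network analysis conventions

* **Degrees.** A self-loop (auto-regulation) contributes 1 to in-degree
  and 1 to out-degree, so $\sum_v K(v) = 2E$.
* **Average degree** is $2E/N$ *truncated* (not rounded) to one decimal —
  the only convention consistent with the published summary values
  (7.227 → 7.2, 6.069 → 6.0). Hub percentages likewise truncate
  $100 \cdot K_{out}^{max}/N$ to an integer.
* **Clustering** is computed on the undirected simple projection with
  self-loops removed; nodes of projected degree < 2 get 0.
* **Centralities.** Degree and betweenness on the directed graph
  (self-loops removed); closeness as *harmonic* centrality, which stays
  well-defined on weakly-but-not-strongly connected digraphs; eigenvector
  centrality on the undirected projection, normalized to unit maximum.
  The eigensolver's start vector is drawn from a pinned RNG state so
  repeated runs are bit-identical.
* **Components** are weak (direction-ignoring), reported in decreasing
  size; the largest is the giant component.
* **Hubs** are TFs ranked by out-degree, ties broken lexicographically by
  id for determinism.
* **Communities.** Blondel's two-phase Louvain algorithm, applied to the
  undirected weighted projection (antiparallel arcs sum their weights) at
  resolution 1 — the method is defined for undirected graphs, so the
  directed GRN is symmetrized explicitly rather than implicitly. The seed
  fixes the node-visit order, making partitions reproducible; community
  counts on large networks remain order-sensitive, which is why they are
  treated as seed-dependent rather than exact quantities.
* **Enrichment.** Per (community, term), a one-sided upper-tail
  hypergeometric test against the annotated universe, with
  Benjamini–Hochberg adjustment across all tests in the family. Terms are
  flat labels; ontology propagation, if wanted, must be precomputed into
  the annotation table. The term × community $-\log_{10}(\text{adjusted }p)$
  matrix is the data layer of the usual enrichment heatmap.

## TF family classification

Proteins are classified as TFs by matching their precomputed PFAM /
InterPro domain annotations against a packaged catalog of eukaryotic
DNA-binding-domain families (37 families, a curated and editable TSV
covering the families recovered from fungal proteomes). PFAM and InterPro
evidence are unioned — a hit from either source suffices — and proteins
whose annotations imply several families are reported both ways: counted
once per family in the family × species matrix, and once under their
exact combination (e.g. `Zn2Cys6+C2H2_ZF`) in a separate combination
table, so the two views stay reconcilable. Combination labels use the
catalog's canonical family order, making them deterministic.

## The six-table store

All inputs and results are assembled into a relational layout of exactly
six tables — `gene`, `ortho`, `pwm`, `regulation`, `tfbs_prediction`,
`network_node` — written as a directory of TSVs with referential
integrity checked on save (an orphan id is a hard error naming the id).
Re-loading the store reproduces the network exactly; the edge table export
is deterministically sorted so byte-level comparison of runs is
meaningful. TSV was chosen as the canonical on-disk form because it keeps
the schema testable, diffable and version-controllable; the layout maps
1:1 onto an embedded SQL database for users who need indexed access.

## The synthetic fixture generator

`generate_fixture()` emulates every input format the pipeline consumes,
with planted ground truth. Defaults (60 gene families, 3 source species,
40 curated interactions per species, 6 TF families, orthology rate 0.8,
co-ortholog rate 0.1, 9-bp motifs, plant rate 0.9, 1000-bp promoters,
effect mix 0.40/0.25/0.35 positive/negative/unknown) were chosen once as
a desk-scale caricature of the real setting: three model fungi, promoters
of the published length, motif widths typical of fungal zinc-cluster
binding sites, and enough interactions that one-, two- and three-species
provenance categories all occur. Planted motif instances use per-position
consensus probability 0.97, which makes a planted 9-mer clear
$p \le 10^{-4}$ with near-certainty, so recall assertions are tight
without flakiness; background sequence is i.i.d. with composition
A/T 0.3, C/G 0.2 (fungal-like AT richness). Co-ortholog fan-outs are
planted deliberately to exercise the cross-product decision.

The generator is a pure function of its config (seed included): the same
config yields byte-identical bundles. Ground-truth edges are derived by a
plain enumeration of the transfer rule over the generated tables,
independently of the vectorized production path, and the test suite
checks that the pipeline reproduces them exactly (edge F1 = 1.0).

What the fixtures do *not* emulate: realistic genome composition
(repeats, isochores, nucleosome-driven positional bias), annotation
errors in the domain tables, curation noise in the interaction tables,
and divergence between a motif's consensus and its in-vivo sites. Passing
fixture tests therefore demonstrates correctness of the machinery — the
transfer rule, the exact null, the joins — not biological accuracy of any
particular real-genome network.

## Problem sizes and runtime choices

The test suite and the acceptance script run at desk scale by design:
fixtures of 60 gene families, exhaustive PWM enumeration up to width 6,
null calibration on $10^6$ positions, exhaustive graph oracles on all
3-node digraphs plus seeded random 4–6-node digraphs, and
planted-partition recovery on a ring of four 5-cliques. These sizes keep
a full run in tens of seconds while still exercising every code path;
full-genome runs (thousands of genes, hundreds of matrices) use exactly
the same code and scale linearly in promoters × matrices.

## Known limitations

* Transfer recall is bounded by ortholog coverage; regulators without
  orthologs in the sources are invisible to the method.
* The cross-product expansion can over-generate edges for large co-ortholog
  families; provenance and TFBS counts are the intended post-hoc filters.
* The 0-order background ignores dinucleotide structure; a Markov
  background would sharpen p-values in CpG-skewed promoters.
* Promoters are fixed windows: UTR-aware or neighbour-trimmed definitions
  are out of scope.
* Louvain community counts are resolution- and order-dependent; only
  seed-pinned runs are comparable.
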