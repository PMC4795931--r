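---
title: "Methods and design of themenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of themenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(themenet)
```

`themenet` is a list-centric toolkit: the unit of analysis is a plain gene
list, and every stage either refines that list (expression filtering,
PPI-partner extension, orthologue conversion) or annotates it
(theme enrichment, heatmap matrices, composite interaction networks,
network topology). This vignette explains the statistical models and
algorithms behind each stage, the defaults and why they were chosen, and
what the synthetic fixtures do and do not demonstrate.

## Theme enrichment

For a foreground list of $n$ genes drawn from a background of $N$ genes,
of which $K$ are annotated to a theme and $k$ fall in the foreground, the
over-representation p-value is the one-sided Fisher's exact
(hypergeometric tail) probability

$$
p \;=\; \sum_{j=k}^{\min(n,K)}
  \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}} .
$$

The test is one-sided because enrichment asks only whether a theme is
over-represented; depletion is not reported. The tail is evaluated through
the numerically stable hypergeometric distribution function rather than by
summing ratios of large binomial coefficients; the test suite checks the
result against exact rational enumeration on every contingency table with
$N \le 30$.

Multiple-testing correction offers Bonferroni, Holm step-down and
Benjamini–Hochberg step-up, with BH at $\alpha = 0.05$ (inclusive) as the
default. Two decisions deserve note:

* **Background.** The default background is the *annotation universe* —
  every gene carrying at least one theme. A whole-genome background would
  silently include genes that can never contribute a success, deflating
  p-values; making the universe explicit keeps the contingency table
  honest and reproducible. An explicit background list can be supplied
  and is intersected with the universe.
* **What counts as a test.** Only themes with at least one annotated
  foreground gene ($k \ge 1$) are tested, and the correction's $m$ is the
  number of tested themes. Themes the foreground cannot touch carry no
  evidence either way, and correcting for them is needlessly
  conservative; because this choice changes adjusted p-values, the
  conservative alternative ($m$ = all themes) is exposed as
  `correct_m = "all"`.

Foreground genes absent from the background are dropped, reported, and
shrink $n$ — they are never silently retained, which would bias $k/n$.

## PPI confidence classes

Evidence rows from different source databases are first canonicalized
(unordered pair, lexicographic order), deduplicated on
(pair, method, publication, source) and stripped of self-interactions. A
pair is **high-confidence** when supported by at least two distinct
detection methods *or* at least two distinct publications. Method
identity is plain string identity on the method accession: no ontology
hierarchy reasoning is attempted, so two different accessions count as
two methods even if one subsumes the other.

The **direct-physical** class is a subset of the high-confidence class: a
high-confidence pair qualifies if any evidence row is flagged as a direct
physical interaction by its source, or was produced by a method capable
of demonstrating direct contact. Capability is supplied as a user-editable
whitelist of method accessions (two-hybrid, FRET, AFM, crystallography and
similar assays ship as the default in
`inst/extdata/direct_methods.tsv`), because no exhaustive published list
of direct-capable methods exists. Both classifications are monotone:
adding evidence can promote a pair but never demote it.

## Network topology

Topology is computed on the largest connected component of the
high-confidence direct-physical graph (self-loops were excluded upstream,
so the graph is simple). When components tie for largest, the component
containing the lexicographically smallest gene id wins — an arbitrary but
deterministic rule.

Betweenness is implemented with Brandes' dependency accumulation:
undirected, unnormalized, endpoints excluded, each unordered
source–target pair counted once, and fractional credit shared equally
among equal-length shortest paths. Any consistent convention preserves
node ranks on a connected graph, and ranks are all the hub/bottleneck
classifier consumes; the convention is stated so that reported absolute
values are interpretable. The implementation is verified against naive
all-pairs shortest-path enumeration and against an independent graph
library.

**Hubs** are the top 10% of nodes by degree, **bottlenecks** the top 10%
by betweenness. With $N$ nodes the cutoff is the value at rank
$k = \lceil 0.10\,N \rceil$, and *every* node at or above the cutoff is
flagged. The tie-inclusive rule can flag more than 10% of nodes (on a
cycle, everyone ties and everyone is flagged); the alternative —
excluding an arbitrary subset of tied nodes — would make results depend
on sort order. The ceiling guarantees a non-empty hub set on any
non-empty graph.

## Compound unification and bioactivity filtering

An InChIKey's first 14-character block hashes the molecular skeleton
(connectivity); compounds from different sources sharing it are collated
into one compound group, the package's unified chemical entity. Keys are
validated for shape only (14 uppercase letters, hyphen, 10, hyphen, 1);
the second and third blocks are never interpreted. Grouping is therefore
deliberately insensitive to stereochemistry and protonation — the right
granularity for cross-database drug–target aggregation, and too coarse
for stereospecific questions.

Bioactivity records pass the binding filter when *all* of the following
hold: assay-to-target confidence score ≥ 4, assay type `B` (binding),
target type `SINGLE PROTEIN`, measurement type IC50, Kd or Ki, and value
≤ 10 000 nM. All comparisons are inclusive. Values must already be in nM;
no unit conversion is attempted, because silent unit guessing is a worse
failure mode than rejection. Curated drug-annotation pairs (DrugBank-style)
are *not* subject to the activity filter — they carry no assay value by
design — and each protein–compound edge records the minimum (most potent)
surviving value across its group members: a group is one chemical entity,
and its strongest measured binding represents it.

## Orthologues by mutual best hits

Two identifiers are orthologues when each is the other's *uniquely* best
similarity hit (minimum e-value) and both hits pass e ≤ 1e-3 (inclusive).
A query whose minimum is achieved by two subjects has no defined best
hit and is disqualified: under ties, a false pairing is worse than an
omission. The unique-best requirement makes the output a one-to-one
matching, which is what makes cross-species list conversion safe —
distinct genes can never collapse onto one target. Bit-score ranking is a
reasonable alternative "best" criterion; e-value minimum is used because
it is the quantity the threshold is stated in.

## Association heatmap and UPGMA

Significant gene–theme associations become a binary matrix (1 = gene
carries theme). Rows (genes) are compared by Euclidean distance — for
0/1 profiles, $\sqrt{\text{Hamming}}$ — and clustered by unweighted
average linkage (UPGMA): at each step the two clusters with the smallest
mean pairwise distance (over all original cross-pairs, maintained by the
size-weighted Lance–Williams update) merge at a height equal to that
mean. "Average linkage" conventionally denotes the unweighted (UPGMA)
variant, and that reading is recorded in the export metadata.

Determinism was a design goal: ties are broken by the smallest pair of
original row indices, and at each merge the cluster containing the lower
original index stays on the left, so leaf order is identical across runs
and platforms. This is why the clustering is implemented in the package
rather than delegated to a generic routine whose tie behaviour is
unspecified; the test suite confirms merge heights against a brute-force
recomputation oracle and against an independent average-linkage
implementation on tie-free inputs. Rows only are clustered by default —
the display question is which *genes* share functional profiles — with
column clustering available by transposition. User-supplied matrices are
accepted; nonzero entries coerce to 1 with a warning and all-zero rows
are dropped and reported.

## Composite networks

The composite network merges four edge families around the query list:
PPI (undirected, restricted to the high-confidence direct-physical class
— the reliability bar for display), miRNA→target and TF→target
(directed), and protein–compound (undirected, to compound-group nodes).
Edges are keyed by (pair, type), so one gene pair may legitimately carry
both a PPI and a TF edge. Only the one-hop neighbourhood of the query is
included; multi-hop expansion grows super-linearly and stops being an
annotation of the list. Query genes are always retained, even isolated,
because the display is anchored on the user's list. The activity filter
applies to assay-backed protein–compound edges only; annotation-only
drug edges survive it. Exports: GraphML (attributes preserved), SIF, and
a Cytoscape-compatible JSON `elements` structure.

## Expression filtering

A Barcode score in $[0,1]$ is the fraction of a tissue's samples in which
the gene is called expressed; ≥ 0.5 (inclusive) is "reliably expressed".
When a gene has records on several platforms in the same tissue it passes
if *any* record passes — the permissive reading, treating platforms as
parallel evidence — and platform disagreements are reported so the
permissiveness is visible. Genes with no record in the tissue are
reported separately from genes that fail the threshold: "no data" and
"not expressed" are different statements.

## Synthetic fixtures

`generate_bundle()` writes every input schema with planted ground truth
from a single seeded random stream (byte-identical across runs). The
defaults define the study conditions used throughout the tests and the
acceptance script: 200 genes per organism, 20 themes of 8–25 genes, a
30-gene foreground drawing 60% of its members from one planted 20-gene
theme, ~400 PPI evidence pairs (30% single-support, 35% two-method, 35%
two-publication, half of the high-confidence pairs given direct-physical
support), 10 planted orthologue pairs, 30 compounds over ~21 skeletons,
and ~47 activity records. Boundary records — confidence score exactly 4,
activity exactly 10 000 nM, Barcode exactly 0.5, e-value exactly 1e-3, a
self-loop, a reversed duplicate evidence row, a tied best hit and an
over-threshold reciprocal pair — are always planted so threshold
semantics are pinned by construction, not by accident of sampling.

The generator emulates table structure and decision boundaries, not
biological realism: PPI degrees are near-Poisson rather than scale-free,
themes are sampled independently rather than nested as real ontologies
are, and identifiers carry no homology structure. Passing tests therefore
demonstrate that the *rules* are implemented exactly as stated and that
planted signal of realistic strength is recovered; they do not
demonstrate power or calibration on real interactomes.

## Numerical and degenerate-input choices

* All significance and threshold comparisons are inclusive (`>=`, `<=`),
  matching how the cutoffs are stated.
* UPGMA tie comparison uses an absolute 1e-15 band so that floating-point
  noise cannot flip a tie-break.
* Empty gene lists, empty graphs, single-row matrices and foregrounds
  disjoint from the background are errors with explanatory messages, not
  silent empties; empty *tables* (no compounds, no edges after filtering)
  are valid and propagate as empty results.
* Problem sizes in the tests and the acceptance script (exhaustive Fisher
  sweep to $N = 30$; 200 twelve-node graphs for betweenness; 100
  eight-leaf matrices for UPGMA; 1000 null simulations for the type-I
  check) were chosen so each oracle comparison is exhaustive or densely
  sampled at scales where the oracle itself is trivially correct.

## Known limitations

No identifier mapping between vocabularies; case-sensitive exact ID
matching throughout. No method-ontology reasoning in PPI confidence. No
unit conversion in bioactivities. Betweenness is exact, so graphs beyond
a few tens of thousands of edges would be slow. Many-to-many orthologue
groups are out of scope — mutual best hits are one-to-one by design.
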