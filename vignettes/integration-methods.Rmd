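---
title: "Qualitative integration and reoccurrence ranking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative integration and reoccurrence ranking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reoccur)
```

## The problem and the model

High-throughput experiments produce more candidate genes, and more putative
gene relationships, than a laboratory can follow up. A biologist typically
holds several heterogeneous result sets — differential-expression lists,
co-expression lists, interaction edge lists — and a set of domain-specific
criteria that a good candidate should satisfy in each of them. `reoccur`
automates that selection without fixing the data sources or the criteria:
each source is filtered with its own user-defined criteria, the filtered
sources are merged, and candidates are ranked by **reoccurrence** — the
number of distinct sources in which the candidate survives its filter.

The integration is deliberately qualitative. No weights, reliability scores
or probabilistic edge confidences are estimated; a source either supports a
candidate (after filtering) or it does not. For $S$ sources and a candidate
$x$, the statistic is

$$ r(x) \;=\; \bigl|\{\, s \in S : x \in F_s(D_s) \,\}\bigr|, $$

where $D_s$ is source $s$ and $F_s$ its filter. Ranking is descending in
$r(x)$, with lexicographic tie-breaks (C collation) so output order is
deterministic across platforms and locales. Reoccurrence counts *sources*,
not rows: duplicate rows inside one source collapse before counting, since
re-listing an element twice in one dataset is not independent evidence.

## The data model

A source is a *named matrix*: a tab-delimited table with a header row, one
identifier column (list source) or two node columns (network source), and
zero or more attribute columns. Attributes are typed:

* **value** — numeric (decimal or scientific notation), filterable with
  `<, <=, >, >=, ==`;
* **label** — free-text tags, filterable by membership in a tag set.

Blank attribute cells are permitted (missing data) and are preserved
through reading and writing. Identifier matching is case-sensitive after
trimming leading/trailing whitespace. The header row is mandatory because
filters address attributes by name. When filters are configured, attribute
kinds must be declared in the run config; type inference (`infer_schema`)
exists for exploratory reading but filtering never relies on it, so a
column that happens to parse numerically one day cannot silently change a
filter's meaning.

## Filter semantics

A filter set is a conjunction over *attribute groups*. Within one group the
member criteria combine with explicit `all` (AND) or `any` (OR) logic:

* `all` expresses cutoff ranges, e.g. `corr >= 0.4` and `corr <= 0.6`;
* `any` expresses disjoint tails, e.g. the absolute-correlation cutoff
  $|r| > 0.9$ as `corr > 0.9` OR `corr < -0.9`, and tag disjunctions such
  as `age == P6 | P10`.

Groups for different attributes always combine with AND. Three decided
edge cases:

* **Blank cells fail every criterion.** Missing data is allowed in the
  inputs, but a record cannot satisfy a criterion on evidence it does not
  carry. This is the conservative choice; filtered-out counts are logged so
  the effect is visible.
* **`==` on value attributes** compares within a fixed absolute tolerance
  of $10^{-9}$, since exact float equality is rarely what a user means.
* **Filters apply only to attributes**, never to the identifier columns;
  selection by identity is a different operation (and trivially done
  upstream).

An empty filter set retains everything, which makes *undefined mode*
(ignore all attributes and filters) exactly equivalent to *defined mode*
with empty filter sets — a property the test suite asserts.

## Network integration

Edge identity is the unordered node pair, ordered lexicographically into a
canonical key, so `(A,B)` and `(B,A)` are one edge. Directedness is a
per-source declaration in the config — the two-column edge-list format
carries no direction marker. Orientation observations accumulate per edge:
undirected sources contribute `none`, directed sources contribute `a->b`
or `b->a` relative to the canonical order. The direction status is then

* `undirected` — only undirected observations;
* `directed` — only directed observations (both orientations may be
  present, and both are retained in the provenance);
* `merged` — at least one undirected and one directed observation.

This mirrors the drawing convention: blue line (undirected), pink line
with pink arrow (directed), blue line with pink arrow (merged). Keeping
opposite orientations in one edge record, rather than as two edges, keeps
the edge table aligned with the drawn network; the orientation set remains
recoverable from the in-memory object.

Node degree counts distinct incident edges, with a self-loop contributing
one; the degree-sum identity
$\sum_v \deg(v) = 2\,|E_{\text{non-loop}}| + |E_{\text{loop}}|$
is asserted on randomized fixtures. Node reoccurrence counts the distinct
sources in which the node appears in any retained edge.

## Reports

List runs produce one three-column table (element, reoccurrence,
semicolon-joined sorted sources). Network runs produce four tables: node
statistics, edge statistics, nodes, and edges. The statistics tables are
cumulative "count at or above level" tables over node degree and edge
reoccurrence, enumerating only observed levels. The edges table has the
fixed columns `node_a, node_b, direction_status, reoccurrence, sources`
and imports directly into Cytoscape as an edge list.

Provenance — integrated files, run mode, applied filters — is duplicated
into `#`-prefixed header lines, and each table is introduced by a
`# table:` marker, so the report is both human-readable and exactly
machine-parseable; `read_list_report()` / `read_network_report()` recover
the ranked structures byte-for-value. One serialization limit: the fixed
five-column edge table does not carry the per-edge orientation set, so a
network rebuilt from a report assigns directed and merged edges the
canonical `a->b` orientation for rendering.

## Thresholding, layout and rendering

`threshold_network()` re-extracts the network at a chosen level of node
degree and/or edge reoccurrence — the batch form of clicking a point on
the cumulative plots. Degree thresholds are evaluated against the
*pre-threshold* degrees (the numbers the user actually selected from);
degrees are then recomputed on the result. Both thresholds, when given,
apply simultaneously. Raising a threshold is anti-monotone (never adds
nodes or edges) and level 1 is the identity.

Interactive dragging is replaced by a seeded Fruchterman–Reingold layout
(`igraph::layout_with_fr`, 500 iterations, coordinates normalized to the
unit square): identical (network, seed) pairs give identical positions,
and re-rendering with the same seed gives identical decoded pixels. A
single node is placed at the canvas center. Rendering styles are data
driven — circle radius grows linearly with degree, stroke width with
reoccurrence — so equal statistics render identically. Output formats are
TIFF and PNG. The two cumulative plots are emitted as a companion chart
image.

## The synthetic fixtures

The generators produce the *outputs* of upstream analyses (ranked lists
and edge lists with attributes), not the analyses themselves — no
expression matrices, correlation estimation or differential-expression
testing are simulated. Ground truth is exact by construction: attribute
values are drawn from the passing or failing region of the source's
filter, so each source's pass set is known without re-evaluating
anything.

The case-study-shaped fixture mirrors the retinal workflow's structure:
eight lists over one pool of 272 genes — six co-expression lists (three
wild-type, three knockout anchors) with a `corr` value attribute filtered
at $|r| > 0.9$, and two differentially-expressed-gene lists with an `age`
label over {E16, P2, P6, P10, 4wk} filtered to {P6, P10}. Five planted
genes pass all eight filters; every background gene is forced to fail at
least one source and passes each other source with probability 0.35 — a
middling overlap chosen so background genes populate all intermediate
reoccurrence tiers the way partially-supported candidates do in real
integrations, while the top tier remains exactly the planted set. Gene
identities are synthetic labels (`g0001` …); the fixture reproduces
cardinalities and criteria, not biology. Consequently, passing tests show
that filtering, integration, ranking and reporting are correct on data of
this shape — they say nothing about the biological quality of any real
candidate list.

Network fixtures plant a path of shared edges in every source plus
source-unique background edges, giving known reoccurrence and
direction-status expectations under any mix of directed and undirected
declarations.

## Numerical and procedural choices

* Problem sizes in the test suite are small (tens of rows, tens of
  randomized repetitions; 20 seeds for the end-to-end recovery check)
  because every property is scale-free: the oracles are exhaustive
  enumerations or brute-force recounts that agree exactly, not
  statistically.
* The overrepresentation test is the one-sided hypergeometric upper tail,
  $P(X \ge k)$, matching the direction of an enrichment claim; the
  contingency counts are taken explicitly rather than inferred from a run,
  because the definition of the gene universe is a scientific choice the
  caller must own.
* All randomness (fixtures, layout) flows through explicit integer seeds;
  generators restore the caller's RNG state.
* Error handling separates configuration errors (reported together, with
  source context; CLI exit code 2) from data errors (first offending row
  named; exit code 1).

## Known limitations

* No interactive visualization; re-render with new thresholds instead.
* One layout scheme; no SVG export.
* Lists and networks never integrate in one run — they are different
  result shapes, and conflating them would make reoccurrence
  incomparable.
* No multiple-testing machinery around the overrepresentation test; it is
  a single planned test.
* Very large inputs are read whole into memory; the format is simple TSV,
  so upstream chunking is straightforward if ever needed.
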