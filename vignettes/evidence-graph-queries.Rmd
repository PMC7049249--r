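---
title: "Evidence-graph traversal queries: model, semantics, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-graph traversal queries: model, semantics, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evigraph)
```

## The data model

`evigraph` stores a directed property graph. A vertex is `(gid, label,
data)`; an edge is `(gid, from, to, label, data)`; `data` is a JSON-shaped
property value — scalars, ordered lists, and maps nested to any depth. Two
modelling decisions matter throughout:

* **Payloads live where the traversal needs them.** A somatic callset's
  link to an allele carries the caller method list and the gene annotation
  *on the edge*, because the canonical mutation-count analysis lands on
  that edge (`outE`) and aggregates its `ensembl_gene` field. The gene
  annotation is deliberately not duplicated onto the `Allele` vertex, so
  there is a single source of truth.
* **Dense vectors are ordinary properties.** A `GeneExpression` vertex
  holds its whole TPM vector as one `values` map. Nothing in the engine
  treats it specially; `render` passes it through unflattened and the
  `expression_to_matrix()` helper tabularizes afterwards.

Iteration order is part of the contract: vertices, edges, and each
vertex's adjacency lists replay in insertion order, so any query over the
same input files produces byte-identical output across runs. Numbers in
property maps are canonicalized to doubles on entry, because JSON cannot
distinguish `12` from `12.0` and write-then-load must be the identity.

The schema (a set of vertex labels plus legal `(from, edge, to)` label
triples, shipped as `inst/extdata/bmeg_schema.yaml`) is enforced by an
explicit validation pass, not at load time. Loading and validation are
separated on purpose: corrupted inputs should be *reportable* (a tibble of
typed violations: unknown label, dangling edge, illegal triple, duplicate
gid, missing required field) rather than unloadable, and integrity checks
belong to a data-release workflow, not to every mutation of the graph.
Validation therefore also accepts unfinalized graphs, which is what lets a
dangling edge surface as a violation instead of the error `finalize()`
would raise.

## Traversal semantics

A query is an ordered list of steps executed by *travelers* — cursors
holding a current element plus named mark snapshots. The semantics the
engine implements, and that the rest of the package depends on:

* `V(gids)` emits one traveler per named vertex in the given order, or all
  vertices in insertion order when no gids are given. A gid that matches
  nothing contributes no traveler (and no error), so a query over an
  unknown project simply returns an empty result.
* `out(labels)` replaces each traveler with one traveler per matching
  out-edge, positioned on the destination vertex and ordered by edge
  insertion; `outE` positions on the edge itself; `in`/`inE` mirror via
  the in-index. An empty label set means "any label". Applying a traversal
  step to a traveler sitting on an edge is an error naming the step.
* `as(name)` snapshots the current element; re-marking a name overwrites
  it; marks are otherwise immutable and survive all later movement.
  `select(name)` repositions the traveler on the marked element (so it is
  idempotent) and keeps all marks.
* `has(cond)` filters with a total predicate: order comparisons require
  both sides numeric and are otherwise false; `contains` is list
  membership and is false on scalar fields (the only semantics the
  canonical queries exercise); `within` tests membership of the resolved
  value in a literal list; a null field fails every leaf except `neq`.
  Totality is deliberate — real property maps are heterogeneous, and a
  filter that throws on a type surprise would make exploratory queries
  brittle.
* `distinct(fields)` keeps the first traveler per distinct tuple of
  resolved values, resolving marks exactly like `render` does — that is
  what lets the case/compound analysis count each (case, compound) pair
  once regardless of how many alleles or publications connect them.
* Terminals: `count`; `render(template)` (one tuple per traveler, missing
  fields resolve to null); `aggregate(term(name, field))` — multiset
  counts of the non-null resolved values, keys as text, buckets sorted by
  count descending with ties broken by key ascending in byte order.
  Travelers whose field is null are skipped rather than bucketed under a
  sentinel: an absent annotation is not a term. A query with no terminal
  emits element rows, which suits interactive exploration.

Field paths accept the forms `_gid`, `synonym`,
`gdc_attributes.sample_type`, `$mark.field`, `$._gid`, and an explicit
`_data` prefix (`$exp._data.values`); `$.x` and bare `x` are synonyms, as
are `$._gid` and `_gid`.

Two ordering decisions are stricter than any published description of
such engines requires: traveler order is fully specified (insertion order
everywhere), and bucket ties are broken deterministically. Both exist so
that the differential tests below can demand *exact* equality, row order
included, rather than equality up to permutation.

## The brute-force oracle

`brute_force_execute()` is a second interpreter written to be wrong in
different ways than the engine would be: it uses no adjacency indices
(every hop scans the full edge table), materializes every intermediate
traveler list, and re-implements filtering, distinct, aggregation
counting/sorting, and output shaping from first principles. It shares
only the field-resolution and term-key helpers, which are data-format
contracts rather than traversal logic. The test suite requires
`execute == brute_force_execute`, `identical()` to the row, on
hand-built fixtures and on 200 seeded random pairs (graphs up to 40
vertices / 120 edges, query depth up to 6, drawn over every step type).
Random queries are generated position-aware — traversal steps are only
emitted for travelers on vertices, marks are defined before use — so all
generated plans compile; invalid plans are tested separately as parse and
compile errors.

## The synthetic cohort and its ground truth

`generate_bmeg()` emulates, at desk scale, the shape of the public
resources an evidence graph integrates:

* a patient-like program (two projects of 20 cases; each case one sample,
  primary tumor with probability 0.8, else solid tissue normal; one
  aliquot and one somatic callset each; 1–15 mutations per case drawn
  from 3 recurrent candidate variants per gene over 50 genes, so alleles
  recur across cases and the allele table deduplicates);
* caller method lists per mutation edge (MUTECT with probability 0.7,
  each other caller 0.4, never empty) — values chosen so that the
  MUTECT filter keeps most but not all edges;
* 10 pathways of 3–12 member genes with membership edges in both
  directions;
* a cell-line-like program whose first project is a drug screen (8
  compounds; each aliquot tests each compound with probability 0.6, and
  aliquot *i* always tests compound *i* so every compound appears; EC50
  log-uniform over 10^-5..10^0, AUC uniform 0.2–0.9) and whose second
  project holds expression assays (log-normal TPM, meanlog 2, sdlog 1),
  with each screen line mirrored into the expression project with
  probability 0.5 via paired directed `same_as` edges — mirroring how a
  screen consortium and an expression consortium profile overlapping
  cell-line panels;
* 30 G2P associations linking mutation alleles to 1–3 compounds, 1–3 of
  12 publications, and a phenotype; the first association always joins a
  project-1 tumor allele to compound 1, so the literature-to-screen
  intersection the cookbook relies on is non-empty by construction.

These defaults are the package's study conditions; they are not tuned to
any dataset and the tests run against them as-is.

Ground truth for the eight cookbook queries is recorded during generation
by direct bookkeeping — e.g. the per-gene mutation tally increments as
each MUTECT-called tumor edge is emitted — and never by running the
engine. Agreement of engine output with this bookkeeping is therefore a
genuine differential check of the whole pipeline, and it is asserted
three ways: in memory, after a serialize/reload round trip, and against
the brute-force oracle. For order-sensitive (render) queries the
bookkeeping replays the same insertion-order traversal the engine is
specified to perform.

What the generator does *not* emulate, and what passing tests therefore
do not show: realistic mutation spectra or hotspot structure, real genome
coordinates, clinical covariates, batch effects or missingness in
expression, dose-response curve shapes behind the scalar EC50, and scale
(the default graph is ~630 vertices / ~1,258 edges, versus tens of
millions in production evidence graphs). Results about engine correctness
transfer; results about biological realism do not.

## Numerical and format choices

* EC50 is rounded to 6 significant digits, expression and AUC to 4
  decimals, at generation time, so every number survives JSON
  serialization exactly and ground-truth equality can be exact.
* JSON is written with full numeric precision (`digits = NA`), UTF-8,
  one object per line; the same graph always serializes byte-identically.
* Aggregation keys sort with radix (byte) order so results do not depend
  on the session locale.
* Edge gids, when absent in input records, are synthesized as
  `"(from)--(label)->(to)#(ordinal)"` — deterministic and unique.
  Duplicate gids on load are an error, not last-wins: silent overwrite
  would corrupt downstream counts.
* The generator restores the caller's RNG state, and all generator
  randomness derives from the single `seed` field.

## Problem sizes

The shipped tests run the default fixture (seed 42; ~630 vertices), a
reduced fixture (6 cases/project, 12 genes) for per-module checks, a
60-case random differential suite in the engine tests plus the 200-case
suite in the acceptance tests, and toy hand-countable inputs for every
ETL loader. The full suite completes in well under a minute on a single
CPU; `scripts/acceptance.R` recomputes everything from scratch in under
half a minute.

## Known limitations

* The store is in-memory and single-threaded by design: no transactions,
  deltas, pagination, or on-disk backends.
* The query language has no optimizer — steps execute in the order
  written — and no regex predicates or mutation steps.
* `has()` on edge travelers can reference vertex marks (resolution is
  uniform across positions), but no canonical analysis exercises it; it
  is covered only by the random differential suite.
* Compound-to-project edges are derived during drug-response loading (a
  compound links to the project whose samples tested it); other
  derivation rules are conceivable and would change the project-filtered
  compound query.
* The brute-force oracle is quadratic-ish by construction and intended
  for graphs of at most a few hundred elements.
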