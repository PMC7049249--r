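# evigraph

Cancer-genomics analyses routinely need data that live in different
repositories: somatic mutation callsets for patient cohorts, cell-line drug
screens, pathway membership databases, and literature-curated
genotype-to-phenotype associations. Evidence-graph systems integrate these
into one property graph — vertices and edges carrying arbitrarily nested
payloads, from a single `sample_type` string up to dense per-aliquot
expression vectors — and expose a traversal-based query language so a
question like *"which drugs in the literature are linked to the mutations
of this cohort, and how sensitive are cell lines to them?"* becomes a few
lines of query instead of weeks of data wrangling.

`evigraph` is a desk-scale implementation of that idea for R users:

* **Graph store** — an in-memory directed property graph with deterministic
  (insertion-order) iteration, JSON Lines persistence (`v.jsonl` /
  `e.jsonl`, one object per line), and validation against a declared schema
  of vertex labels and `(from_label, edge_label, to_label)` triples.
* **Schema** — a built-in cancer-genomics schema: the cohort tree
  `Program → Project → Case → Sample → Aliquot`, somatic callsets and
  deduplicated alleles, genes/pathways, compounds and drug-response
  experiments, gene-expression payloads, and G2P association vertices
  linking alleles to compounds, publications, and phenotypes.
* **Query engine** — a Gremlin-inspired traversal language. A query is a
  series of steps undertaken by *travelers*: `V`, `hasLabel`, `hasId`,
  `has(condition)`, `out`/`in` (move along edges), `outE`/`inE` (land on
  the edge itself, whose payload is then addressable), `as` (mark),
  `select` (recall a mark), `distinct`, `limit`, and the terminals
  `render`, `aggregate` (term counts), `count`. Conditions support
  `eq/neq/gt/gte/lt/lte/contains/within` with `and`/`or`/`not`, and field
  paths like `gdc_attributes.sample_type`, `$sample._gid`, or
  `$exp._data.values`.
* **Reference oracle** — `brute_force_execute()` re-interprets any query by
  naive path enumeration with no adjacency indices; engine and oracle must
  agree elementwise, which the test suite checks on hundreds of seeded
  random graph/query pairs.
* **ETL loaders** — MAF-like variant TSVs, GMT gene sets, TSV expression
  matrices, drug-response CSVs, and association JSON Lines, all emitting
  schema-conformant graph elements.
* **Synthetic cohort generator** — `generate_bmeg()` builds a seeded,
  schema-clean mini cohort (TCGA-like patient program plus a CTRP/CCLE-like
  cell-line program with `same_as` links between its screen and expression
  projects) and records ground-truth answers for the eight cookbook
  analyses by independent bookkeeping, never by running the engine.
* **Cookbook** — the eight canonical analyses (`q1_mutation_counts()` ...
  `q8_expression_matrix()`), each implemented purely as a query document
  handed to the engine. Results are tibbles away via `tidy()` /
  `as_tibble()`, and aggregations plot with `autoplot()`.

## Worked example

```r
library(evigraph)

fx <- generate_bmeg(synthetic_config(seed = 42))
fx$graph
#> <evigraph: 630 vertices, 1258 edges, finalized>
#>   vertex labels: Aliquot (72), Allele (134), Case (72), Compound (8), ...

# q1: mutations per gene in the patient cohort's first project, counting
# callset->allele edges whose caller list contains MUTECT
q1 <- q1_mutation_counts(fx$graph, "Project:TCGA-SYN-BRCA")
tidy(q1)
#> # A tibble: 41 × 3
#>   name      key             count
#>   <chr>     <chr>           <int>
#> 1 geneCount ENSG00000000030     5
#> 2 geneCount ENSG00000000050     5
#> 3 geneCount ENSG00000000004     4
#> # ...
```

Each bucket is a gene (the key is the `ensembl_gene` annotation carried on
the callset-to-allele edge) and the count is the number of MUTECT-called
mutation edges reachable from the project's primary-tumor aliquots — a
crude prevalence signal for candidate driver genes.

```r
# q7: EC50 of every screened cell line for one compound
tidy(q7_ec50_for_compound(fx$graph, "Program:CTRP-SYN", "Compound:CID0000001"))
#> # A tibble: 12 × 3
#>   `$sample._gid`              `$response.submitter_compound_id` `$response.ec50`
#> 1 Sample:CTRP-SYN:ACH-SYN-001 alpevistat                               0.0419
#> 2 Sample:CTRP-SYN:ACH-SYN-002 alpevistat                               0.359
#> 3 Sample:CTRP-SYN:ACH-SYN-003 alpevistat                               0.0000497
#> # ...

# q8: expression vectors for those lines, reached across same_as links into
# the expression project, assembled into a samples-by-genes table
m <- expression_to_matrix(q8_expression_matrix(fx$graph))
m[, 1:4]
#> # A tibble: 5 × 4
#>   sample                      ENSG00000000001 ENSG00000000002 ENSG00000000003
#> 1 Sample:CTRP-SYN:ACH-SYN-001           76.4             2.76            3.64
#> 2 Sample:CTRP-SYN:ACH-SYN-002           24.2             7.12           11.2
#> # ...
```

EC50 values are concentrations (log-uniform over five decades here), and
the expression table holds TPM values — the kind of matrix a drug-response
prediction model would train on. Every cookbook result is checked three
ways in the tests: against the generator's independently recorded ground
truth, against the brute-force oracle, and after a serialize/reload round
trip.

Custom queries use the same machinery directly:

```r
doc <- list(
  list(op = "V"), list(op = "hasLabel", args = list("Pathway")),
  list(op = "as", args = "pathway"), list(op = "out", args = list("genes")),
  list(op = "select", args = "pathway"),
  list(op = "aggregate", args = list(name = "pathwayGeneCount", field = "_gid"))
)
tidy(execute(fx$graph, parse_query(doc)))
```

A thin command-line wrapper ships in `exec/evigraph`
(`evigraph synth|validate|query|etl|cookbook`); see the script header for
usage.

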