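---
title: "A queryable RDF integration schema for multi-omics results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A queryable RDF integration schema for multi-omics results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omigraph)
```

## The problem and the model

Late integration of multi-omics studies starts from *result tables* — DEG
lists per contrast, DMR lists, peak lists per condition, compartment-switch
regions — plus a genome annotation that locates genes. The questions people
actually ask of these data are joins: relational joins ("DEGs of contrast X")
and *positional* joins ("genes overlapping a peak"). `omigraph` models both
uniformly as a labeled directed graph of RDF triples, organised in five
blocks:

1. **Genomic features** (gene, mRNA/transcript, exon, CDS, UTRs) from GFF3,
   with `parent` relations following the GFF3 `Parent` attribute.
2. **Functional annotation** — plain attribute columns (biotype, curated
   annotation lists) on feature entities.
3. **Experimental design** — `Condition` (one precise experimental
   condition), `Context` (an aggregation of conditions, giving flexibility
   when designs with several varying factors group conditions differently
   per comparison), and `Contrast` (compares two contexts; the entity every
   differential result attaches to).
4. **Differential entities** — rows of result tables, linked to their
   Contrast via declared relations.
5. **Regulatory/epigenomic entities** — peaks, switch regions, TF motifs —
   typically connected to everything else *only* through their genomic
   location.

What makes block 5 integrable without bespoke code is the location model.
Every located entity is serialized twice over (a deliberate dual encoding):

* a **FALDO** region node — `faldo:location` to a `faldo:Region` with
  `faldo:begin`/`faldo:end` exact-position nodes carrying 1-based inclusive
  `faldo:position` values, a `faldo:reference` link to a chromosome entity,
  and strand expressed through `ForwardStrandPosition` /
  `ReverseStrandPosition` classes (a plain `ExactPosition` when unknown) —
  used by overlap joins;
* four **flat attributes** (chromosome, start, end, strand) used by cheap
  tabular-style filters.

Whether strand should live in position classes or plain attributes is a
genuinely open design point; emitting both costs a handful of triples per
entity and lets each query style use the cheaper form.

## Conventions for lifting tables

Tables follow a first-column-is-entity convention: the first header names
the entity class and the column holds ids. A header `label@TargetClass`
declares a relation; its cells hold target-entity ids (comma-separated for
multi-valued cells, mirroring GFF3 `Parent` lists), minted in the target
class's namespace — which is how a DEG table whose first column is `gene`
*merges* with the GFF-derived gene entities rather than duplicating them.
Position columns are recognized by case-insensitive synonyms
(chromosome/chrom/chr/ref/reference/seqid; start/begin; end/stop; strand)
and are all-or-none. Everything else is an attribute; a column is numeric
iff every non-empty cell parses as a number (all-integral columns stay
integers), which keeps SPARQL `FILTER` comparisons predictable. Missing
cells emit no triple (open-world), never empty-string literals. Regulation
and methylation senses (UP/DOWN, hyper/hypo) are plain string attributes,
not subclasses — they are per-row facts of the source tables.

IRI minting is deterministic: `<namespace>/<class>/<id>` with strict
RFC 3986 percent-encoding of the id (including `%` itself, so encoding is
injective and re-minting can never collide or drift between runs).
Identical inputs always produce identical IRIs; loading the same file twice
is a no-op by RDF set semantics.

GFF3 records lacking an `ID` get the deterministic synthetic id
`<type>:<seqid>:<start>-<end>:<ordinal>`; `transcript` and `mRNA` remain
distinct classes unless the caller passes a type alias map, because merging
them is a modelling choice the converter should not make silently.
Chromosome labels are kept verbatim from each source; when sources disagree
("chr1" vs "1"), an alias map at conversion time is the right fix — silent
normalization could corrupt overlap counts.

## Query graphs and overlap semantics

A query is an abstract graph: nodes (entity class + attribute filters +
projected properties) and edges that are either declared relations or
overlap constraints. Compilation validates every class and property against
the merged dataset schema *before* emitting SPARQL, turns relation edges
into triple patterns on the declared predicates, overlap edges into FALDO
walks plus a `FILTER`, and an optional aggregate into `COUNT(DISTINCT ?v)`.
Non-aggregate queries are `DISTINCT` and ordered by the first projected
variable, so output is deterministic.

Overlap uses **closed 1-based intervals** on a shared reference:

```
any_overlap:  start(a) <= end(b) && start(b) <= end(a)
a_within_b:   start(a) >= start(b) && end(a) <= end(b)
```

Abutting intervals sharing exactly one base therefore *do* overlap — the
natural reading for inclusive coordinates, and the boundary case is pinned
by tests. The default is strand-blind `any_overlap`: biological statements
like "genes overlapping switches/peaks" carry no strand or containment
qualification. `same_strand` compares the normalized strand labels
(unknown == unknown matches; filtering unknowns out is a caller decision,
not a silent one). Overlaps are evaluated by `FILTER` inequalities rather
than materialized overlap triples — correctness first; materialization is a
performance opt-in left out of scope here.

`brute_force_overlap()` re-implements exactly these semantics as an
all-pairs scan over plain coordinate tables. It is deliberately independent
of the store and compiler, and the test suite asserts equality of the two
routes over randomized interval sets (three modes × two strand policies ×
50 seeds, 200 intervals per seed).

## The embedded store and SPARQL engine

No RDF engine exists for R in this package's dependency footprint, so the
store is an embedded triple table with named graphs (one per integrated
file, enabling per-dataset replacement) and a SPARQL SELECT engine covering
the fragment the compiler emits plus plain SELECTs: basic graph patterns,
`FILTER` with comparisons / `&&` / `||` / `!` / `CONTAINS` / `STR`,
`DISTINCT`, `COUNT(DISTINCT)`, `ORDER BY`, `LIMIT`. The default query graph
is the union of all named graphs, because questions span datasets freely.
Evaluation is a naive most-constrained-first BGP join; filters apply as soon
as their variables are bound. Numeric comparison is used when both operands
are numeric literals, lexical comparison otherwise.

The engine is *not* trusted on its own word: tests run the identical
compiled SPARQL and identical N-Triples export through `rdflib` (Python)
and assert equal answers, row for row on projections and count for count on
aggregates. Turtle exports are likewise round-tripped through an
independent parser.

## What the synthetic generator emulates — and what it does not

`generate_toy_annotation()` lays genes out sequentially per chromosome with
gaps of 400–900 bp and lengths of 800–3000 bp, mixed strands, 1–2 mRNAs per
gene and 1–3 exons (plus CDS) per mRNA. Because genes never overlap one
another, planting becomes constructive: `generate_omics_tables()` *places*
a peak inside each gene chosen to be a DEG∧peak hit and places decoy peaks
strictly inside intergenic gaps (with margins larger than the ±10 bp
extension used for switch regions), so every expected count is exact by
construction rather than by rejection sampling. The default plant emulates a
two-contrast, four-condition design (2Qvs2W / 4Qvs4W over 2Q/2W/4Q/4W):
20 and 30 DEGs per contrast (8/12 and 18/12 UP/DOWN), 4 and 7 planted
DEG∧peak overlaps, 6 and 10 gene∧switch overlaps, a caste-annotation list
whose intersection with the 4Qvs4W DEG∧peak set is 3, and a focal gene with
2 hyper- and 1 hypo-methylated associated DMRs. Generation is deterministic
per seed (byte-identical GFF3) and restores the caller's RNG state.

What passing these tests shows: the conversion conventions, FALDO encoding,
compiler and engine compose correctly, and counting queries return planted
truth exactly. What they do not show: realistic effect sizes, p-value
distributions, overlapping gene models, assembly-scale data volumes, or
chromosome-naming mismatches between real sources — the fixture genome is
clean by design.

## Numerical and scale choices

Default problem sizes keep the full test battery a few minutes on one CPU:
80 genes × 3 chromosomes for end-to-end runs, 100 + 100 intervals per seed
for oracle equivalence, 10 seeds in the acceptance script's agreement rate.
Decimal literals are written with up to 15 significant digits; integers stay
integral end to end. Coordinate validation is strict (`start >= 1`,
`start <= end`) with row/line context in errors; invalid table rows are
skipped with a counted warning (a bad row should not abort a 5000-row
integration), while invalid GFF3 lines are fatal (a malformed annotation
usually signals the wrong file).

## Reproduction suites and their limits

The two case-study suites transcribe published counts as write-once
constants next to the query graph that recomputes each: eight HCM counting
queries (691/835 up/down DEGs, 264/207 lncRNAs, 297/523 co-regulated —
the source supplement holds 523 entries although its text says 524, so 523
is the value a table-faithful reproduction must return — and 1453/3600
hyper/hypo DMRs) and the honeybee queries (325/247 switch-overlapping genes
per contrast; ATAC 253/382/4618/448 and ChIP 37/181/703/578 unique peaks per
condition). Running them against the *real* studies requires downloading
their supplements and genomes, which this package does not redistribute;
the shipped stand-in generators produce directories of the identical shape
with planted counts so the prepare → integrate → reproduce machinery is
fully exercised offline. Should the real honeybee gene-overlap counts not
reproduce under strand-blind `any_overlap`, the containment modes are the
first alternative semantics to try — the choice is exposed per edge rather
than hard-coded.

## Known limitations

* The SPARQL engine covers a deliberate subset — no `OPTIONAL`, `UNION`,
  property paths, subqueries or federation (`SERVICE`).
* No OWL reasoning or SHACL validation; relation ranges are checked lazily
  (a warning for targets absent from every schema), matching the open-world
  stance of incremental integration.
* BAM/VCF/bigWig, GTF/GFF2 and on-the-fly xlsx are out of scope; tables
  arrive as CSV/TSV.
* The naive join order is fine at fixture scale and for selective queries,
  but an assembly-scale annotation (millions of triples) would want the
  materialized-overlap path this package intentionally leaves out.
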