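---
title: "The seedledger data model: pedigrees, inheritance by reference, and redacting exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The seedledger data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedledger)
```

## The problem

A plant-biology lab's seed collection is a pedigree: founder accessions and
transformants are crossed and re-mutagenized over years, and each resulting
line carries an accumulating set of heritable modifications. Two practical
questions dominate day-to-day work and compliance: *which modifications does
this line carry, and where did each come from?* (the GMO question reduces to
"does any of them involve an inserted transgene?"), and *is this material
encumbered by a Material Transfer Agreement signed for some ancestor?*
`seedledger` answers both structurally, from the pedigree, rather than by
asking users to copy annotations forward.

## The model

### Lines, features, and inheritance by reference

A **plant line** is a named genetic context: species, ecotype label, and a
set of **genetic features**. All selfed/backcrossed generations live inside
one line as plants and seed batches; a cross, a secondary mutagenesis or an
import creates a *new* line. Lines therefore form a directed acyclic graph:
parents must already exist when a child is created, and imports sever
parental links, so cycles cannot arise — the suite nevertheless asserts
acyclicity on every generated pedigree.

Each feature is stored exactly once and is *owned* by the line in which it
was created. The **effective** feature set of a line is

$$\mathrm{eff}(L) \;=\; \mathrm{owned}(L)\;\cup\;\bigcup_{P \in \mathrm{parents}(L)} \mathrm{eff}(P)$$

computed by a parent-first depth-first walk with a visited set (linear in
the pedigree even when both sides of a cross share ancestors). Because
inherited features are references, an edit performed on the origin line is
immediately visible in every descendant, and the `"from <origin>"` label in
a descendant's feature table tracks renames of the origin line. Edits
attempted *through* a descendant raise an immutability error — the single
stored copy is the consistency mechanism, not a convention.

Features come in exactly two categories. `TRANSGENESIS` covers T-DNA and
transposon insertions and is rendered GREEN; `ENDOGENOUS` covers point
mutations, deletions and insertions of native loci with no inserted
transgene (EMS, irradiation, natural variants, nuclease-edited loci) and is
rendered BLUE. A line is a GMO precisely when `eff(L)` contains a GREEN
feature. CRISPR/TALEN/ZFN events are modeled as two features on one line —
the machinery T-DNA (green) and the target locus (blue) — which is why the
seeded `CRISPR` mutation method is declared `ENDOGENOUS`: it describes the
edited locus, while the delivery construct is recorded with the `T-DNA`
method.

### MTA propagation

An MTA legally constrains the received material *and all its progeny*
through every amplification, cross and mutagenesis. We operationalize this
transitively: `mta_affected_set(L)` returns the MTA-protected members of
the ancestor closure of `L` (including `L`). The protected flag is a
per-line boolean plus free-text details; details may be non-empty only when
the flag is set, and only the flag survives export.

### Seed-batch identity

Seed batches carry a system-allocated positive integer id drawn from a
counter that is never rewound: ids are strictly increasing across the
database lifetime and deleted ids are never reallocated, so an id printed
on a tube years ago still identifies one batch (or provably none).
User-chosen personal identifiers may repeat freely. This discipline is
tested with randomized create/delete/copy traces checked against a model
allocator.

### Search

Patterns follow the SQL-LIKE-style grammar: `%` matches any run of
characters (including none), `_` exactly one character, and a `$` prefix
escapes both (`$%`, `$_`); a trailing bare `$` is rejected. `$` before any
other character yields that literal character — the grammar names only the
two escapes, and treating other `$` pairs literally is the least surprising
completion. Without any wildcard a pattern matches the whole value exactly
— widening a search is an explicit act of adding `%`, so substring matching
is never the silent default. Matching is case-insensitive throughout, since
lab spellings vary in case; uniqueness of vocabulary values is
case-insensitive for the same reason. Wildcards may appear anywhere in a
pattern, not only at the edges. Criteria from different datasheet sections
combine as AND *at the line level*: a criterion is satisfied by the line's
own value or by at least one of its plants/batches. The alternative —
requiring co-occurrence on the same plant or batch — is stricter and can be
emulated by searching and then inspecting the matching datasheets.

### Interchange and redaction

An export is a single self-contained JSON document (format_version "1",
defined by this package and validated structurally with JSON-pointer error
locations): the line's general information, its *effective* features
flattened to copies whose origin-line name survives as provenance text, the
requested seed batches, any plant referenced as a mother by an exported
batch, all attachments base64-embedded, and the genealogy embedded as
Graphviz DOT text (`genealogy.gv`). Redaction is by allowlist — person
names, notebook references, storage places and MTA details are simply never
emitted — so the "zero leaked strings" property holds by construction and
is still verified by brute-force scans of serialized exports of randomized
fixtures. On import all parental links are severed, every feature becomes
owned by the new line, an unknown ecotype degrades to the reserved
`"(Other)"` sentinel with a warning, and unknown species/methods/strains/
resistances abort with an actionable report unless a mapping is supplied.
Species must resolve against the vocabulary (unlike ecotype) because
intra-species validation of later crosses depends on it.

## Tunable parameters and defaults

| Parameter | Where | Default | Why |
|---|---|---|---|
| `p_cross` | `generate_fixture()` | 0.5 | crosses and secondary mutageneses about equally common in a working collection |
| `p_mta` | `generate_fixture()` | 0.1 | a minority of founder accessions arrive under MTA |
| founders / events | `generate_fixture()` | caller-set | tests use 3–40 founders, 6–160 events; the deepest checks run on a 200-line pedigree |
| genotype states | registry | WT / HETEROZYGOUS / HOMOZYGOUS / UNKNOWN | het/hom are the recorded states; UNKNOWN accommodates imports and ungenotyped material |
| generation labels | registry | free text | labs deliberately skip generations; no workflow is imposed beyond non-emptiness where mandated |

## The synthetic-data generator

`generate_fixture()` emulates a small working registry: five lab members,
two species with their common accessions, founders carrying 0–2 random
features of both categories, a history of intra-species crosses (with
occasional pollen-mutagenesis extra features) and secondary mutageneses,
random MTA protection of founders, and plants/batches with random
generations, genotypes, storage places and notebook references. It is
deterministic for a given seed and restores the caller's RNG state. What it
does **not** emulate: real nomenclature, realistic segregation ratios,
attachment payloads of real size, concurrent multi-user edit patterns, or
the long-tailed pedigree depths of decades-old collections — so green tests
show the bookkeeping is sound, not that the vocabulary defaults or field
sets cover every lab's habits.

## Numerical and design choices

- **Store**: an environment-backed registry persisted as one JSON file per
  laboratory, attachments base64-embedded. The schema is relational in
  shape (typed tables, stable internal ids as foreign keys); a
  client/server backend is a documented extension point behind the same
  operation surface.
- **Vocabulary references by id**: records reference vocabulary entries by
  internal id, so renaming an entry updates every record; usage counting
  scans lines, features, plants and batches and counts each referencing
  record once. Deletion requires a zero count; persons are soft-deactivated
  instead, which hides them from menus for new entries while old records
  keep displaying the name.
- **Self-crosses are refused**: selfed progeny are, by the line concept,
  new plants/batches of the same line, not a new line.
- **Combined ecotype labels** use ASCII `" x "` between the parental labels
  when they differ.
- **Duplicate feature designations** within a line are allowed with a
  warning — nothing forbids two alleles sharing a name, but it is usually a
  typo.
- **Deletion of lines** with descendant lines or seed batches is refused,
  protecting both pedigree integrity and the id no-reuse guarantee.
- **DOT export** is deterministic (nodes in line-creation order), marks
  MTA-protected lines `fillcolor=red`, labels edges with the parental role
  and the seed batch used, and places parents at the bottom via `rankdir`.
  PNG rendering needs an external Graphviz `dot` binary; without one the
  PNG path fails with a degraded-mode error that points to DOT.
- **Authentication** is a salted-hash thin gate for a single-lab trust
  model, not a security boundary; the role lattice is total
  (READER < WRITER < ADMINISTRATOR).

## Problem sizes used by the test suite

The deepest property checks run on: one 200-line pedigree (inheritance
soundness and rename-tracking), 100 seeded 10-line pedigrees (descendant
and MTA oracles), 1,000-operation randomized id traces, and 100 random
wildcard patterns against brute-force scans. All oracles are independent
implementations (recursive matcher, ancestor-closure union, reverse
reachability) living in the test helpers.

## Known limitations

- Segregation is recorded, not simulated: no Mendelian prediction of
  offspring genotypes and no linkage/recombination model.
- The interchange schema is this package's own versioned format; it does
  not read exports of other registry programs.
- Merging two whole databases is out of scope; exchange is per line, with
  rename-on-import as the only conflict handling.
- Attachments are held in memory; very large embedded files will make the
  single-file database correspondingly large.
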