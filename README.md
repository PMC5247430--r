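# seedledger

A seed-stock and plant-line registry for basic-research plant biology
laboratories. Modern labs accumulate hundreds of lines carrying T-DNA
insertions, transposons, CRISPR edits, EMS alleles and their combinations;
tracking which mutation entered which pedigree where — and which material is
legally encumbered — quickly outgrows a spreadsheet. `seedledger` models the
lab's collection as:

- **Plant lines** — one record per genetic context (species, ecotype, set of
  genetic features). Selfed and backcrossed generations stay within a line;
  crosses, secondary mutageneses and imports create new lines with recorded
  parentage.
- **Genetic features** — one mutation or transgene each, in exactly two
  categories: *transgenesis* (T-DNA/transposon insertion; rendered green;
  makes a line a GMO) and *endogenous gene mutagenesis* (sequence change of
  a native locus; rendered blue). A CRISPR event is two features: the
  editing-machinery T-DNA (green) and the edited locus (blue).
- **Inheritance by reference** — a feature is stored once, owned by its
  origin line. A child of a cross carries the *union* of both parents'
  effective feature sets; a mutagenized line inherits everything and owns
  the one new feature. Formally, for a line *L* with parents
  *P₁…Pₖ*:

  > effective(L) = owned(L) ∪ effective(P₁) ∪ … ∪ effective(Pₖ)

  Edits are only possible through the origin line and are instantly visible
  in every descendant; inherited entries are read-only downstream.
- **MTA propagation** — a Material Transfer Agreement constrains the
  protected line and all its progeny; `mta_affected_set()` returns the
  protected ancestors encumbering any line, and genealogy renderings flag
  protected lines in red.
- **Plants and seed batches** — physical material under a line, with
  per-feature genotypes, per-plant transgene insertion sites, segregation
  profiles and attachments. Every seed batch gets a system id that is
  strictly increasing and *never reused*, so the number on a stock tube
  always resolves unambiguously.
- **Search** — SQL-LIKE-style wildcards (`%` any run, `_` one character,
  `$%`/`$_` literals) over line names, genes, feature designations and
  per-section criteria.
- **Interchange** — one line (optionally with seed batches, mother plants
  and attachments) exports to a single JSON document with person names,
  notebook references, storage places and MTA details redacted by
  construction; imports sever parental links and keep provenance as text.

Controlled vocabularies (persons, species, ecotypes, mutation methods,
method references, strains, resistances) and user accounts
(reader/writer/administrator) parameterize everything, with usage counting
and delete-only-when-unused semantics.

## Worked example

```r
library(seedledger)

db <- seed_db()                          # administrator logged in
add_vocab_entry(db, "PERSON", "alice")
add_vocab_entry(db, "SPECIES", "Arabidopsis thaliana")
add_vocab_entry(db, "ECOTYPE", "Col-0", linked_species = "Arabidopsis thaliana")
add_vocab_entry(db, "ECOTYPE", "Ler",   linked_species = "Arabidopsis thaliana")

gus <- create_line(db, "GUS-reporter", "alice", "Arabidopsis thaliana",
                   ecotype = "Col-0")
add_feature(db, "GUS-reporter", "TRANSGENESIS", "Pro35S:GUS",
            mutation_method = "T-DNA")
mut <- create_line(db, "pht-mutant", "alice", "Arabidopsis thaliana",
                   ecotype = "Ler")
add_feature(db, "pht-mutant", "ENDOGENOUS", "pht1;1-1", mutation_method = "EMS")
set_mta(db, "pht-mutant", TRUE, "from X institute, restricted use")

f1 <- cross_lines(db, "GUS-reporter", "pht-mutant")
effective_features(db, f1$id)
#>   feature_id designation     category color origin_line    origin_label inherited
#> 1         F1  Pro35S:GUS TRANSGENESIS GREEN          L1 from GUS-reporter     TRUE
#> 2         F2    pht1;1-1   ENDOGENOUS  BLUE          L2   from pht-mutant     TRUE

is_gmo(db, f1$id)
#> [1] TRUE
mta_affected_set(db, f1$id)       # encumbered by the protected parent
#> [1] "L2"
```

The child of the cross carries both features by reference (one green box —
the line is a GMO — and one blue), each labeled with the line it came from,
and inherits the MTA constraint of the protected parent. `export_tree(db,
f1$id)` emits the genealogy as Graphviz DOT with the protected parent
filled red.

A command-line interface wraps the same operations
(`exec/seedledger init|vocab|line|feature|plant|batch|cross|mutag|tree|search|export|import ...`);
see `?cli_main`.

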