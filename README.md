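# lipidclassr

Structure-based functional-group annotation and ontology classification of
lipids.

## What it does, and for whom

Curated lipid databases assign each molecule to a class by hand.
`lipidclassr` is for cheminformaticians and database curators who want
those assignments to be *computed* from formal class definitions instead:
every lipid class is defined by a logical expression over the functional
groups a molecule contains, and membership is decided by evaluating that
expression against the molecule's structure.  Computed assignments can
then be checked against curated ones — agreements validate the curation,
disagreements localize either a defective definition or a database error.

## The core formalism

A molecule's SMILES is annotated with the set of **unique, non-overlapping
occurrences** of functional groups from a SMARTS pattern library: matches
are found by subgraph isomorphism, deduplicated by atom set, and reduced
per pattern to a maximum pairwise atom-disjoint selection.  The resulting
profile is **closed-world**: it asserts these are *all* the
functional-group parts, mutually distinct — which is what makes exact
cardinalities decidable.

A lipid class is an intersection of existential and qualified-cardinality
restrictions on the *has proper part* relation, in description-logic
notation

    C  ≡  (=1 hasProperPart.PrimaryAcylChain) ⊓ (∃ hasProperPart.Epoxy)
          ⊓ (∃ hasProperPart.CarboxylicAcid) ⊓ (=3 hasProperPart.AlkenylGroup)

written in the package's concrete syntax as

    part exactly 1 Primary_Acyl_Chain and part some Epoxy
    and part some Carboxylic_Acid and part exactly 3 Alkenyl_Group

(the epoxyeicosatrienoic acid class, LIPID MAPS FA0308).  A class
subsumes a molecule's closed description iff its restrictions are
satisfied by the profile; satisfied classes are pruned to the most
specific set under the asserted hierarchy and mapped to LIPID MAPS class
ids and categories.  Ubiquitous substructures (the bare carbon atom,
generic alkyl chains) are reported once as "at least one" witnesses, and
exact cardinalities over them are rejected as undecidable.

Molecules move in and out as Turtle RDF in the SIO vocabulary ('has
attribute' SIO_000008, 'has value' SIO_000300, 'has proper part'
SIO_000053) or as plain SMILES lists; a synthetic eicosanoid generator
provides a ground-truth corpus; and an evaluation module tabulates
exact / partial / mismatch outcomes (with dual classifications tracked
separately) against gold assignments.

## Worked example

The shipped example document `inst/extdata/lmfa03010001.ttl` describes a
prostaglandin by its SMILES attribute:

```r
library(lipidclassr)

lib <- load_pattern_library()
ont <- load_ontology(lib = lib)

rec <- read_molecule_rdf(system.file("extdata", "lmfa03010001.ttl",
                                     package = "lipidclassr"))
profile <- annotate(list(uri = rec$uri, smiles = rec$smiles), lib)
profile
#> <fg_profile> http://semanticscience.org/LMFA03010001
#>   Acyclic_C3_Chain             >= 1
#>   Alcohol                      3
#>   Alkenyl_Group                1
#>   Alkyl_Chain                  >= 1
#>   Carbon_Atom                  >= 1
#>   Carboxylic_Acid              1
#>   Cyclopentane_Ring            1
#>   Ketone                       1
#>   Methyl                       >= 1
#>   Primary_Acyl_Chain           1
#>   Propyl                       >= 1
```

Three hydroxyls on saturated carbons, one alkene, one cyclopentane ring,
one carboxylic acid and one primary acyl chain — the prostanoid
fingerprint.  Classification:

```r
classify(profile, ont, lib)
#> <classification_result> http://semanticscience.org/LMFA03010001
#>   LC_Isoprostane [FA0311, Fatty Acyls]
#>   LC_Prostaglandin [FA0301, Fatty Acyls]
#>   (pruned superclasses: LC_Fatty_Acid )
```

The molecule lands in *two* most-specific classes.  That is correct
behavior, not noise: prostaglandins and isoprostanes differ by synthetic
route, not constitution, so any structure-only classifier must report
both (their definitions are deliberately identical).  The general
fatty-acid class was satisfied too and pruned as an ancestor.

Evaluating a synthetic ground-truth corpus:

```r
corpus <- generate_fixture_set(50, seed = 7, ont = ont, lib = lib)
results <- lapply(seq_len(nrow(corpus)), function(i)
  classify(annotate(list(uri = corpus$uri[i], smiles = corpus$smiles[i]),
                    lib), ont, lib))
tabulate_outcomes(results, corpus, ont)
#> <evaluation_tally> n = 50 molecules
#>   exact       50  (100.0%)
#>   partial      0  (  0.0%)
#>   mismatch     0  (  0.0%)
#>   none         0  (  0.0%)
#>   consistent (exact+partial): 100.0% (62.0% excluding dual)
#>   dual-classified: 19 (38.0%)
```

Every molecule reaches its intended class; the dual fraction is exactly
the prostanoid fixtures, each of which also picks up the
structurally-indistinguishable sibling class.

## Command line

A thin Rscript front end ships at `inst/cli/lipidclassr`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","lipidclassr",package="lipidclassr"))')
Rscript "$CLI" classify --smiles 'CCCCCC1OC1C=CCC=CCC=CCCCCCC(=O)O' \
        --out-format tsv
Rscript "$CLI" fixtures --n 50 --seed 7 --out corpus.tsv
Rscript "$CLI" evaluate --in corpus.tsv --gold corpus.gold.tsv
```

Logs go to stderr, data to stdout or `--out`; per-molecule failures are
logged and skipped without aborting the batch.

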