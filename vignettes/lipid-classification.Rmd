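---
title: "Structure-based lipid classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based lipid classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidclassr)
```

## The problem

Chemical databases classify lipids by expert curation: a person looks at a
structure and files it under, say, *epoxyeicosatrienoic acids*.
`lipidclassr` implements the alternative: lipid classes are given *formal,
structure-based definitions* — logical expressions over the functional
groups a molecule contains — and membership is decided by computation.  A
class definition is an intersection of existential and qualified-cardinality
restrictions on the mereological relation *has proper part*, for example
(the epoxyeicosatrienoic acid class, LIPID MAPS FA0308):

```
part exactly 1 Primary_Acyl_Chain
and part some Epoxy
and part some Carboxylic_Acid
and part exactly 3 Alkenyl_Group
```

Definitions are equivalences — necessary *and* sufficient — so a molecule
whose functional-group inventory satisfies the expression *is* a member,
and a curated assignment that disagrees with the computed one indicates
either a gap in the definition or an error in the curation.  Eicosanoids
(C20 oxygenated fatty-acid derivatives: prostaglandins, isoprostanes,
leukotrienes, epoxy- and hydroxy-eicosatrienoic acids) are the shipped
domain because their classes differ by exactly the kind of feature this
formalism captures well: counts of alkenes, presence of epoxide versus
hydroxyl, a cyclopentane ring.

## Pipeline

1. **Annotation** (`annotate()`): the SMILES is parsed to a molecular
   graph; every SMARTS pattern in the library is matched by subgraph
   isomorphism; matches are deduplicated by atom set ("unique") and, per
   pattern, reduced to a maximum pairwise atom-disjoint selection
   ("non-overlapping"); the result is a *closed-world profile*: the listed
   occurrences are asserted to be all functional-group parts of the
   molecule, mutually distinct.
2. **Classification** (`classify()`): every named class definition is
   checked against the profile; satisfied classes are pruned to the most
   specific set using the asserted class hierarchy, then mapped to LIPID
   MAPS ids and rolled up to categories (FA0301 → FA, Fatty Acyls).
3. **Evaluation** (`tabulate_outcomes()`): predictions are compared with
   gold assignments as *exact* (a most-specific class maps to the gold
   id), *partial* (an asserted ancestor of the gold class — a correct but
   more general classification), *mismatch* (a different terminal class),
   or *none*; molecules carrying a consistent and an inconsistent terminal
   class simultaneously are flagged *dual*, orthogonally to the category.

## Closed-world satisfaction instead of a DL reasoner

The classical way to decide membership is to hand an OWL reasoner the
anonymous class expression describing the molecule — one cardinality
conjunct per functional group, plus closure axioms stating that no other
parts exist and that all part individuals are distinct — and ask whether
the named class subsumes it.  For such *fully specified* individuals,
subsumption reduces to directly evaluating the definition's restrictions
against the profile: `part some C` holds iff at least one occurrence lies
in the subclass closure of `C`, `part exactly n C` iff exactly `n` do.
`satisfies()` implements this evaluation; it is semantically equivalent to
the reasoner call on closed descriptions while removing a heavyweight
dependency.

Two guards back the equivalence claim.  `oracle_satisfies()` is an
independent brute-force implementation that materializes one individual
per occurrence, types it with its group class and all asserted
superclasses, and checks each restriction by set comprehension; the test
suite asserts agreement on hundreds of randomized profile/expression
pairs.  And `export_ontology_owl()` writes the ontology in OWL functional
syntax so any external description-logic reasoner can be used as an
offline cross-check.

A consequence of evaluating conjunctions worth stating explicitly:
satisfaction is *anti-monotone in the definition* — removing a conjunct
weakens a class, so every molecule that satisfied the full definition
still satisfies the reduced one.  Perturbation tests must therefore be
read in the correct direction: deleting the epoxide conjunct from the
FA0308 definition does not stop epoxide-bearing molecules from matching
it; what it destroys is the *discrimination* between FA0308 and the
hydroxy class FA0305, which the regression tests assert.

## Ubiquitous groups and decidability of exact counts

Some substructures (the bare carbon atom, generic alkyl or propyl chains)
occur in overwhelming numbers in lipids.  Counting them is useless — no
class definition needs their cardinality — and expensive.  Classes flagged
`ubiquitous` in the pattern library are therefore reported *at most once*:
the single occurrence is a witness that the count is at least one.  They
may appear under `part some` and `part min`, but `part exactly` over a
filler whose subclass closure contains a ubiquitous class is rejected with
an error, at ontology load and at evaluation: the stored count is only a
lower bound, so equality is undecidable.  This is a hard error rather than
a silent `FALSE` because a definition that asks for it is a modelling
mistake.

## The SMARTS pattern library

The library (`inst/extdata/patterns.yaml`) is an editable YAML file of
group classes (with a subclass hierarchy and the ubiquitous flag) and
SMARTS patterns.  It is a reconstruction sufficient for eicosanoid
classification, about twenty patterns, not a reproduction of any
historical list.  Pattern-design decisions that carry semantics:

* **Alcohol** is `[OX2H1][CX4]`: a hydroxyl on a *saturated* carbon.
  Carboxyl OH (attached to an sp2 carbon) and the terminal OH of a
  hydroperoxide (attached to oxygen) are excluded by the pattern itself,
  not by post-filtering — so an epoxy acid is correctly found *without*
  alcohol, hydroperoxide or peroxide groups despite its carboxyl.
* **Alkenyl_Group** is `C=C` with aliphatic atoms: aromatic bonds never
  count as alkenes, so alkene cardinalities (`exactly 3`) are unaffected
  by aromatic rings.
* **Peroxide** (`[#6][OX2][OX2][#6]`) and **Hydroperoxide**
  (`[OX2H1][OX2][#6]`) are disjoint by construction.
* Non-overlap is enforced **within** each pattern only; occurrences of
  different patterns may share atoms (the carboxyl carbon is also part of
  the acyl chain).  Cross-type exclusions belong in SMARTS design, as with
  Alcohol above.  Whether overlaps should also be filtered across
  patterns is genuinely open; within-pattern filtering is this package's
  documented choice, made because class definitions count each group type
  independently.

The matcher itself supports a documented SMARTS subset: element symbols
(aromatic lowercase), `#n`, `a`/`A`, `X`/`H`/`D` counts, `R`/`R0` ring
membership, charge signs, `!`/`&`/`,`/`;` logic, bonds `- = # : ~`,
branches, and ring closures.  Recursive SMARTS (`$(...)`) and isotopes are
not supported — no shipped pattern needs them.  Matching is
constitution-only: stereo descriptors are parsed and ignored.  SMILES
parsing is delegated to OpenBabel (via ChemmineOB), combining the SDF
serialization (kekulized bond orders, which keep the two carboxyl oxygens
distinguishable) with MOL2 atom types (aromatic perception); both preserve
the input atom order, and occurrences carry 1-based atom indices over that
order, the R convention.  Hydrogen counts are recovered from standard
valences; formal charges are not modelled, so the supported domain is
neutral organic molecules — which lipid structures are.

## Unique and non-overlapping occurrences

Symmetric (automorphic) embeddings of a pattern hit the same atoms and are
collapsed by atom-set identity.  The non-overlap rule then asks for a
*maximum* set of pairwise atom-disjoint matches — a maximum independent
set of the overlap graph.  For up to 20 matches `select_disjoint()` solves
this exactly by branch-and-bound over the canonically ordered match list
(include-before-exclude depth-first search, so the first solution of any
size is the lexicographically smallest and ties are broken
deterministically); beyond 20 a greedy pass in ascending sorted-atom-index
order is used.  The threshold is a cost bound: 2^20 worst-case nodes is
still fast, and in practice eicosanoid-scale molecules produce far fewer
matches per pattern.  The test suite checks the selection against an
exhaustive enumeration oracle on all match sets of size ≤ 12.

## The eicosanoid ontology fixture

`inst/extdata/leo.yaml` ships seven classes.  The FA0305
(hydroxy/hydroperoxy-eicosatrienoic) and FA0308 (epoxy-eicosatrienoic)
definitions follow the published equivalence expressions for those LIPID
MAPS classes.  The others are fixture reconstructions authored from the
informal LIPID MAPS descriptions:

* `LC_Fatty_Acid` (root): an alkyl or primary acyl chain, a carboxylic
  acid derivative, and an acyclic three-carbon chain.
* `LC_Prostaglandin` (FA0301) and `LC_Isoprostane` (FA0311) carry
  **identical** structural restrictions (one cyclopentane ring, one
  primary acyl chain, a carboxylic acid, a hydroxyl).  This is deliberate:
  the two classes differ by synthetic route — enzymatic versus radical —
  which no structure-only classifier can see, so a prostaglandin input is
  *dually* classified into both.  Dual classification is a reported
  diagnostic feature, never an error.
* `LC_Leukotriene` (FA0302): four alkenes, hydroxyl, acyl chain, acid.
* `LC_Eicosanoid` is an asserted-only node (no definition): it is never
  returned as satisfied but anchors the hierarchy for pruning and for
  partial-match evaluation.

Pruning uses the **asserted** hierarchy, not definitional entailment
between class expressions: a satisfied class is dropped iff it is an
asserted strict ancestor of another satisfied class.  Inferred
class-to-class subsumption could in principle re-rank "most specific";
asserted-only pruning avoids TBox reasoning and matches how stored
hierarchies behave, and is this package's documented choice.  Category
roll-up uses the LIPID MAPS prefix convention (first two letters of the
class id) rather than a lookup table — deterministic and offline.

## The synthetic corpus

`generate_fixture_set()` emulates a curated eicosanoid sample: C20-style
scaffolds — linear chains or a cyclopentane core — decorated with
controlled counts of alkenes (isolated by a methylene so occurrences never
overlap), hydroxyls, hydroperoxides, epoxides, and exactly one carboxylic
acid, each built so its intended terminal class is known by construction.
Prostanoid fixtures carry one or two alkenes — real prostaglandins vary
more widely, but keeping the count away from three and four prevents
accidental overlap with the trienoic and leukotriene definitions, which is
what makes the ground truth exact.  Template parameters (tail lengths,
second ring hydroxyl, chain hydroxyl versus hydroperoxide) are drawn from
a small deterministic linear-congruential generator seeded by the caller,
so a corpus is bit-reproducible and independent of R's global RNG state.

What the generator does **not** emulate: stereochemistry (all fixtures are
flat), protonation states and salts, ring ketones and lactones,
conjugated polyene systems, the long tail of rare decorations in real
LIPID MAPS records, and curation noise.  Tests passing on this corpus
therefore demonstrate that the pipeline implements its own semantics
correctly and recovers constructed ground truth; they do not measure
accuracy on real curated data.  For that, `cmd_evaluate()` accepts any
user-supplied SMILES list plus gold TSV and runs the same tabulation.

Problem sizes used by the checked-in tests and the acceptance script —
a 50–60 molecule corpus, 250 randomized oracle pairs, exhaustive
independent-set checks up to 12 matches — were chosen as comfortably
sufficient for the properties being asserted while keeping the suite
quick to run.

## Degenerate inputs and numerical corners

* Unparsable SMILES raise an error carrying the offending string; in batch
  commands the error is logged, the molecule skipped, and the exit status
  reflects the failure without aborting the batch.
* Dot-separated (multi-fragment) SMILES are annotated as a single entity.
* An empty pattern library or empty ontology is valid and yields empty
  profiles or no classifications, not errors.
* The empty profile's molecule expression is the closure-only conjunction.
* `part min 0 C` is vacuously true.
* All emitted RDF IRIs come from one vocabulary table (`leo_vocab()`);
  Turtle output is deterministic (sorted prefixes, canonical occurrence
  order), so repeated runs are byte-identical.  The reader accepts the
  `sios:` prefix misprint found in circulating example documents and
  treats it as `sio:`.

## Known limitations

* The SMARTS subset has no recursive patterns; exclusion logic must be
  expressed with the supported primitives.
* Aromaticity follows OpenBabel's perception; exotic aromatic systems may
  be perceived differently by other toolkits.
* Formal charges are ignored (neutral-molecule domain).
* Classification is structure-only by design: classes that differ by
  non-structural information (prostaglandin versus isoprostane) are
  reported dually, and resolving them needs annotations outside the scope
  of this package.
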