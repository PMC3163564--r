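# Functional-group pattern library for eicosanoid annotation.
#
# This is a reconstructed library: it covers the functional groups needed to
# classify eicosanoid-type fatty acyls (alkenes, hydroxyls, hydroperoxides,
# peroxides, epoxides, carboxyl features, acyl chains, the cyclopentane
# ring), not any particular historical pattern list.
#
# Record syntax:
#   classes:  name, parents (list of class names), ubiquitous (bool)
#   patterns: id, smarts (see vignette for the supported subset), class
#
# Design notes on individual patterns:
#  * alcohol: hydroxyl on a saturated (sp3) carbon only.  Carboxyl and
#    hydroperoxide hydroxyls are excluded structurally (their O binds an sp2
#    carbon or another oxygen), so no post-filtering is needed.
#  * alkenyl: non-aromatic C=C only; aromatic bonds never count as alkenes.
#  * ubiquitous classes (carbon atom, alkyl/propyl/C3 chains, methyl) occur
#    in overwhelming numbers in lipids; they are reported at most once and
#    carry only an "at least one" witness.

classes:
  - name: Carbon_Atom
    parents: []
    ubiquitous: true
  - name: Alkyl_Chain
    parents: []
    ubiquitous: true
  - name: Propyl
    parents: []
    ubiquitous: true
  - name: Acyclic_C3_Chain
    parents: []
    ubiquitous: true
  - name: Methyl
    parents: []
    ubiquitous: true
  - name: Hydroxy_Compound
    parents: []
    ubiquitous: false
  - name: Alcohol
    parents: [Hydroxy_Compound]
    ubiquitous: false
  - name: Hydroperoxide
    parents: []
    ubiquitous: false
  - name: Peroxide
    parents: []
    ubiquitous: false
  - name: Epoxy
    parents: []
    ubiquitous: false
  - name: Carboxylic_Acid_Derivative
    parents: []
    ubiquitous: false
  - name: Carboxylic_Acid
    parents: [Carboxylic_Acid_Derivative]
    ubiquitous: false
  - name: Ester
    parents: [Carboxylic_Acid_Derivative]
    ubiquitous: false
  - name: Amide
    parents: [Carboxylic_Acid_Derivative]
    ubiquitous: false
  - name: Ketone
    parents: []
    ubiquitous: false
  - name: Aldehyde
    parents: []
    ubiquitous: false
  - name: Primary_Acyl_Chain
    parents: []
    ubiquitous: false
  - name: Alkenyl_Group
    parents: []
    ubiquitous: false
  - name: Cyclopentane_Ring
    parents: []
    ubiquitous: false
  - name: Aromatic_Ring
    parents: []
    ubiquitous: false

patterns:
  - id: acyclic_c3_chain
    smarts: "[C;!R][C;!R][C;!R]"
    class: Acyclic_C3_Chain
  - id: alcohol
    smarts: "[OX2H1][CX4]"
    class: Alcohol
  - id: aldehyde
    smarts: "[CX3H1](=O)[#6]"
    class: Aldehyde
  - id: alkenyl
    smarts: "C=C"
    class: Alkenyl_Group
  - id: alkyl_chain
    smarts: "[CX4][CX4][CX4][CX4]"
    class: Alkyl_Chain
  - id: amide
    smarts: "[NX3][CX3]=O"
    class: Amide
  - id: aromatic_ring
    smarts: "c1ccccc1"
    class: Aromatic_Ring
  - id: carbon_atom
    smarts: "[#6]"
    class: Carbon_Atom
  - id: carboxylic_acid
    smarts: "[CX3](=O)[OX2H1]"
    class: Carboxylic_Acid
  - id: cyclopentane_ring
    smarts: "C1CCCC1"
    class: Cyclopentane_Ring
  - id: epoxide
    smarts: "[CX4]1[OX2][CX4]1"
    class: Epoxy
  - id: ester
    smarts: "[CX3](=O)[OX2][#6]"
    class: Ester
  - id: hydroperoxide
    smarts: "[OX2H1][OX2][#6]"
    class: Hydroperoxide
  - id: ketone
    smarts: "[#6][CX3](=O)[#6]"
    class: Ketone
  - id: methyl
    smarts: "[CX4H3]"
    class: Methyl
  - id: peroxide
    smarts: "[#6][OX2][OX2][#6]"
    class: Peroxide
  - id: primary_acyl_chain
    smarts: "[CX4][CX4][CX3](=O)[OX2]"
    class: Primary_Acyl_Chain
  - id: propyl
    smarts: "[CX4H3][CX4][CX4]"
    class: Propyl
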