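# Eicosanoid lipid class ontology fixture.
#
# Each class carries a definitional expression (necessary AND sufficient)
# over functional-group parthood, an asserted parent, and a LIPID MAPS class
# id where one applies.  The FA0305 and FA0308 definitions follow the
# published LEO equivalence expressions for those LIPID MAPS classes; the
# remaining definitions are fixture reconstructions authored from the
# informal LIPID MAPS class descriptions.
#
# LC_Prostaglandin and LC_Isoprostane are deliberately given identical
# structural restrictions: the two classes differ by synthetic route (a
# non-structural property), so any structure-only classifier must assign
# both.  LC_Eicosanoid is an asserted-only hierarchy node (no definition):
# it is never returned as satisfied but participates in pruning and in
# partial-match evaluation.

classes:
  - name: LC_Fatty_Acid
    parent: ~
    lm_id: ~
    definition: >-
      part some (Alkyl_Chain or Primary_Acyl_Chain)
      and part some Carboxylic_Acid_Derivative
      and part some Acyclic_C3_Chain

  - name: LC_Eicosanoid
    parent: LC_Fatty_Acid
    lm_id: FA03

  - name: LC_Prostaglandin
    parent: LC_Eicosanoid
    lm_id: FA0301
    definition: >-
      part exactly 1 Cyclopentane_Ring
      and part exactly 1 Primary_Acyl_Chain
      and part some Carboxylic_Acid
      and part some Alcohol

  - name: LC_Isoprostane
    parent: LC_Eicosanoid
    lm_id: FA0311
    definition: >-
      part exactly 1 Cyclopentane_Ring
      and part exactly 1 Primary_Acyl_Chain
      and part some Carboxylic_Acid
      and part some Alcohol

  - name: LC_Leukotriene
    parent: LC_Eicosanoid
    lm_id: FA0302
    definition: >-
      part exactly 1 Primary_Acyl_Chain
      and part some Carboxylic_Acid
      and part some Hydroxy_Compound
      and part exactly 4 Alkenyl_Group

  - name: LC_Hydroxyeicosatrienoic_Acid
    parent: LC_Eicosanoid
    lm_id: FA0305
    definition: >-
      part exactly 1 Primary_Acyl_Chain
      and part some Carboxylic_Acid
      and part some (Alcohol or Hydroperoxide or Peroxide)
      and part exactly 3 Alkenyl_Group

  - name: LC_Epoxyeicosatrienoic_Acid
    parent: LC_Eicosanoid
    lm_id: FA0308
    definition: >-
      part exactly 1 Primary_Acyl_Chain
      and part some Epoxy
      and part some Carboxylic_Acid
      and part exactly 3 Alkenyl_Group

lm_categories:
  FA: Fatty Acyls
  GL: Glycerolipids
  GP: Glycerophospholipids
  SP: Sphingolipids
  ST: Sterol Lipids
  PR: Prenol Lipids
  SL: Saccharolipids
  PK: Polyketides
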