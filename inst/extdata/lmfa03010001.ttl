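# Example molecule input: a prostaglandin (LIPID MAPS LMFA03010001,
# prostaglandin F2alpha 11-epimer family member) described by its SMILES
# attribute in the SIO vocabulary.
@prefix ss: <http://semanticscience.org/> .
@prefix sio: <http://semanticscience.org/resource/> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .

ss:LMFA03010001 sio:SIO_000008 ss:LMFA03010001smiles .

ss:LMFA03010001smiles
    rdf:type sio:CHEMINF_000018 ;
    sio:SIO_000300 "CCCCC[C@H](O)/C=C/[C@H]1[C@H](O)C[C@H](O)[C@@H]1CC(=O)CCCCC(=O)O" .
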