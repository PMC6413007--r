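# Substituent lists for the dioxopiperazine FPR library, transcribed
# verbatim from the printed substitution table (one-letter codes per anchor
# position). Fragment SMILES are kept exactly as printed even where they
# disagree with the printed name (e.g. "propyl" = CC[R], "isobutyl" =
# CC(C)[R]); such mismatches are deliberate and flagged here, not silently
# fixed. The `repairs` block overrides the two fragments that are
# structurally unusable as printed; each repair records the printed form,
# the chosen reading and any alternative.
#
# Note: as printed, the R3 list repeats three fragments (butyl at C and F,
# propyl at D and I, benzyl at A and H), so enumerated molecules differing
# only in those codes are chemically identical.
anchors: [R1, R2, R3, R4]
substituents:
  R1:
    - {code: "A", name: 2-naphthylmethyl, smiles: "[R]C1=CC2=CC=CC=C2C=C1"}
    - {code: "B", name: propyl, smiles: "CC[R]"}
    - {code: "C", name: isopropyl, smiles: "[R](C)(C)"}
    - {code: "D", name: butyl, smiles: "[R]CCC"}
    - {code: "E", name: benzyl, smiles: "[R]C1=CC=CC=C1"}
  R2:
    - {code: "A", name: 4-hydroxybenzyl, smiles: "OC1=CC=C(C=C1)[R]"}
    - {code: "B", name: 2-naphthylmethyl, smiles: "[R]C1=CC2=CC=CC=C2C=C1"}
    - {code: "C", name: cyclohexyl, smiles: "C1CCCCC1[R]"}
    - {code: "D", name: propyl, smiles: "CC[R]"}
    - {code: "E", name: hydroxymethyl, smiles: "O[R]"}
    - {code: "F", name: butyl, smiles: "[R]CCC"}
    - {code: "G", name: benzyl, smiles: "[R]C1=CC=CC=C1"}
    - {code: "H", name: isobutyl, smiles: "CC(C)[R]"}
  R3:
    - {code: "A", name: benzyl, smiles: "[R]C1=CC=CC=C1"}
    - {code: "B", name: 4-hydroxybenzyl, smiles: "OC1=CC=C(C=C1)[R]"}
    - {code: "C", name: butyl, smiles: "[R]CCC"}
    - {code: "D", name: propyl, smiles: "CC[R]"}
    - {code: "E", name: S-phenyl, smiles: "[R]1=CC=CC=C1"}
    - {code: "F", name: butyl, smiles: "[R]CCC"}
    - {code: "G", name: cyclohexyl, smiles: "C1CCCCC1[R]"}
    - {code: "H", name: benzyl, smiles: "[R]C1=CC=CC=C1"}
    - {code: "I", name: propyl, smiles: "CC[R]"}
  R4:
    - {code: "A", name: 4-methyl-1-cyclohexyl-methyl, smiles: "[R]C1CCC(C)CC1"}
    - {code: "B", name: cyclohexylpropyl, smiles: "[R]CCC1CCCCC1"}
    - {code: "C", name: cyclohexylmethyl, smiles: "[R]C1CCCCC1"}
    - {code: "D", name: cyclopentylmethyl, smiles: "[R]C1CCCC1"}
    - {code: "E", name: cycloheptylmethyl, smiles: "[R]C1CCCCCC1"}
    - {code: "F", name: cyclobutylmethyl, smiles: "[R]C1CCC1"}
    - {code: "G", name: 3-methylpentyl, smiles: "[R]CC(C)CC"}
    - {code: "H", name: 2-biphenyl-4-yl-ethyl, smiles: "[R]CC(C=C1)=CC=C1C2=CC=CC=C2"}
    - {code: "I", name: 4-tert-butyl-cyclohexylmethyl, smiles: "[R]C1CCC(C(C)(C)C)CC1"}
    - {code: "J", name: 2-(3-methoxyphenyl)-ethyl, smiles: "[R]CC1=CC(OC)=CC=C1"}
    - {code: "K", name: 2-(4-isobutylphenyl)-propyl, smiles: "[R]C(C1=CC=C(CC(C)C)C=C1)C"}
    - {code: "L", name: m-tolylethyl, smiles: "[R]CC1=CC(C)=CC=C1"}
    - {code: "M", name: p-tolylethyl, smiles: "[R]CC1=CC=C(C)C=C1"}
    - {code: "N", name: 2-(4-methoxyphenyl)-ethyl, smiles: "[R]CC1=CC=C(OC)C=C1"}
    - {code: "O", name: 2-(4-ethoxyphenyl)-ethyl, smiles: "[R]CC1=CC=C(OCC)C=C1"}
    - {code: "P", name: phenethyl, smiles: "[R]CC1=CC=CC=C1"}
    - {code: "Q", name: 3-(3,4-dimethoxyphenyl)-propyl, smiles: "[R]CCC1=CC=C(OC)C(OC)=C1"}
repairs:
  - anchor: R3
    code: "E"
    printed: "[R]1=CC=CC=C1"
    smiles: "[R]SC1=CC=CC=C1"
    reason: >
      Printed fragment is syntactically unusable (the ring-closure digit sits
      on the anchor marker). The name "S-phenyl" points to phenylthio, which
      also keeps the R3 list free of a third benzyl; the phenyl reading is
      recorded as the alternative. Affects the 680 molecules with R3=E.
    alternatives: ["[R]C1=CC=CC=C1"]
  - anchor: R1
    code: "C"
    printed: "[R](C)(C)"
    smiles: "[R]C(C)C"
    reason: >
      As printed the anchor marker carries two bonds; under the
      marker-contributes-no-atom convention the attachment point must be a
      terminal marker. The isopropyl reading (attachment CH bearing two
      methyls) matches the printed name.
    alternatives: []
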