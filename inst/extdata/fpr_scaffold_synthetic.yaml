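# SYNTHETIC scaffold transcription. The base structure of the
# dioxopiperazine FPR library is published only as a drawing; this file
# records the package's chemically coherent transcription of that drawing as
# SMILES: a pyrrolidine bis-diketopiperazine — two 2,5-dioxopiperazine rings
# bridged through a 2-(aminomethyl)pyrrolidine, with R1/R2/R3 on
# diketopiperazine alpha-carbons and R4 on a ring nitrogen. Screening counts
# computed from this scaffold therefore depend on the transcription, not
# only on the printed substituent lists; see the methods vignette.
scaffold:
  smiles: "O=C1NC([R1])C(=O)N(C1[R2])CC2CCCN2CC3N([R4])C(=O)C([R3])NC3=O"
  anchors: [R1, R2, R3, R4]
  provenance: synthetic transcription of the published drawing
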