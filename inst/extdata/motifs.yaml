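# MHC class I anchor-residue motifs, keyed by allele name.
# anchors: 1-based peptide position -> allowed residues
"Mafa-A1*063":
  anchors:
    "1": ["S"]
    "2": ["P"]
    "3": ["N"]
  cterm: ["W"]
  length_range: [8, 11]
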