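# GO term groups tagging network nodes with processes relevant to the
# source-kinase dataset, and the phospho-tyrosine-modifier terms.
categories:
  adhesion-motility:
    - GO:0048870   # cell motility
    - GO:0007155   # cell adhesion
    - GO:0034330   # cell junction organization
    - GO:0022610   # biological adhesion
    - GO:0060352   # cell adhesion molecule production
    - GO:0030030   # cell projection organization
  growth-death:
    - GO:0008283   # cell population proliferation
    - GO:0007049   # cell cycle
    - GO:0008219   # cell death
    - GO:0019835   # cytolysis
    - GO:0000920   # septum digestion after cytokinesis
    - GO:0007569   # cell aging
    - GO:0051301   # cell division
    - GO:0060242   # contact inhibition
  immunity-inflammation:
    - GO:0002376   # immune system process
    - GO:0001906   # cell killing
  differentiation:
    - GO:0030154   # cell differentiation
    - GO:0036166   # phenotypic switching
modifier_terms:
  - GO:0004713   # protein tyrosine kinase activity
  - GO:0004725   # protein tyrosine phosphatase activity
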