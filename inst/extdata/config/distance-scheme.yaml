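# The six edge-distance levels, editable. dp_tags lists the evidence
# classes counting as site-level differential phosphorylation for the
# demotion rules.
levels:
  promoted_both: 1            # identified modifier source -> identified target
  modifier_source: 2          # modifier source -> identified target
  identified_source: 3        # edge out of an identified protein
  normal: 5
  demoted_identified_source: 6   # identified non-modifier source -> diff-phospho target
  demoted: 8                  # unidentified non-modifier source -> diff-phospho target
dp_tags:
  - site-level
  - direct-substrate
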