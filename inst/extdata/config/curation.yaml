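# Reference curation lists for direct-substrate selection.
# Proteins excluded because their in-vitro phosphopeptides were not retrieved
# exclusively in the Syk-expressing cellular condition.
exclude_proteins:
  - Q14192   # FHL2
  - Q06124   # PTPN11
  - P18031   # PTPN1
  - Q14247   # cortactin
  - P08670   # vimentin
  - Q05209   # PTPN12
# Per-peptide exclusion: the protein stays a substrate if another of its
# peptides matches (MAP1B case).
exclude_peptides:
  - protein_id: P46821   # MAP1B
    sequence: ITSFPESEGYSyETSTK
# Forced inclusions backed by a cellular-exclusive phosphopeptide.
include_proteins:
  - P23528   # cofilin-1
  - Q9Y281   # cofilin-2
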