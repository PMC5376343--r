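# Mapping of database relation vocabularies to the three interaction type
# labels (phosphorylation / modification / regulation, plus other) and a
# sign. Unlisted relations fall back to {type: other, sign: unknown}.
kgml:
  activation: {type: regulation, sign: positive}
  inhibition: {type: regulation, sign: negative}
  expression: {type: regulation, sign: positive}
  repression: {type: regulation, sign: negative}
  phosphorylation: {type: phosphorylation, sign: unknown}
  dephosphorylation: {type: phosphorylation, sign: negative}
  ubiquitination: {type: modification, sign: unknown}
  glycosylation: {type: modification, sign: unknown}
  methylation: {type: modification, sign: unknown}
  "binding/association": {type: other, sign: unknown}
  dissociation: {type: other, sign: unknown}
  "indirect effect": {type: regulation, sign: unknown}
  "state change": {type: other, sign: unknown}
sif:
  controls-phosphorylation-of: {type: phosphorylation, sign: unknown}
  phosphorylates: {type: phosphorylation, sign: positive}
  dephosphorylates: {type: phosphorylation, sign: negative}
  controls-state-change-of: {type: modification, sign: unknown}
  controls-expression-of: {type: regulation, sign: unknown}
  controls-transport-of: {type: other, sign: unknown}
  activates: {type: regulation, sign: positive}
  inhibits: {type: regulation, sign: negative}
  catalysis-precedes: {type: other, sign: unknown}
  in-complex-with: {type: other, sign: unknown}
  interacts-with: {type: other, sign: unknown}
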