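# Conventional main-lineage gate hierarchy on the transformed scale.
cofactor: 3000
default_threshold: 1.65
rules:
  - lineage: gdT
    all_of: {CD3: high, TCRgd: high}
  - lineage: CD4T
    all_of: {CD3: high, CD4: high, CD8: low}
  - lineage: CD8T
    all_of: {CD3: high, CD8: high, CD4: low}
  - lineage: B
    all_of: {CD3: low, CD19: high}
  - lineage: NK
    all_of: {CD3: low, CD19: low, CD56: high}
  - lineage: ILC
    all_of: {CD3: low, CD19: low, CD56: low, CD127: high}
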