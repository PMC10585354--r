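# Candidate haematopoietic model: dedicated NK branch.
# Lymphoid T/B cells and NK cells develop through different branches: T and
# B from the common lymphoid progenitor, NK from a dedicated NK progenitor.
nodes:
  - {name: HSC, observed: false, branch: none,     ancestor: null}
  - {name: MPP, observed: false, branch: none,     ancestor: HSC}
  - {name: CMP, observed: false, branch: myeloid,  ancestor: MPP}
  - {name: CLP, observed: false, branch: lymphoid, ancestor: MPP}
  - {name: NKP, observed: false, branch: lymphoid, ancestor: MPP}
  - {name: MEP, observed: false, branch: myeloid,  ancestor: CMP}
  - {name: GMP, observed: false, branch: myeloid,  ancestor: CMP}
  - {name: T,   observed: true,  branch: lymphoid, ancestor: CLP}
  - {name: B,   observed: true,  branch: lymphoid, ancestor: CLP}
  - {name: NK,  observed: true,  branch: lymphoid, ancestor: NKP}
  - {name: G,   observed: true,  branch: myeloid,  ancestor: GMP}
  - {name: M,   observed: true,  branch: myeloid,  ancestor: GMP}
  - {name: P,   observed: true,  branch: myeloid,  ancestor: MEP}
  - {name: ERY, observed: true,  branch: myeloid,  ancestor: MEP}
edges:
  - [HSC, MPP]
  - [MPP, CMP]
  - [MPP, CLP]
  - [MPP, NKP]
  - [CMP, MEP]
  - [CMP, GMP]
  - [MEP, P]
  - [MEP, ERY]
  - [GMP, G]
  - [GMP, M]
  - [CLP, T]
  - [CLP, B]
  - [NKP, NK]
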