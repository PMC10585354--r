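# In-silico scalability net: the dichotomic haematopoietic tree with the
# HSC and every progenitor (MPP, CMP, CLP, MEP, GMP) unobserved; only the
# seven mature lineages produce data.
nodes:
  - {name: HSC, observed: false, branch: none,     ancestor: null}
  - {name: MPP, observed: false, branch: none,     ancestor: HSC}
  - {name: CMP, observed: false, branch: myeloid,  ancestor: MPP}
  - {name: CLP, observed: false, branch: lymphoid, ancestor: MPP}
  - {name: MEP, observed: false, branch: myeloid,  ancestor: CMP}
  - {name: GMP, observed: false, branch: myeloid,  ancestor: CMP}
  - {name: T,   observed: true,  branch: lymphoid, ancestor: CLP}
  - {name: B,   observed: true,  branch: lymphoid, ancestor: CLP}
  - {name: NK,  observed: true,  branch: lymphoid, ancestor: CLP}
  - {name: G,   observed: true,  branch: myeloid,  ancestor: GMP}
  - {name: M,   observed: true,  branch: myeloid,  ancestor: GMP}
  - {name: P,   observed: true,  branch: myeloid,  ancestor: MEP}
  - {name: ERY, observed: true,  branch: myeloid,  ancestor: MEP}
edges:
  - [HSC, MPP]
  - [MPP, CMP]
  - [MPP, CLP]
  - [CMP, MEP]
  - [CMP, GMP]
  - [MEP, P]
  - [MEP, ERY]
  - [GMP, G]
  - [GMP, M]
  - [CLP, T]
  - [CLP, B]
  - [CLP, NK]
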