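# In-silico validation net: myeloid-biased two-branch tree (the myeloid
# progenitor also produces NK cells). Structurally distinct counterpart of
# insilico-branching for misspecification experiments; this exact topology
# is a package choice.
nodes:
  - {name: HSC, observed: false, branch: none,     ancestor: null}
  - {name: P1,  observed: false, branch: none,     ancestor: HSC}
  - {name: P2,  observed: false, branch: myeloid,  ancestor: P1}
  - {name: P3,  observed: false, branch: lymphoid, ancestor: P1}
  - {name: G,   observed: true,  branch: myeloid,  ancestor: P2}
  - {name: M,   observed: true,  branch: myeloid,  ancestor: P2}
  - {name: NK,  observed: true,  branch: lymphoid, ancestor: P2}
  - {name: T,   observed: true,  branch: lymphoid, ancestor: P3}
  - {name: B,   observed: true,  branch: lymphoid, ancestor: P3}
edges:
  - [HSC, P1]
  - [P1, P2]
  - [P1, P3]
  - [P2, G]
  - [P2, M]
  - [P2, NK]
  - [P3, T]
  - [P3, B]
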