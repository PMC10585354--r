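# Candidate haematopoietic model: single-branch developmental tree.
# HSC feed a single multipotent progenitor whose common myeloid-lymphoid
# progenitor produces the mature lymphoid cells directly and the
# erythroid/myeloid cells through MEP and GMP.
nodes:
  - {name: HSC,  observed: false, branch: none,     ancestor: null}
  - {name: MPP,  observed: false, branch: none,     ancestor: HSC}
  - {name: CMLP, observed: false, branch: none,     ancestor: MPP}
  - {name: MEP,  observed: false, branch: myeloid,  ancestor: CMLP}
  - {name: GMP,  observed: false, branch: myeloid,  ancestor: CMLP}
  - {name: T,    observed: true,  branch: lymphoid, ancestor: CMLP}
  - {name: B,    observed: true,  branch: lymphoid, ancestor: CMLP}
  - {name: NK,   observed: true,  branch: lymphoid, ancestor: CMLP}
  - {name: G,    observed: true,  branch: myeloid,  ancestor: GMP}
  - {name: M,    observed: true,  branch: myeloid,  ancestor: GMP}
  - {name: P,    observed: true,  branch: myeloid,  ancestor: MEP}
  - {name: ERY,  observed: true,  branch: myeloid,  ancestor: MEP}
edges:
  - [HSC, MPP]
  - [MPP, CMLP]
  - [CMLP, T]
  - [CMLP, B]
  - [CMLP, NK]
  - [CMLP, MEP]
  - [CMLP, GMP]
  - [MEP, P]
  - [MEP, ERY]
  - [GMP, G]
  - [GMP, M]
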