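# In-silico validation net: small single-branch chain HSC -> P1 -> P2
# feeding three mature lineages. All nodes are observed by default; hide
# the progenitors per study with observed_override (or an edited copy).
nodes:
  - {name: HSC, observed: true, branch: none,     ancestor: null}
  - {name: P1,  observed: true, branch: none,     ancestor: HSC}
  - {name: P2,  observed: true, branch: none,     ancestor: P1}
  - {name: T,   observed: true, branch: lymphoid, ancestor: P2}
  - {name: B,   observed: true, branch: lymphoid, ancestor: P2}
  - {name: G,   observed: true, branch: myeloid,  ancestor: P2}
edges:
  - [HSC, P1]
  - [P1, P2]
  - [P2, T]
  - [P2, B]
  - [P2, G]
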