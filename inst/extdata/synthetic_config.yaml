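# Self-contained synthetic fixture: a 300-node scale-free network with
# hub-biased planted sets and ~500 simulated tumor samples.
seed: 1
outdir: oncotopo_run
stages: [simulate, mutations, topology, proximity, steiner]
simulate:
  n_nodes: 300
  model: preferential-attachment
  pa_m: 3
  set_specs:
    - {name: TSG, size: 30, alpha: 2.0, rate: 0.05}
    - {name: OCG, size: 30, alpha: 1.0, rate: 0.01}
    - {name: Target, size: 40, alpha: 0.5, rate: 0.005}
    - {name: Essential, size: 40, alpha: 0.5, rate: 0.002}
  background_rate: 0.002
options:
  merge_coadread: false
  nonsilent_only: false
  normalized_betweenness: false
  strict_terminal_overlap: true
  max_distance: 8
steiner:
  terminal_a: TSG
  terminal_b: OCG
proximity:
  source: Target
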