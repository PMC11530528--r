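# Synthetic multi-scale world for `muse simulate` (see ?synthetic_spec).
n_entities: 120
n_links: 550
graph_size: [12, 20]
rho_struct: 0.75
rho_net: 0.9
hidden_fraction: 0.3
seed: 42
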