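# Flat training configuration for `muse train` (see ?read_config_file).
em.alpha: 0.5
em.beta: 0.5
em.pseudo_threshold_t: 0.3
em.max_iterations: 6
em.epochs_per_step: 40
encoder.hidden: 32
network.hidden: 32
seed: 1
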