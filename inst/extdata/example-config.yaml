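# Example pipeline configuration: closed-form R1 ring, full-model NMA.
design: r1c
method: nma
modes: 16
cutoff: 0.8
n_label: 10
seed: 1
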