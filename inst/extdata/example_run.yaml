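# Example run configuration: production setup 6 (neutralized CTD, 50-bp
# DNA, 10-bp spacer, 300 A sphere) with a short trajectory.
preset: 6
steps: 100000
stride: 1000
seed: 7
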