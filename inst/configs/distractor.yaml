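# cue followed by an equal-strength distractor four seconds later
name: distractor
connectome:
  synthetic: {n_areas: 30, seed: 1}
mode: strongly-distributed
protocol: {type: distractor, distractor_amplitude: 0.3, gap: 4}
numerics: {duration: 10, dt: 0.0005, seed: 1}
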