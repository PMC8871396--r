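# reduced attractor census at moderate coupling
name: census
connectome:
  synthetic: {n_areas: 30, seed: 1}
mode: custom
gradient: {J_max: 0.5}
G: 0.25
protocol: {type: census, n_samples: 500, relax_time: 10}
numerics: {seed: 1}
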