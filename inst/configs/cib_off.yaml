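# same trial without the counterstream inhibitory bias (cib_scale = 0)
name: cib_off
connectome:
  synthetic: {n_areas: 30, seed: 1}
mode: distributed
cib_scale: 0
protocol:
  type: simulate
  events:
  - {area: V1, population: A, onset: 1, duration: 0.5, amplitude: 0.3}
numerics: {duration: 10, dt: 0.0005, seed: 1}
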