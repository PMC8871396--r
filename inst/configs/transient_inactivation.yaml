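# brief inactivation of a memory-holding area in the strongly distributed net
name: transient_inactivation
connectome:
  synthetic: {n_areas: 30, seed: 1}
mode: strongly-distributed
protocol:
  type: simulate
  events:
  - {area: V1, population: A, onset: 1, duration: 0.5, amplitude: 0.3}
  silencing: {areas: ['9/46d'], start: 4, end: 5}
numerics: {duration: 12, dt: 0.0005, seed: 1}
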