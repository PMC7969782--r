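# Concurrent vascularisation of a unit disc from two opposite equiradial
# inlets: a short sprouting stage balances the inlets, then a volumetric
# stage fills the domain efficiently.
stages:
  - label: 1
    domain: {shape: disc, center: [0, 0], radius: 1}
    geo: {gamma: 3, delta: 0}
    opt: {nu: 1.0, f_r: 0.9, f_n: 8, delta_v: 7}
    budget: 25
    cost: {name: sprout, c_v: 50, c_p: 0.5, c_d: 1.0}
    vessel: {role: distribution, behaviour: versatile}
    density: {type: uniform}
    roots:
      - {position: [-1, 0], radius: 0.05, inflow: 0.5}
      - {position: [1, 0], radius: 0.05, inflow: 0.5}
  - label: 2
    domain: {shape: disc, center: [0, 0], radius: 1}
    geo: {gamma: 3, delta: 0}
    opt: {nu: 1.0, f_r: 0.9, f_n: 8, delta_v: 7}
    budget: 975
    cost: vol
    vessel: {role: distribution, behaviour: versatile}
    density: {type: uniform}
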