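# Stripe-like patterns from horizontally polarized protrusions.
mode: coupled
lattice: {nx: 45, ny: 45}
pathway: {w_a: 1, q_a: 0.001, w_b: 0.2, q_b: 0.15}
protrusion: {length: 5, directions: [0, 3.141592653589793], width: 0.15707963267948966}
mesh: {n_voxels: 40}
t_end: 200
times: [4, 20, 40, 200]
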