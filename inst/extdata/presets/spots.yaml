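# Sparse spot patterns by differential signal weighting.
mode: coupled
lattice: {nx: 45, ny: 45}
pathway: {w_a: 1, q_a: 0.001, w_b: 0.06, q_b: 0.06}
mesh: {n_voxels: 40}
t_end: 200
times: [4, 20, 40, 200]
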