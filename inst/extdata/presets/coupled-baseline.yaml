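# Full two-layer model: baseline pathway over a replayed growth log.
# Supply the recorded log with --events.
mode: coupled
lattice: {nx: 45, ny: 45}
mesh: {n_voxels: 40}
t_end: 200
times: [4, 20, 40, 200]
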