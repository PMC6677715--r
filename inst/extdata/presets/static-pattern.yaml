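# Stochastic lateral inhibition on a static hexagonal grid (baseline).
mode: wellmixed
lattice: {nx: 10, ny: 10}
t_end: 200
times: [4, 20, 40, 200]
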