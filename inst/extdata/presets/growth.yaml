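# Nutrient-limited growth from a single founder cell to 1000 cells.
mode: growth
lattice: {nx: 45, ny: 45}
growth: {target_size: 1000}
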