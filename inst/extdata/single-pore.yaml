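# Single unit pore on the reflecting plane: the capacitance benchmark.
geometry:
  plane_pores:
    - center: [0, 0]
      radius: 1
run:
  M: 2000
  seed: 9
  release:
    surface: hemisphere
    radius: 5
output:
  records: records.tsv
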