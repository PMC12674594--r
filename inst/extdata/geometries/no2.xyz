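3
optimized with neodh B3LYP/synTZ (synthetic basis), cyclic quadratic refinement; charge -1
N       0.000000000000     0.000000000000     0.000000000000
O       1.069805123667     0.000000000000     0.673070349898
O      -1.069805123667     0.000000000000     0.673070349898
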