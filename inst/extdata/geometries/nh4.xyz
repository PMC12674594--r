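5
optimized with neodh B3LYP/synTZ (synthetic basis), cyclic quadratic refinement; charge 1
N       0.000000000000     0.000000000000     0.000000000000
H       0.591180777549     0.591180777549     0.591180777549
H       0.591180777549    -0.591180777549    -0.591180777549
H      -0.591180777549     0.591180777549    -0.591180777549
H      -0.591180777549    -0.591180777549     0.591180777549
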