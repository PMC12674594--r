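4
optimized with neodh B3LYP/synTZ (synthetic basis), cyclic quadratic refinement; charge 0
O       0.000000000000     0.000000000000     0.000000000000
N       1.434353712137     0.000000000000     0.000000000000
H      -0.208443283659     0.000000000000    -0.943551718899
O       1.850157271703     0.000000000000     1.086441484149
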